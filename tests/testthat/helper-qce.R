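# shared constants and shortcuts for the suite
kc <- qce_constants

# quick parameter bundle
par_q <- function(amf = 0, bxv = 1, omega0 = 0, n = 1,
                  grid = seq(250, 500, 10), P = 1e5) {
  qce_parameters(amf = amf, bxv = bxv, omega0 = omega0, monomer_amount = n,
                 temperature_grid = grid, pressure = P)
}

# stable state at one (T, P): gas + liquid seeds, Gibbs selection
stable_state <- function(T, P, set, params) {
  states <- list(self_consistent_state(T, P, set, params, "gas"),
                 self_consistent_state(T, P, set, params, "liquid"))
  select_stable_state(states)
}

# the frozen pseudo-water set, built once per test file
pw_set <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- make_pseudo_water()
    cached
  }
})

# independent closed-form entropy of an ideal gas of rigid-rotor/harmonic
# molecules (Sackur-Tetrode + rotational + vibrational terms), J/mol/K.
# Written from the textbook formulas, independent of the engine's path.
ideal_entropy_oracle <- function(T, P, mass, wavenumbers, inertia, sigma) {
  h <- 6.62607015e-34; kB <- 1.380649e-23; Na <- 6.02214076e23
  c0 <- 2.99792458e8
  V <- Na * kB * T / P              # molar volume
  q_tr <- (2 * pi * mass * kB * T / h^2)^1.5 * V
  S_tr <- Na * kB * (log(q_tr / Na) + 1 + 1.5)      # Sackur-Tetrode
  S_rot <- 0
  if (!is.null(inertia)) {
    q_rot <- sqrt(pi) / sigma * (8 * pi^2 * kB * T / h^2)^1.5 *
      sqrt(prod(inertia))
    S_rot <- Na * kB * (log(q_rot) + 1.5)
  }
  S_vib <- 0
  for (w in wavenumbers) {
    x <- h * c0 * 100 * w / (kB * T)
    S_vib <- S_vib + Na * kB * (x / (exp(x) - 1) - log(1 - exp(-x)))
  }
  S_tr + S_rot + S_vib
}
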