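#' Chai--Head-Gordon damping function
#'
#' Switching weight between the harmonic-oscillator and hindered-rotor
#' descriptions of a vibrational mode:
#' \deqn{f(\omega) = \left(1 + (\omega_0/\omega)^4\right)^{-1}}
#' High-frequency modes (`omega >> omega0`) get `f -> 1` (harmonic);
#' low-frequency modes get `f -> 0` (free internal rotation).
#' `f(omega0, omega0) = 1/2` exactly, and `omega0 = 0` gives exactly 1.
#'
#' @param omega mode wavenumber(s), cm^-1, > 0 (vectorized).
#' @param omega0 rotor cutoff wavenumber, cm^-1, >= 0.
#' @return damping value(s) in (0, 1].
#' @export
damping_f <- function(omega, omega0) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("damping_f: omega must be positive")
  if (!is.finite(omega0) || omega0 < 0)
    stop("damping_f: omega0 must be non-negative")
  if (omega0 == 0) return(rep(1, length(omega)))
  1 / (1 + (omega0 / omega)^4)
}

# vibrational temperature theta = h c omega / kB, K (omega in cm^-1)
.theta_vib <- function(wavenumbers) {
  (qce_constants$h * qce_constants$c * 100 / qce_constants$kB) * wavenumbers
}

#' Harmonic-oscillator vibrational partition function (log)
#'
#' \eqn{\ln q = \sum_i \ln[ e^{-\theta_i/2T} (1 - e^{-\theta_i/T})^{-1}]}
#' with \eqn{\theta_i = h c \tilde\omega_i / k_B}. The zero-point factor
#' \eqn{e^{-\theta/2T}} is included by default; the electronic energies in a
#' cluster set exclude ZPE, so the vibrational partition function is its
#' one unambiguous home.
#'
#' @param wavenumbers harmonic wavenumbers, cm^-1 (> 0); empty gives 0.
#' @param T temperature, K (> 0).
#' @param include_zpe include the zero-point factor (default `TRUE`).
#' @return `ln q_vib` (dimensionless scalar).
#' @export
q_vib_harmonic <- function(wavenumbers, T, include_zpe = TRUE) {
  stopifnot(is.finite(T), T > 0)
  if (length(wavenumbers) == 0L) return(0)
  if (any(wavenumbers <= 0)) stop("q_vib_harmonic: wavenumbers must be positive")
  th <- .theta_vib(wavenumbers) / T
  sum(.ln_q_ho_modes(th, include_zpe))
}

# per-mode harmonic ln q given theta/T
.ln_q_ho_modes <- function(th_over_T, include_zpe = TRUE) {
  lq <- -log1p(-exp(-th_over_T))
  if (include_zpe) lq <- lq - th_over_T / 2
  lq
}

#' Hindered-rotor partition function for one mode (log)
#'
#' One-dimensional free-rotor partition function with an effective reduced
#' moment of inertia. The mode's intrinsic moment is
#' \eqn{\mu(\omega) = \hbar / (4\pi\nu)} with \eqn{\nu = c\,\tilde\omega}
#' the frequency in s^-1, reduced against the cluster's average moment
#' \eqn{\bar I}: \eqn{\mu' = \mu \bar I / (\mu + \bar I)}. Then
#' \deqn{\ln q_{HR} = \tfrac12 \ln\!\left(2 \mu' k_B T \pi / \hbar^2\right).}
#' The reduction caps the rotor at the cluster's overall rotation for
#' vanishing frequencies and carries no zero-point term.
#'
#' @param omega mode wavenumber(s), cm^-1, > 0 (vectorized).
#' @param mean_inertia cluster average moment of inertia, kg m^2, > 0.
#' @param T temperature, K, > 0.
#' @return per-mode `ln q_HR` (dimensionless).
#' @export
q_mode_hindered <- function(omega, mean_inertia, T) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("q_mode_hindered: omega must be positive")
  if (!is.finite(mean_inertia) || mean_inertia <= 0)
    stop("q_mode_hindered: mean_inertia must be positive")
  stopifnot(is.finite(T), T > 0)
  hbar <- qce_constants$hbar
  nu <- qce_constants$c * 100 * omega            # s^-1
  mu <- hbar / (4 * pi * nu)                     # kg m^2
  mu_eff <- mu * mean_inertia / (mu + mean_inertia)
  0.5 * log(2 * mu_eff * qce_constants$kB * T * pi / hbar^2)
}

#' Modified RRHO vibrational partition function (log)
#'
#' Per-mode geometric-mean interpolation between the harmonic oscillator
#' and the hindered rotor, weighted by the Chai--Head-Gordon damping
#' function:
#' \deqn{\ln q_{vib} = \sum_i f(\omega_i)\ln q_{HO}(\omega_i) +
#'   (1 - f(\omega_i))\ln q_{HR}(\omega_i).}
#' Mixing is performed on logarithms (the interpolation is a product of
#' powers), and the zero-point contribution lives in the harmonic branch
#' only, so it is weighted by `f`. `omega0 = 0` reduces exactly to
#' [q_vib_harmonic()]; `omega0 -> Inf` to the pure hindered-rotor sum.
#'
#' @inheritParams q_vib_harmonic
#' @param mean_inertia cluster average moment of inertia, kg m^2; required
#'   whenever any mode has non-negligible hindered-rotor weight.
#' @param omega0 rotor cutoff, cm^-1 (0 disables mixing).
#' @param include_zpe include zero-point factor in the harmonic branch.
#' @return `ln q_vib` (dimensionless scalar).
#' @export
q_vib_mrrho <- function(wavenumbers, mean_inertia = NULL, omega0 = 0, T,
                        include_zpe = TRUE) {
  stopifnot(is.finite(T), T > 0)
  if (length(wavenumbers) == 0L) return(0)
  f <- damping_f(wavenumbers, omega0)
  lq_ho <- .ln_q_ho_modes(.theta_vib(wavenumbers) / T, include_zpe)
  if (is.null(mean_inertia)) {
    if (any(f < 1 - 1e-12))
      stop("q_vib_mrrho: mean_inertia required when omega0 > 0 activates ",
           "hindered-rotor weight on some mode")
    return(sum(f * lq_ho))
  }
  lq_hr <- q_mode_hindered(wavenumbers, mean_inertia, T)
  sum(f * lq_ho + (1 - f) * lq_hr)
}

#' Per-mode partition terms (diagnostic)
#'
#' Returns the per-mode decomposition used by [q_vib_mrrho()]: damping
#' weight, harmonic and hindered-rotor logs, and their mixture.
#'
#' @inheritParams q_vib_mrrho
#' @return data.frame with columns `wavenumber`, `f_weight`, `ln_q_ho`,
#'   `ln_q_hr`, `ln_q_mixed`.
#' @export
mode_partition <- function(wavenumbers, mean_inertia = NULL, omega0 = 0, T,
                           include_zpe = TRUE) {
  f <- damping_f(wavenumbers, omega0)
  lq_ho <- .ln_q_ho_modes(.theta_vib(wavenumbers) / T, include_zpe)
  lq_hr <- if (is.null(mean_inertia)) rep(NA_real_, length(wavenumbers))
           else q_mode_hindered(wavenumbers, mean_inertia, T)
  mixed <- ifelse(f > 1 - 1e-12 & is.na(lq_hr), f * lq_ho,
                  f * lq_ho + (1 - f) * lq_hr)
  data.frame(wavenumber = wavenumbers, f_weight = f,
             ln_q_ho = lq_ho, ln_q_hr = lq_hr, ln_q_mixed = mixed)
}

#' Translational partition function (log)
#'
#' Particle in a box: \eqn{\ln q = \tfrac32 \ln(2\pi m k_B T / h^2) +
#' \ln V_{acc}} where the accessible volume is the phase volume reduced by
#' the excluded volume of the clusters.
#'
#' @param mass particle mass, kg.
#' @param T temperature, K.
#' @param accessible_volume accessible volume, m^3 (> 0).
#' @return `ln q_trans`.
#' @export
q_translational <- function(mass, T, accessible_volume) {
  stopifnot(is.finite(mass), mass > 0, is.finite(T), T > 0)
  if (!is.finite(accessible_volume) || accessible_volume <= 0)
    stop("q_translational: accessible volume must be positive (collapsed phase)")
  1.5 * log(2 * pi * mass * qce_constants$kB * T / qce_constants$h^2) +
    log(accessible_volume)
}

#' Rigid-rotor rotational partition function (log)
#'
#' Nonlinear: \eqn{\ln[(\sqrt{\pi}/\sigma)(8\pi^2 k_B T/h^2)^{3/2}
#' \sqrt{I_A I_B I_C}]}; linear: \eqn{\ln[8\pi^2 I k_B T/(\sigma h^2)]};
#' monatomic (`inertia = NULL`): 0.
#'
#' @param inertia principal moments, kg m^2 (length 3, or 1 with
#'   `linear = TRUE`, or `NULL` for monatomic).
#' @param sigma rotational symmetry number.
#' @param T temperature, K.
#' @param linear logical.
#' @return `ln q_rot`.
#' @export
q_rotational <- function(inertia, sigma = 1L, T, linear = FALSE) {
  stopifnot(is.finite(T), T > 0)
  if (is.null(inertia) || length(inertia) == 0L) return(0)
  h <- qce_constants$h; kB <- qce_constants$kB
  if (linear) {
    if (length(inertia) != 1L) stop("q_rotational: linear species takes one moment")
    log(8 * pi^2 * inertia * kB * T / (sigma * h^2))
  } else {
    if (length(inertia) != 3L)
      stop("q_rotational: polyatomic nonlinear species needs three moments")
    log(sqrt(pi) / sigma) + 1.5 * log(8 * pi^2 * kB * T / h^2) +
      0.5 * sum(log(inertia))
  }
}

#' Electronic partition function with mean-field term (log)
#'
#' Only the adiabatic ground state is considered (degeneracy 1) plus an
#' attractive mean-field energy describing average intercluster
#' interactions, \eqn{\epsilon_{mf} = -a_{mf}\, i\, \rho} (J/mol) with
#' \eqn{\rho} the monomer density in mol m^-3. Then
#' \eqn{\ln q_{elec} = -(E_{assoc} + \epsilon_{mf})/(k_B T)} per particle.
#'
#' @param assoc_energy association energy, J per particle.
#' @param amf mean-field parameter, J m^3 mol^-2.
#' @param monomer_count cluster size i.
#' @param monomer_density total monomer density, mol m^-3.
#' @param T temperature, K.
#' @return `ln q_elec` per particle.
#' @export
electronic_term <- function(assoc_energy, amf, monomer_count, monomer_density, T) {
  stopifnot(is.finite(T), T > 0, monomer_density >= 0)
  emf <- mean_field_energy(amf, monomer_count, monomer_density) / qce_constants$N_A
  -(assoc_energy + emf) / (qce_constants$kB * T)
}

#' Mean-field energy per mole of cluster
#'
#' \eqn{\epsilon_{mf} = -a_{mf}\, i\, \rho}, J mol^-1.
#'
#' @inheritParams electronic_term
#' @return J per mole of cluster (<= 0).
#' @export
mean_field_energy <- function(amf, monomer_count, monomer_density) {
  -amf * monomer_count * monomer_density
}

#' Assemble per-cluster log partition functions
#'
#' Computes `ln q` per particle for every cluster in a set at temperature
#' `T`, phase volume `V`, and excluded volume `Vexcl`. The result splits
#' into a volume-independent part (vibration, rotation, the mass-dependent
#' translational prefactor, the association energy) and the
#' volume-dependent part (`ln V_acc` and the mean-field term), so that the
#' equilibrium solver can cheaply update `ln q` while iterating on the
#' volume.
#'
#' @param set `qce_cluster_set`.
#' @param params `qce_parameters` (uses `amf`, `omega0`, `monomer_amount`).
#' @param T temperature, K.
#' @param V phase volume, m^3.
#' @param Vexcl excluded volume, m^3 (< V).
#' @return numeric vector of per-cluster `ln q` (per particle), named by
#'   cluster label.
#' @export
cluster_ln_q <- function(set, params, T, V, Vexcl = 0) {
  base <- .ln_q_T_part(set, params, T)
  .ln_q_full(base, params, T, V, Vexcl)
}

# volume-independent pieces, computed once per (set, params, T)
.ln_q_T_part <- function(set, params, T) {
  kB <- qce_constants$kB
  n <- length(set)
  lq0 <- numeric(n); i <- integer(n)
  for (k in seq_len(n)) {
    r <- set[[k]]
    lq_vib <- q_vib_mrrho(r$wavenumbers, r$mean_inertia, params$omega0, T)
    lq_rot <- q_rotational(r$inertia, r$sigma, T, r$linear)
    lq_tr0 <- 1.5 * log(2 * pi * r$mass * kB * T / qce_constants$h^2)
    lq_el0 <- -(r$energy / qce_constants$N_A) / (kB * T)
    lq0[k] <- lq_vib + lq_rot + lq_tr0 + lq_el0
    i[k] <- r$monomer_count
  }
  list(lq0 = lq0, i = i, T = T,
       vol = vapply(set, `[[`, numeric(1), "volume"),
       labels = vapply(set, `[[`, character(1), "label"))
}

# add ln V_acc and the mean-field term
.ln_q_full <- function(base, params, T, V, Vexcl) {
  Vacc <- V - Vexcl
  if (!is.finite(Vacc) || Vacc <= 0)
    stop("collapsed phase: accessible volume <= 0")
  rho <- params$monomer_amount / V                       # mol m^-3
  lq <- base$lq0 + log(Vacc) +
    (params$amf * base$i * rho) / (qce_constants$R * T)  # -eps_mf/(kB T) per particle
  names(lq) <- base$labels
  lq
}
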