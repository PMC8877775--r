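test_that("damping function matches its closed form and symmetry", {
  expect_identical(damping_f(c(10, 50, 3000), 0), c(1, 1, 1))
  expect_equal(damping_f(50, 50), 0.5)                # f(omega0, omega0) = 1/2
  expect_equal(damping_f(100, 50), 16 / 17)
  expect_equal(damping_f(10, 100), 1 / 10001)
  expect_error(damping_f(-5, 50), "positive")
  # monotone increasing in omega, decreasing in omega0
  w <- seq(5, 500, by = 5)
  expect_true(all(diff(damping_f(w, 50)) > 0))
  expect_true(all(damping_f(w, 100) < damping_f(w, 50)))
})

test_that("harmonic vibrational partition function has its textbook limits", {
  # single mode with theta/T = ln 2 gives q = 2 (geometric series)
  T <- 300
  w <- T * log(2) / (kc$h * kc$c * 100 / kc$kB)
  expect_equal(exp(q_vib_harmonic(w, T, include_zpe = FALSE)), 2,
               tolerance = 1e-12)
  # ground state only as T -> 0
  expect_equal(exp(q_vib_harmonic(500, 1e-2, include_zpe = FALSE)), 1)
  # classical limit k_B T/(h c w) within 1% for theta/T < 0.01
  T_hot <- 1e6
  w_soft <- 5
  th <- kc$h * kc$c * 100 * w_soft / kc$kB
  expect_lt(th / T_hot, 0.01)
  expect_equal(exp(q_vib_harmonic(w_soft, T_hot, include_zpe = FALSE)),
               T_hot / th, tolerance = 1e-2)
  # frozen oracle: water monomer modes at 298.15 K (independent arithmetic)
  expect_equal(q_vib_harmonic(c(1595, 3657, 3756), 298.15),
               -21.73441420020886, tolerance = 1e-12)
  expect_equal(q_vib_harmonic(c(1595, 3657, 3756), 298.15, include_zpe = FALSE),
               0.00045434340246788656, tolerance = 1e-9)
})

test_that("hindered-rotor mode reaches both reduced-moment limits", {
  T <- 298.15
  Ibar <- 1e-45
  # omega -> 0: mu >> Ibar, q -> sqrt(2 Ibar kB T pi / hbar^2)
  expect_equal(q_mode_hindered(1e-6, Ibar, T),
               0.5 * log(2 * Ibar * kc$kB * T * pi / kc$hbar^2),
               tolerance = 1e-6)
  # large omega, tiny Ibar never binds: mu' -> mu
  w_hi <- 3000
  mu <- kc$hbar / (4 * pi * kc$c * 100 * w_hi)
  expect_equal(q_mode_hindered(w_hi, 1e30 * mu, T),
               0.5 * log(2 * mu * kc$kB * T * pi / kc$hbar^2),
               tolerance = 1e-9)
  # frozen oracle: omega = 30 cm^-1, Ibar = 1e-45 kg m^2, 298.15 K
  expect_equal(q_mode_hindered(30, 1e-45, 298.15), 1.5340241022670715,
               tolerance = 1e-12)
  expect_error(q_mode_hindered(30, -1e-45, T), "positive")
})

test_that("mRRHO interpolation recovers both limits and the frozen mixture", {
  w <- c(25, 60, 250, 1600)
  Ibar <- 1e-45
  T <- 300
  # omega0 = 0: identical to the harmonic form to machine precision
  expect_identical(q_vib_mrrho(w, Ibar, omega0 = 0, T = T),
                   q_vib_harmonic(w, T))
  # omega0 -> infinity: pure hindered-rotor sum
  expect_equal(q_vib_mrrho(w, Ibar, omega0 = 1e6, T = T),
               sum(q_mode_hindered(w, Ibar, T)), tolerance = 1e-10)
  # frozen oracle: mixed value at omega0 = 50 (independent per-mode script)
  expect_equal(q_vib_mrrho(w, Ibar, omega0 = 50, T = T),
               -1.1932768273828747, tolerance = 1e-12)
  # configuration error: rotor weight without an inertia to reduce against
  expect_error(q_vib_mrrho(w, NULL, omega0 = 50, T = T), "mean_inertia")
  # mode-level mixing stays between the two branches
  mp <- mode_partition(w, Ibar, omega0 = 50, T = T)
  expect_true(all(mp$ln_q_mixed >= pmin(mp$ln_q_ho, mp$ln_q_hr) - 1e-12))
  expect_true(all(mp$ln_q_mixed <= pmax(mp$ln_q_ho, mp$ln_q_hr) + 1e-12))
  expect_equal(mp$ln_q_mixed,
               mp$f_weight * mp$ln_q_ho + (1 - mp$f_weight) * mp$ln_q_hr)
})

test_that("translational and rotational terms scale as required", {
  m <- 18.0152 * kc$amu
  T <- 298.15
  expect_equal(q_translational(m, T, 2e-3) - q_translational(m, T, 1e-3),
               log(2))
  expect_equal(q_translational(m, 4 * T, 1) - q_translational(m, T, 1),
               3 * log(2), tolerance = 1e-12)
  expect_equal(q_translational(m, T, 1), 73.38134023065598, tolerance = 1e-12)
  expect_error(q_translational(m, T, 0), "volume")

  expect_identical(q_rotational(NULL, 1, T), 0)
  I3 <- c(0.6150, 1.1550, 1.7699) * kc$amu * 1e-20
  expect_equal(q_rotational(I3, 2, T) - q_rotational(I3, 1, T), -log(2))
  expect_equal(q_rotational(I3, 2, T), 3.7571629949626533, tolerance = 1e-12)
  expect_error(q_rotational(I3[1:2], 1, T), "three")
})

test_that("electronic term reproduces the mean-field arithmetic", {
  T <- 298.15
  expect_equal(electronic_term(0, 0, 1, 0, T), 0)
  E <- -2e4 / kc$N_A
  expect_equal(electronic_term(E, 0, 1, 5e4, T), -E / (kc$kB * T))
  # amf = 0.2 J m^3 mol^-2, i = 4, rho = 5.5e4 mol/m^3: eps_mf = -4.4e4 J/mol
  expect_equal(mean_field_energy(0.2, 4, 5.5e4), -4.4e4)
  expect_equal(electronic_term(0, 0.2, 4, 5.5e4, T), 17.749400039845533,
               tolerance = 1e-12)
})

test_that("analytic temperature derivative of ln q matches finite differences", {
  # the internal-energy formulas used by the thermodynamics module are the
  # analytic dln q/dT of every term; verify with central differences
  set <- pw_set()
  params <- par_q(amf = 0.15, bxv = 1.4, omega0 = 50)
  T <- 310; V <- 3e-4
  dT <- 1e-3
  base_p <- qce:::.ln_q_T_part(set, params, T + dT)
  base_m <- qce:::.ln_q_T_part(set, params, T - dT)
  lq_p <- qce:::.ln_q_full(base_p, params, T + dT, V, 0)
  lq_m <- qce:::.ln_q_full(base_m, params, T - dT, V, 0)
  dlnq_fd <- (lq_p - lq_m) / (2 * dT)
  u <- qce:::.cluster_u(set, params, T, V)   # u = kB T^2 dln q/dT
  dlnq_an <- u / (kc$kB * T^2)
  expect_equal(dlnq_fd, dlnq_an, tolerance = 1e-6, ignore_attr = TRUE)
})
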