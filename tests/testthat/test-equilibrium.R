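test_that("population solver is exact for a single cluster and conserves mass", {
  set <- make_monomer_only()
  params <- par_q(amf = 0, bxv = 1e-300)
  lq <- cluster_ln_q(set, params, 300, 0.024, 0)
  sol <- solve_populations(lq, 1L, 2.5)
  expect_equal(unname(sol$n), 2.5, tolerance = 1e-12)

  # conservation on the full fixture at an arbitrary volume
  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5)
  sizes <- vapply(pw, `[[`, integer(1), "monomer_count")
  for (T in c(260, 340, 460)) {
    lq <- cluster_ln_q(pw, params, T, 1e-3, 2e-5)
    sol <- solve_populations(lq, sizes, 1)
    expect_equal(sum(sizes * sol$n), 1, tolerance = 1e-10)
  }
})

test_that("populations match the closed-form monomer-dimer quadratic", {
  set <- make_monomer_dimer()
  params <- par_q(amf = 0, bxv = 1e-300)
  for (T in seq(250, 450, by = 25)) {
    V <- kc$R * T / 1e5
    lq <- cluster_ln_q(set, params, T, V, 0)
    sol <- solve_populations(lq, c(1L, 2L), 1)
    oracle <- monomer_dimer_oracle(lq, 1)
    expect_equal(unname(sol$n), unname(oracle), tolerance = 1e-8)
  }
})

test_that("volume candidates degenerate to the (shifted) ideal gas law", {
  T <- 350; P <- 1e5; n_c <- 0.4; n_tot <- 1
  expect_equal(volume_candidates(P, T, n_c, n_tot, 0, 0),
               n_c * kc$R * T / P, tolerance = 1e-12)
  Vx <- 2e-5
  expect_equal(volume_candidates(P, T, n_c, n_tot, Vx, 0),
               Vx + n_c * kc$R * T / P, tolerance = 1e-12)
})

test_that("cubic roots agree with an independent polynomial solver", {
  # generic coefficients evaluated through base::polyroot directly on the
  # cubic written out by hand (independent of the package's assembly)
  P <- 1e5; T <- 350; n_c <- 0.1; n_tot <- 1; Vx <- 2e-5; amf <- 0.2
  v <- volume_candidates(P, T, n_c, n_tot, Vx, amf)
  coef <- c(-amf * n_tot^2 * Vx, amf * n_tot^2,
            -(P * Vx + kc$R * T * n_c), P)
  r <- polyroot(coef)
  r <- sort(Re(r[abs(Im(r)) < 1e-8 * abs(r)]))
  r <- r[r > Vx]
  expect_equal(v, r, tolerance = 1e-7)
  # every root satisfies the pressure equation written independently
  for (V in v)
    expect_equal(kc$R * T * n_c / (V - Vx) - amf * n_tot^2 / V^2, P,
                 tolerance = 1e-9 * P)
})

test_that("returned volumes satisfy the differentiated pressure constraint", {
  # spot version of the volume-equation oracle: finite differences of the
  # full system ln Q around each candidate volume
  pw <- pw_set()
  sizes <- vapply(pw, `[[`, integer(1), "monomer_count")
  set.seed(7)
  for (k in 1:10) {
    params <- par_q(amf = runif(1, 0, 2), bxv = runif(1, 0.5, 2))
    T <- runif(1, 250, 500); P <- runif(1, 1e4, 5e5)
    lnn <- runif(length(pw), -25, -1)
    n_tot <- sum(sizes * exp(lnn))
    params$monomer_amount <- n_tot
    base <- qce:::.solver_base(pw, params, T)
    Vexcl <- qce:::.excluded_volume(base, params, lnn)
    v <- volume_candidates(P, T, sum(exp(lnn)), n_tot, Vexcl, params$amf)
    expect_gt(length(v), 0)
    for (V in v) {
      h <- 1e-7 * V
      dlnQ <- (system_ln_q(pw, params, T, V + h, lnn) -
               system_ln_q(pw, params, T, V - h, lnn)) / (2 * h)
      expect_equal(kc$kB * T * dlnQ, P, tolerance = 1e-6 * P)
    }
  }
})

test_that("monomer-only ideal system converges immediately and deterministically", {
  set <- make_monomer_only()
  params <- par_q(amf = 0, bxv = 1)
  params$bxv <- 1e-300   # effectively no excluded volume
  st <- self_consistent_state(300, 1e5, set, params, "gas")
  expect_true(st$converged)
  expect_lte(st$iterations, 2L)
  expect_equal(st$volume, kc$R * 300 / 1e5, tolerance = 1e-10)
  st2 <- self_consistent_state(300, 1e5, set, params, "gas")
  expect_identical(st$volume, st2$volume)
  expect_identical(st$ln_populations, st2$ln_populations)
})

test_that("gas and liquid branches of the fixture are distinct at 298 K", {
  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5)
  sg <- self_consistent_state(298, 1e5, pw, params, "gas")
  sl <- self_consistent_state(298, 1e5, pw, params, "liquid")
  expect_true(sg$converged && sl$converged)
  expect_gt(sg$volume / sl$volume, 10)
  expect_lt(sl$gibbs_energy, sg$gibbs_energy)   # liquid stable at 298 K
  expect_identical(select_stable_state(list(sg, sl))$branch_tag, "liquid")
  expect_gt(sl$volume, sl$excluded_volume)
})

test_that("stable-state selection follows the Gibbs criterion", {
  mk <- function(G, V, conv = TRUE)
    structure(list(gibbs_energy = G, volume = V, converged = conv),
              class = "qce_state")
  expect_identical(select_stable_state(list(mk(-5, 1)))$volume, 1)
  expect_identical(select_stable_state(list(mk(-5, 1), mk(-7, 2)))$volume, 2)
  # tie resolved toward the larger volume
  expect_identical(select_stable_state(list(mk(-5, 1), mk(-5, 3)))$volume, 3)
  expect_error(select_stable_state(list(mk(-5, 1, conv = FALSE))),
               "no converged")
})

test_that("isobar scan finds exactly one transition on the fixture and none on an ideal gas", {
  set <- make_monomer_only()
  params <- par_q(amf = 0, bxv = 1, grid = seq(250, 450, 10))
  params$bxv <- 1e-300
  iso <- isobar_scan(set, params)
  expect_true(all(iso$table$converged))
  expect_true(is.na(iso$transition_temperature))
  # with amf = 0 the volume is non-decreasing in T
  expect_true(all(diff(iso$table$volume) > 0))
  expect_equal(iso$table$volume, kc$R * iso$table$temperature / 1e5,
               tolerance = 1e-8)

  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5, grid = seq(300, 450, 5))
  iso <- isobar_scan(pw, params)
  expect_true(is.finite(iso$transition_temperature))
  jumps <- abs(diff(iso$table$volume)) /
    pmin(iso$table$volume[-1], iso$table$volume[-nrow(iso$table)])
  expect_equal(sum(jumps > 0.5), 1L)   # a single volume collapse
})

test_that("transition refinement is stable under grid halving", {
  pw <- pw_set()
  p1 <- par_q(amf = 0.2, bxv = 1.5, grid = seq(355, 372, 1))
  p2 <- par_q(amf = 0.2, bxv = 1.5, grid = seq(355, 372, 0.5))
  t1 <- isobar_scan(pw, p1)$transition_temperature
  t2 <- isobar_scan(pw, p2)$transition_temperature
  expect_lt(abs(t1 - t2), 0.02)
})
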