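test_that("ideal monomer gas reproduces the closed-form entropy and density", {
  set <- make_monomer_only()
  params <- par_q(amf = 0, bxv = 1)
  params$bxv <- 1e-300
  T <- 298.15; P <- 1e5
  st <- self_consistent_state(T, P, set, params, "gas")
  tp <- thermo_point(st, set, params)
  S_ref <- ideal_entropy_oracle(T, P, set[[1]]$mass, set[[1]]$wavenumbers,
                                set[[1]]$inertia, set[[1]]$sigma)
  expect_equal(tp$entropy, S_ref, tolerance = 1e-6)
  expect_equal(tp$mass_density, set[[1]]$mass * kc$N_A * P / (kc$R * T),
               tolerance = 1e-9)

  # monatomic variant: Sackur-Tetrode only
  mono <- make_monomer_only(mass_amu = 39.948, frequencies = numeric(),
                            inertia_amuA2 = NULL)
  st <- self_consistent_state(T, P, mono, params, "gas")
  tp <- thermo_point(st, mono, params, compute_cp = FALSE)
  S_ref <- ideal_entropy_oracle(T, P, mono[[1]]$mass, numeric(), NULL, 1)
  expect_equal(tp$entropy, S_ref, tolerance = 1e-6)
})

test_that("thermodynamic identities hold on fixture states", {
  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5)
  for (T in c(280, 340, 420)) {
    st <- stable_state(T, 1e5, pw, params)
    tp <- thermo_point(st, pw, params, compute_cp = FALSE)
    # G = H - T S and G = -kB T lnQ + PV agree by construction and with
    # the solver's own Gibbs energy
    expect_equal(tp$gibbs_energy, st$gibbs_energy / params$monomer_amount,
                 tolerance = 1e-9)
    expect_equal(tp$gibbs_energy, tp$enthalpy - T * tp$entropy,
                 tolerance = 1e-6)
    # finite-difference U from lnQ at fixed V and populations
    dT <- 0.05
    lnQp <- system_ln_q(pw, params, T + dT, st$volume, st$ln_populations)
    lnQm <- system_ln_q(pw, params, T - dT, st$volume, st$ln_populations)
    U_fd <- kc$kB * T^2 * (lnQp - lnQm) / (2 * dT)
    expect_equal(tp$internal_energy, U_fd / params$monomer_amount,
                 tolerance = 1e-5)
  }
})

test_that("entropy per mole of monomer is intensive", {
  pw <- pw_set()
  p1 <- par_q(amf = 0.2, bxv = 1.5, n = 1)
  p2 <- par_q(amf = 0.2, bxv = 1.5, n = 2)
  s1 <- thermo_point(stable_state(320, 1e5, pw, p1), pw, p1, compute_cp = FALSE)
  s2 <- thermo_point(stable_state(320, 1e5, pw, p2), pw, p2, compute_cp = FALSE)
  expect_equal(s1$entropy, s2$entropy, tolerance = 1e-8)
})

test_that("monomer-normalized populations sum to one and follow arithmetic", {
  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5)
  st <- stable_state(298, 1e5, pw, params)
  x <- monomer_normalized_populations(st)
  expect_equal(sum(x), 1, tolerance = 1e-10)

  # hand-built state: n1 = n2 = n_tot/3 gives fractions 1/3, 2/3
  toy <- structure(list(sizes = c(1, 2), populations = c(1, 1) / 3,
                        ln_populations = log(c(1, 1) / 3)),
                   class = "qce_state")
  expect_equal(unname(monomer_normalized_populations(toy)), c(1, 2) / 3)
})

test_that("ionic product follows the concentration arithmetic and its sentinel", {
  pw <- pw_set()
  # hand-computable toy state: one ion-pair cluster, n = 1e-7 mol, V = 1 L
  z <- vapply(pw, `[[`, integer(1), "ion_pairs")
  lnn <- rep(-745, length(pw))
  lnn[which(z > 0)[1]] <- log(1e-7)
  toy <- structure(list(temperature = 298.15, volume = 1e-3,
                        ln_populations = lnn, populations = exp(lnn),
                        sizes = vapply(pw, `[[`, integer(1), "monomer_count")),
                   class = "qce_state")
  ip <- ionic_product(toy, pw)
  expect_equal(ip$c_ion, 1e-7)
  expect_equal(ip$pKw, 14)
  # joint (n, V) scaling leaves Kw unchanged
  toy2 <- toy; toy2$ln_populations <- lnn + log(2); toy2$volume <- 2e-3
  expect_equal(ionic_product(toy2, pw)$Kw, ip$Kw, tolerance = 1e-12)
  # relabeling/reordering clusters does not change pKw
  perm <- rev(seq_along(pw))
  pw_r <- cluster_set(unclass(pw)[perm])
  ord <- match(vapply(pw_r, `[[`, character(1), "label"),
               vapply(pw, `[[`, character(1), "label"))
  toy3 <- toy; toy3$ln_populations <- lnn[ord]
  toy3$sizes <- toy$sizes[ord]
  expect_equal(ionic_product(toy3, pw_r)$pKw, ip$pKw)
  # set without ion pairs: Kw = 0, pKw = +Inf sentinel
  mono <- make_monomer_only()
  st0 <- structure(list(temperature = 300, volume = 1e-3,
                        ln_populations = 0, populations = 1, sizes = 1L),
                   class = "qce_state")
  ip0 <- ionic_product(st0, mono)
  expect_identical(ip0$Kw, 0)
  expect_identical(ip0$pKw, Inf)
})

test_that("pKw of the fixture decreases from cold liquid to hot liquid", {
  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5)
  p_cold <- ionic_product(stable_state(280, 1e5, pw, params), pw)$pKw
  p_warm <- ionic_product(stable_state(350, 1e5, pw, params), pw)$pKw
  expect_true(is.finite(p_cold) && is.finite(p_warm))
  expect_lt(p_warm, p_cold)   # thermal activation of self-dissociation
})

test_that("vaporization entropy is consistent with the transition enthalpy", {
  pw <- pw_set()
  params <- par_q(amf = 0.2, bxv = 1.5, grid = seq(300, 450, 2))
  iso <- isobar_scan(pw, params)
  Tt <- iso$transition_temperature
  expect_true(is.finite(Tt))
  dS_trs <- vaporization_entropy(iso, Tt)
  dH <- transition_enthalpy(iso)
  # at equilibrium Delta G = 0, so Delta S = Delta H / T
  expect_equal(dS_trs, dH / Tt, tolerance = 2e-2)
  # extrapolated value below the transition is finite and positive, and
  # robust to widening the fit window
  dS298_30 <- vaporization_entropy(iso, 298)
  dS298_50 <- vaporization_entropy(iso, 298, window = 50)
  expect_gt(dS298_30, dS_trs)    # larger at lower temperature
  expect_lt(abs(dS298_50 - dS298_30), 2)
  # errors: no transition / short window
  mono <- make_monomer_only()
  pm <- par_q(amf = 0, bxv = 1, grid = seq(300, 400, 10))
  iso0 <- isobar_scan(mono, pm)
  expect_error(vaporization_entropy(iso0, 298), "transition")
  expect_error(vaporization_entropy(iso, 298, window = 5), "5 grid points")
})
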