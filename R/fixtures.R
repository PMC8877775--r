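# Lehmer / Park-Miller MINSTD generator (state_{k+1} = 48271 * state_k mod
# 2^31 - 1). Chosen over R's ambient RNG so fixture generation is a named,
# explicitly seeded algorithm reproducible from any language; all products
# stay below 2^47 and are exact in doubles.
.lcg_new <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  if (s <= 0) s <- s + 2147483646
  env <- new.env(parent = emptyenv())
  env$state <- s
  env
}

.lcg_runif <- function(gen, n = 1L, min = 0, max = 1) {
  out <- numeric(n)
  for (k in seq_len(n)) {
    gen$state <- (48271 * gen$state) %% 2147483647
    out[k] <- gen$state / 2147483647
  }
  min + (max - min) * out
}

# water-like monomer descriptors (file units)
.water_monomer_defaults <- list(
  mass_amu = 18.0152,
  frequencies = c(1594.8, 3656.7, 3755.8),
  inertia_amuA2 = c(0.6150, 1.1550, 1.7699),
  sigma = 2L,
  volume_A3 = 29.9)

#' Monomer-only cluster set
#'
#' Single-record set. With `amf = 0, bxv = 0` the engine must reproduce
#' ideal-gas behavior on it exactly, which makes it the basic limit
#' fixture. Passing `frequencies = numeric()` and `inertia = NULL` gives a
#' monatomic variant whose entropy is the pure translational
#' (Sackur--Tetrode) closed form.
#'
#' @param mass_amu monomer mass, amu.
#' @param frequencies harmonic wavenumbers, cm^-1.
#' @param inertia_amuA2 three principal moments, amu Angstrom^2, or `NULL`
#'   for a monatomic species.
#' @param sigma rotational symmetry number.
#' @param volume_A3 monomer volume, Angstrom^3.
#' @return `qce_cluster_set` with one record.
#' @export
make_monomer_only <- function(mass_amu = 18.0152,
                              frequencies = c(1594.8, 3656.7, 3755.8),
                              inertia_amuA2 = c(0.6150, 1.1550, 1.7699),
                              sigma = 2L, volume_A3 = 29.9) {
  rec <- cluster_record(
    label = "m1", monomer_count = 1L, energy = 0,
    wavenumbers = frequencies,
    inertia = if (!is.null(inertia_amuA2)) inertia_amuA2 * .u_amuA2,
    sigma = if (is.null(inertia_amuA2)) 1L else sigma,
    volume = volume_A3 * .u_A3,
    mass = mass_amu * qce_constants$amu)
  cluster_set(list(rec))
}

#' Monomer--dimer cluster set
#'
#' Smallest nontrivial chemical equilibrium; its mass-action solution has
#' the closed quadratic form provided by [monomer_dimer_oracle()], making
#' this the reference fixture for the population solver.
#'
#' @param association_energy dimer association energy, kJ per mole of
#'   dimer (negative for a bound dimer).
#' @param dimer_frequencies dimer wavenumbers, cm^-1; the default is the
#'   doubled monomer modes plus six intermolecular modes, all at or above
#'   150 cm^-1 so the mRRHO cutoffs of 50 and 100 cm^-1 leave the dimer
#'   untouched.
#' @param monomer monomer descriptor list as in [make_monomer_only()]
#'   arguments (`mass_amu`, `frequencies`, `inertia_amuA2`, `sigma`,
#'   `volume_A3`).
#' @return `qce_cluster_set` with two records.
#' @export
make_monomer_dimer <- function(association_energy = -20,
                               dimer_frequencies = NULL,
                               monomer = .water_monomer_defaults) {
  if (is.null(dimer_frequencies))
    dimer_frequencies <- sort(c(rep(monomer$frequencies, 2) + c(-8, 8),
                                c(152, 185, 214, 357, 522, 708)))
  m <- cluster_record(
    label = "m1", monomer_count = 1L, energy = 0,
    wavenumbers = monomer$frequencies,
    inertia = monomer$inertia_amuA2 * .u_amuA2,
    sigma = monomer$sigma,
    volume = monomer$volume_A3 * .u_A3,
    mass = monomer$mass_amu * qce_constants$amu)
  d <- cluster_record(
    label = "d2", monomer_count = 2L,
    energy = association_energy * .u_kJmol,
    wavenumbers = dimer_frequencies,
    inertia = c(8.0, 70.0, 75.0) * .u_amuA2,
    sigma = 1L,
    volume = 2 * monomer$volume_A3 * .u_A3,
    mass = 2 * monomer$mass_amu * qce_constants$amu)
  cluster_set(list(m, d))
}

#' Closed-form monomer--dimer populations
#'
#' For a two-cluster set the mass-action condition reduces to the
#' quadratic \eqn{2 K N_1^2 + N_1 - N_{tot} = 0} with
#' \eqn{K = q_2/q_1^2} (particle scale), solved by
#' \eqn{N_1 = (\sqrt{1 + 8 K N_{tot}} - 1)/(4K)}. Used as an independent
#' oracle for [solve_populations()].
#'
#' @param ln_q length-2 vector of per-particle log partition functions
#'   (monomer, dimer) at the working volume.
#' @param monomer_amount total monomer amount, mol.
#' @return named amounts (mol) of monomer and dimer.
#' @export
monomer_dimer_oracle <- function(ln_q, monomer_amount) {
  stopifnot(length(ln_q) == 2L)
  Ntot <- monomer_amount * qce_constants$N_A
  lnK <- ln_q[2] - 2 * ln_q[1]
  K <- exp(lnK)
  # stable form of (sqrt(1 + 8 K N) - 1) / (4 K)
  x <- 8 * K * Ntot
  N1 <- if (x < 1e-8) Ntot * (1 - 2 * K * Ntot)
        else 2 * Ntot / (1 + sqrt(1 + x))
  N2 <- K * N1^2
  c(m1 = N1, d2 = N2) / qce_constants$N_A
}

#' Deterministic pseudo-water cluster set
#'
#' Synthetic 15-cluster set emulating the structural features of a
#' hydrogen-bonded cluster ensemble: sizes 1--10 with cooperative
#' association energies (per-monomer binding strengthening with size
#' toward `energy_scale`), six low-frequency intermolecular modes per
#' cluster of size >= 3 drawn in 20--150 cm^-1 (so rotor cutoffs of both
#' 50 and 100 cm^-1 engage), volumes and moments of inertia scaling with
#' size, and five ion-pair clusters (sizes 5--9) destabilized by
#' `ion_pair_penalty` so their populations stay minute (monomer-normalized
#' fractions many orders of magnitude below the regular clusters, as
#' expected for self-dissociation). The monomer and dimer carry no mode
#' below 150 cm^-1, so mRRHO leaves their partition functions untouched.
#'
#' All randomness comes from the Lehmer MINSTD generator seeded with
#' `seed`: identical arguments give a bit-identical set.
#'
#' @param seed integer seed (default 42, the frozen default set).
#' @param max_size largest cluster size (default 10).
#' @param energy_scale asymptotic per-monomer association energy,
#'   kJ mol^-1 (default -75).
#' @param ion_pair_penalty destabilization of ion-pair clusters,
#'   kJ mol^-1 (default +60); `Inf` removes ion-pair population entirely
#'   (pKw sentinel +Inf downstream).
#' @return `qce_cluster_set` with 15 records (10 regular, 5 ion-pair).
#' @export
make_pseudo_water <- function(seed = 42L, max_size = 10L,
                              energy_scale = -75, ion_pair_penalty = 60) {
  stopifnot(max_size >= 6L)
  gen <- .lcg_new(seed)
  mono <- .water_monomer_defaults
  mk <- function(label, i, energy_kJ, ion_pairs) {
    if (i == 1L) {
      freqs <- mono$frequencies
      inertia <- mono$inertia_amuA2
      sigma <- mono$sigma
    } else {
      intra <- as.vector(vapply(mono$frequencies, function(w)
        w + .lcg_runif(gen, i, -40, 40), numeric(i)))
      n_inter <- 6L * i - 6L
      if (i == 2L) {
        inter <- .lcg_runif(gen, n_inter, 150, 800)
      } else {
        low <- .lcg_runif(gen, 6L, 20, 150)
        rest <- .lcg_runif(gen, n_inter - 6L, 200, 1000)
        inter <- c(low, rest)
      }
      freqs <- sort(c(intra, inter))
      inertia <- sort(i^(5 / 3) * c(18, 24, 30) * .lcg_runif(gen, 3L, 0.9, 1.1))
      sigma <- 1L
    }
    cluster_record(
      label = label, monomer_count = i,
      energy = energy_kJ * .u_kJmol,
      wavenumbers = freqs,
      inertia = inertia * .u_amuA2,
      sigma = sigma,
      volume = i * mono$volume_A3 * .lcg_runif(gen, 1L, 0.95, 1.05) * .u_A3,
      mass = i * mono$mass_amu * qce_constants$amu,
      ion_pairs = ion_pairs)
  }
  recs <- list()
  e_reg <- numeric(max_size)
  for (i in seq_len(max_size)) {
    # strongly cooperative binding: per-monomer energy approaches
    # energy_scale for large clusters but stays shallow for the dimer and
    # trimer, so the vapor phase is essentially monomeric (as for water)
    e_reg[i] <- if (i == 1L) 0 else
      i * energy_scale * (1 - 1 / i)^3 * (1 + .lcg_runif(gen, 1L, -0.03, 0.03))
    recs[[length(recs) + 1L]] <- mk(sprintf("w%d", i), i, e_reg[i], 0L)
  }
  if (is.finite(ion_pair_penalty)) {
    # zwitterionic isomers of the mid-size clusters: same backbone energy as
    # the regular sibling, destabilized by the charge-separation penalty
    ip_sizes <- seq(max_size - 5L, max_size - 1L)
    for (i in ip_sizes) {
      recs[[length(recs) + 1L]] <-
        mk(sprintf("w%dip", i), i, e_reg[i] + ion_pair_penalty, 1L)
    }
  }
  # an infinite penalty removes the ion-pair clusters entirely (zero ion
  # population; ionic_product() then reports the pKw = +Inf sentinel)
  cluster_set(recs)
}
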