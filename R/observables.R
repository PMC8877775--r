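# per-particle internal energy, J, for every cluster at the state's (T, V)
.cluster_u <- function(set, params, T, V) {
  kB <- qce_constants$kB
  rho <- params$monomer_amount / V
  vapply(set, function(r) {
    u <- 1.5 * kB * T                                   # translation
    u <- u + if (is.null(r$inertia) || length(r$inertia) == 0L) 0
             else if (r$linear) kB * T else 1.5 * kB * T # rotation
    if (length(r$wavenumbers) > 0) {
      th <- .theta_vib(r$wavenumbers)
      f <- damping_f(r$wavenumbers, params$omega0)
      u_ho <- kB * th * (0.5 + 1 / expm1(th / T))       # incl. ZPE
      u_hr <- 0.5 * kB * T                              # 1D free rotor
      u <- u + sum(f * u_ho + (1 - f) * u_hr)
    }
    emf <- mean_field_energy(params$amf, r$monomer_count, rho) / qce_constants$N_A
    u + r$energy / qce_constants$N_A + emf
  }, numeric(1))
}

#' Thermodynamic observables of a converged state
#'
#' Internal energy from the analytic temperature derivative of
#' \eqn{\ln Q} at fixed volume and populations (3/2 k_B T translation and
#' nonlinear rotation, harmonic-mode formula including ZPE, 1/2 k_B T per
#' hindered-rotor branch weighted by \eqn{1-f}, electronic and mean-field
#' energies); then \eqn{S = U/T + k_B \ln Q}, \eqn{H = U + PV},
#' \eqn{G = H - TS}. The isobaric heat capacity is a central finite
#' difference of \eqn{H} over re-solved states at \eqn{T \pm \delta}
#' (volume re-equilibrated at constant pressure), because the isobar is a
#' constant-pressure object. All energies are reported per mole of
#' monomer.
#'
#' @param state converged `qce_state`.
#' @param set `qce_cluster_set`.
#' @param params `qce_parameters`.
#' @param compute_cp include the heat capacity (two extra state solves;
#'   default `TRUE`).
#' @param dT finite-difference step for Cp, K.
#' @return list of class `qce_thermo`: `temperature` (K),
#'   `internal_energy`, `enthalpy`, `gibbs_energy` (J/mol),
#'   `entropy`, `heat_capacity` (J/mol/K), `mass_density` (kg/m^3).
#' @export
thermo_point <- function(state, set, params, compute_cp = TRUE, dT = 0.05) {
  if (!isTRUE(state$converged)) stop("thermo_point: state not converged")
  T <- state$temperature; P <- state$pressure; V <- state$volume
  n_tot <- params$monomer_amount
  u <- .cluster_u(set, params, T, V)
  U <- qce_constants$N_A * sum(state$populations * u)     # J, extensive
  S <- U / T + qce_constants$kB * state$ln_Q
  H <- U + P * V
  G <- H - T * S
  Cp <- NA_real_
  if (compute_cp) {
    Hs <- vapply(c(T - dT, T + dT), function(Tp) {
      sp <- self_consistent_state(Tp, P, set, params, init_state = state)
      if (!sp$converged) stop("thermo_point: Cp re-solve failed at T = ", Tp)
      up <- .cluster_u(set, params, Tp, sp$volume)
      qce_constants$N_A * sum(sp$populations * up) + P * sp$volume
    }, numeric(1))
    Cp <- (Hs[2] - Hs[1]) / (2 * dT) / n_tot
  }
  structure(list(temperature = T,
                 internal_energy = U / n_tot,
                 enthalpy = H / n_tot,
                 gibbs_energy = G / n_tot,
                 entropy = S / n_tot,
                 heat_capacity = Cp,
                 mass_density = mass_density(state, set)),
            class = "qce_thermo")
}

#' Mass density of a state
#'
#' Total monomer mass over the phase volume,
#' \eqn{\rho = n_{tot} M_1 / V} in kg m^-3, with \eqn{n_{tot}} recovered
#' from the populations (\eqn{\sum_p i_p n_p}).
#'
#' @param state `qce_state`.
#' @param set `qce_cluster_set`.
#' @return density, kg m^-3.
#' @export
mass_density <- function(state, set) {
  n_tot <- sum(state$sizes * state$populations)
  mono_molar_mass <- set[[1L]]$mass * qce_constants$N_A
  n_tot * mono_molar_mass / state$volume
}

#' Monomer-normalized cluster populations
#'
#' Fraction of all monomers bound in each cluster type,
#' \eqn{x_p = i_p n_p / n_{tot}}; sums to 1.
#'
#' @param state `qce_state`.
#' @return named numeric vector of fractions.
#' @export
monomer_normalized_populations <- function(state) {
  w <- state$sizes * state$populations
  w / sum(w)
}

#' Ionic product from ion-pair cluster populations
#'
#' Every ion-pair cluster carries `ion_pairs` separated cation/anion
#' pairs, so the ion concentrations are equal and
#' \deqn{K_w = c_+ c_- = \left(\sum_p z_p N_p / V\right)^2}
#' with concentrations in mol L^-1 against the 1 mol L^-1 standard state
#' (the convention under which ambient water gives pKw near 14).
#' A set without populated ion-pair clusters gives `Kw = 0` and
#' `pKw = +Inf` (a sentinel, not an error).
#'
#' @param state `qce_state`.
#' @param set `qce_cluster_set`.
#' @return list of class `qce_ionic`: `temperature`, `c_ion` (mol/L),
#'   `Kw` ((mol/L)^2), `pKw`.
#' @export
ionic_product <- function(state, set) {
  z <- vapply(set, `[[`, integer(1), "ion_pairs")
  has <- z > 0
  if (!any(has)) {
    c_ion <- 0
  } else {
    ln_c <- .logsumexp(log(z[has]) + state$ln_populations[has]) -
      log(state$volume) - log(1000)                 # mol m^-3 -> mol L^-1
    c_ion <- exp(ln_c)
  }
  Kw <- c_ion^2
  structure(list(temperature = state$temperature, c_ion = c_ion,
                 Kw = Kw, pKw = if (Kw > 0) -log10(Kw) else Inf),
            class = "qce_ionic")
}

# thermo (without Cp) for each grid state of an isobar; cached in the object
.isobar_thermo <- function(iso) {
  vapply(iso$states, function(s) {
    tp <- thermo_point(s, iso$set, iso$params, compute_cp = FALSE)
    c(S = tp$entropy, H = tp$enthalpy, G = tp$gibbs_energy)
  }, numeric(3))
}

# re-solve both branches exactly at the refined transition temperature
.transition_states <- function(iso) {
  if (!is.finite(iso$transition_temperature))
    stop("isobar has no detected phase transition")
  Tt <- iso$transition_temperature
  liq <- self_consistent_state(Tt, iso$params$pressure, iso$set, iso$params,
                               init_state = iso$state_below)
  gas <- self_consistent_state(Tt, iso$params$pressure, iso$set, iso$params,
                               init_state = iso$state_above)
  if (!liq$converged || !gas$converged)
    stop("branch re-solve at the transition temperature did not converge")
  list(liquid = liq, gas = gas)
}

#' Direct vaporization enthalpy at the transition
#'
#' \eqn{\Delta H_{vap} = H_{gas}(T_{trs}) - H_{liq}(T_{trs})} per mole of
#' monomer, with both branches re-solved exactly at the refined transition
#' temperature.
#'
#' @param iso `qce_isobar` with a detected transition.
#' @return J mol^-1.
#' @export
transition_enthalpy <- function(iso) {
  st <- .transition_states(iso)
  hg <- thermo_point(st$gas, iso$set, iso$params, compute_cp = FALSE)$enthalpy
  hl <- thermo_point(st$liquid, iso$set, iso$params, compute_cp = FALSE)$enthalpy
  hg - hl
}

#' Vaporization entropy, with gas-branch extrapolation below the transition
#'
#' \eqn{\Delta S_{vap}(T) = S_{gas}(T) - S_{liq}(T)} per mole of monomer.
#' At or above the transition both branches are evaluated directly. Below
#' the transition the liquid entropy is taken from the stable branch and
#' the gas entropy from an ordinary least-squares line fitted to the
#' gas-branch \eqn{S(T)} over the first `window` kelvin above the
#' transition — the gas-phase entropy is very nearly linear in T there, so
#' the linear extrapolation is the natural estimate of the (hypothetical)
#' vapor entropy at lower temperatures.
#'
#' @param iso `qce_isobar` with a detected transition.
#' @param at_temperature evaluation temperature, K.
#' @param window extrapolation fit window above the transition, K
#'   (default 30; must contain at least 5 grid points).
#' @return \eqn{\Delta S_{vap}}, J mol^-1 K^-1.
#' @export
vaporization_entropy <- function(iso, at_temperature, window = 30) {
  if (!is.finite(iso$transition_temperature))
    stop("vaporization_entropy: isobar has no detected transition")
  Tt <- iso$transition_temperature
  Tg <- iso$table$temperature
  if (at_temperature >= Tt) {
    st <- lapply(c(liquid = "liquid", gas = "gas"), function(br) {
      seed <- if (br == "liquid") iso$state_below else iso$state_above
      s <- self_consistent_state(at_temperature, iso$params$pressure, iso$set,
                                 iso$params, init_state = seed)
      if (!s$converged) stop("branch solve failed at T = ", at_temperature)
      s
    })
    Sg <- thermo_point(st$gas, iso$set, iso$params, compute_cp = FALSE)$entropy
    Sl <- thermo_point(st$liquid, iso$set, iso$params, compute_cp = FALSE)$entropy
    return(Sg - Sl)
  }
  # gas-branch OLS window
  sel <- which(Tg > Tt & Tg <= Tt + window)
  if (length(sel) < 5L)
    stop("vaporization_entropy: extrapolation window holds fewer than 5 grid points")
  Sgas <- vapply(iso$states[sel], function(s)
    thermo_point(s, iso$set, iso$params, compute_cp = FALSE)$entropy, numeric(1))
  fit <- stats::lm(Sgas ~ Tg[sel])
  S_gas_ex <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * at_temperature)
  # stable (liquid) branch at the requested temperature
  k <- which.min(abs(Tg - at_temperature))
  s_liq <- self_consistent_state(at_temperature, iso$params$pressure, iso$set,
                                 iso$params, init_state = iso$states[[k]])
  if (!s_liq$converged) stop("liquid solve failed at T = ", at_temperature)
  S_liq <- thermo_point(s_liq, iso$set, iso$params, compute_cp = FALSE)$entropy
  S_gas_ex - S_liq
}

#' Isobar table with thermodynamic observables
#'
#' Extends the [isobar_scan()] table with per-temperature enthalpy,
#' entropy, internal energy (J/mol and J/mol/K, per mole of monomer) and
#' one monomer-normalized population column per cluster.
#'
#' @param iso `qce_isobar`.
#' @param populations include per-cluster population columns.
#' @return data.frame.
#' @export
isobar_table <- function(iso, populations = TRUE) {
  th <- .isobar_thermo(iso)
  tab <- iso$table
  tab$enthalpy <- th["H", ]
  tab$entropy <- th["S", ]
  tab$gibbs_molar <- th["G", ]
  if (populations) {
    pops <- vapply(iso$states, monomer_normalized_populations,
                   numeric(length(iso$set)))
    pops <- if (is.null(dim(pops))) matrix(pops, ncol = 1L) else t(pops)
    colnames(pops) <- paste0("x_", vapply(iso$set, `[[`, character(1), "label"))
    tab <- cbind(tab, pops)
  }
  tab
}
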