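# log(sum(exp(x))) without overflow; -Inf-safe
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve cluster populations by the law of mass action
#'
#' At fixed per-cluster partition functions, the chemical-equilibrium
#' condition (equal chemical potential per monomer) together with
#' Stirling's approximation gives the mass-action form
#' \deqn{\ln N_p = \ln q_p + i_p (\ln N_1 - \ln q_1),}
#' closed by the mass balance \eqn{\sum_p i_p N_p = N_A n_{tot}}. The
#' single unknown \eqn{\ln N_1} is found by Newton iteration on the
#' log-sum-exp form of the balance, which is smooth, convex and strictly
#' increasing, so convergence is monotone from the all-monomer start.
#' All arithmetic is in log space; populations spanning hundreds of orders
#' of magnitude are handled exactly as well as order-one ones.
#'
#' @param ln_q per-cluster log partition functions (per particle) at the
#'   working volume, as from [cluster_ln_q()].
#' @param sizes per-cluster monomer counts \eqn{i_p}.
#' @param monomer_amount total amount of monomers, mol.
#' @return list with `ln_n` (log amounts, mol) and `n` (amounts, mol;
#'   may underflow to 0 for extremely disfavored clusters while `ln_n`
#'   stays finite), named by cluster.
#' @export
solve_populations <- function(ln_q, sizes, monomer_amount) {
  stopifnot(length(ln_q) == length(sizes), monomer_amount > 0)
  if (any(!is.finite(ln_q))) stop("solve_populations: non-finite ln q")
  i <- as.numeric(sizes)
  k1 <- which(i == 1)[1L]
  if (is.na(k1)) stop("solve_populations: no monomer (size 1) present")
  target <- log(monomer_amount) + .lnNA
  sol <- .solve_pops(ln_q, i, log(i), k1, target)
  if (is.null(sol))
    stop("solve_populations: mass-balance iteration did not reach tolerance")
  ln_n <- sol$ln_n
  names(ln_n) <- names(ln_q)
  list(ln_n = ln_n, n = exp(ln_n))
}

.lnNA <- log(6.02214076e23)

# Newton iteration on the log-sum-exp mass balance; returns NULL on
# failure. `s` is an optional warm start for ln N_1 - ln q_1.
.solve_pops <- function(ln_q, i, log_i, k1, target, s = NULL) {
  a <- ln_q - i * ln_q[k1]          # ln N_p = a_p + i_p * s
  if (is.null(s)) s <- target - ln_q[k1]   # all-monomer start (above root)
  res <- Inf
  for (iter in 1:200) {
    la <- log_i + a + i * s
    m <- max(la)
    w <- exp(la - m)
    sw <- sum(w)
    res <- m + log(sw) - target
    if (abs(res) < 1e-14) break
    s <- s - res / (sum(i * w) / sw)
  }
  if (!is.finite(res) || abs(res) > 1e-10) return(NULL)
  list(ln_n = a + i * s - .lnNA, s = s)
}

#' Candidate phase volumes from the pressure constraint
#'
#' With Stirling's approximation, the volume dependence of \eqn{\ln Q} is
#' \eqn{N_c \ln(V - V_{excl})} (translation) plus
#' \eqn{a_{mf} n_{tot}^2 N_A / (R T V)} (mean field), so the pressure
#' condition \eqn{P = k_B T\, \partial \ln Q/\partial V} becomes
#' \deqn{P = \frac{R T n_c}{V - V_{excl}} - \frac{a_{mf} n_{tot}^2}{V^2},}
#' equivalently the cubic
#' \deqn{P V^3 - (P V_{excl} + R T n_c) V^2 + a_{mf} n_{tot}^2 V
#'   - a_{mf} n_{tot}^2 V_{excl} = 0.}
#' Roots are found with [base::polyroot()] and polished by Newton steps;
#' only real roots with \eqn{V > V_{excl}} are physical. Up to three may
#' exist (gas, liquid and an unstable middle root).
#'
#' @param pressure external pressure, Pa.
#' @param T temperature, K.
#' @param total_cluster_amount total amount of clusters \eqn{n_c}, mol.
#' @param monomer_amount total monomer amount \eqn{n_{tot}}, mol.
#' @param excluded_volume \eqn{V_{excl}}, m^3 (>= 0).
#' @param amf mean-field parameter, J m^3 mol^-2.
#' @return increasing numeric vector of admissible volumes (m^3), possibly
#'   empty.
#' @export
volume_candidates <- function(pressure, T, total_cluster_amount,
                              monomer_amount, excluded_volume, amf) {
  stopifnot(pressure > 0, T > 0, total_cluster_amount > 0,
            excluded_volume >= 0, amf >= 0)
  R <- qce_constants$R
  c3 <- pressure
  c2 <- -(pressure * excluded_volume + R * T * total_cluster_amount)
  c1 <- amf * monomer_amount^2
  c0 <- -amf * monomer_amount^2 * excluded_volume
  roots <- polyroot(c(c0, c1, c2, c3))
  re <- Re(roots); im <- Im(roots)
  real <- abs(im) <= 1e-8 * (abs(re) + 1e-300)
  v <- re[real]
  # Newton polish on the cubic for full double precision
  for (k in seq_along(v)) {
    for (it in 1:6) {
      p  <- ((c3 * v[k] + c2) * v[k] + c1) * v[k] + c0
      dp <- (3 * c3 * v[k] + 2 * c2) * v[k] + c1
      if (dp == 0) break
      step <- p / dp
      v[k] <- v[k] - step
      if (abs(step) <= 1e-16 * abs(v[k])) break
    }
  }
  v <- v[v > excluded_volume * (1 + 1e-12) & v > 0]
  sort(unique(v))
}

# system log partition function (Stirling form), populations in log-mol
.system_ln_Q <- function(base, params, T, V, lnn) {
  Vexcl <- .excluded_volume(base, params, lnn)
  lq <- .ln_q_full(base, params, T, V, Vexcl)
  t <- lnn + log(qce_constants$N_A)           # ln N_p
  sum(exp(t) * (lq - t + 1))
}

#' System log partition function
#'
#' \eqn{\ln Q = \sum_p [N_p \ln q_p - \ln N_p! ]} with Stirling's
#' approximation \eqn{\ln N! = N \ln N - N}. Exposed mainly so the
#' pressure constraint can be verified against numerical differentiation.
#'
#' @param set `qce_cluster_set`.
#' @param params `qce_parameters`.
#' @param T temperature, K.
#' @param V phase volume, m^3.
#' @param ln_n per-cluster log amounts, mol (the excluded volume is
#'   recomputed from these).
#' @return `ln Q` (dimensionless, extensive).
#' @export
system_ln_q <- function(set, params, T, V, ln_n) {
  base <- .ln_q_T_part(set, params, T)
  .system_ln_Q(base, params, T, V, ln_n)
}

.excluded_volume <- function(base, params, lnn) {
  params$bxv * qce_constants$N_A * sum(exp(lnn) * base$vol)
}

# the per-temperature base carries everything the solver needs
.solver_base <- function(set, params, T) .ln_q_T_part(set, params, T)

#' Solve one self-consistent QCE state
#'
#' Alternates [solve_populations()] at fixed volume with
#' [volume_candidates()] at fixed populations (choosing the root nearest
#' the current volume) until the relative change in the volume and in every
#' population falls below `tol`. Population updates are damped by
#' successive substitution (convex combination with factor 0.5, falling
#' back to 0.25 after a divergent step) because undamped substitution
#' oscillates near the binodal; the convex combination preserves the
#' monomer balance at every iterate.
#'
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param set `qce_cluster_set`.
#' @param params `qce_parameters`.
#' @param initial_branch `"gas"` (ideal-gas volume seed) or `"liquid"`
#'   (1.1 x bxv x total monomer eigenvolume packing seed).
#' @param init_state optional converged `qce_state` used as a warm start
#'   (overrides `initial_branch` seeding).
#' @param tol relative convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 500).
#' @return A `qce_state`: list with `temperature`, `pressure`, `volume`,
#'   `populations` (mol, named), `ln_populations`, `excluded_volume`,
#'   `ln_Q`, `gibbs_energy` (J), `converged`, `branch_tag`, `iterations`.
#' @export
self_consistent_state <- function(T, P, set, params,
                                  initial_branch = c("gas", "liquid"),
                                  init_state = NULL,
                                  tol = 1e-9, max_iter = 500L,
                                  base = NULL) {
  initial_branch <- if (length(initial_branch) > 1L) initial_branch[1L]
                    else match.arg(initial_branch)
  if (is.null(base)) base <- .solver_base(set, params, T)
  n_tot <- params$monomer_amount
  R <- qce_constants$R
  kNA <- qce_constants$N_A

  if (!is.null(init_state)) {
    V <- init_state$volume
    lnn <- unname(init_state$ln_populations)
    tag <- init_state$branch_tag
  } else if (initial_branch == "gas") {
    V <- n_tot * R * T / P
    lnn <- c(log(n_tot), rep(-745, length(set) - 1L))
    tag <- "gas"
  } else {
    V <- 1.1 * params$bxv * n_tot * kNA * set[[1L]]$volume
    lnn <- c(log(n_tot), rep(-745, length(set) - 1L))
    tag <- "liquid"
  }
  i <- base$i; log_i <- log(i)
  bvol <- params$bxv * kNA * base$vol
  cmf <- params$amf * i * n_tot / (R * T)   # mean-field term is cmf / V
  target <- log(n_tot) + .lnNA
  beta <- 0.5
  converged <- FALSE
  resid_prev <- Inf
  iter <- 0L
  s_warm <- NULL
  for (iter in seq_len(max_iter)) {
    en <- exp(lnn)
    Vexcl <- sum(en * bvol)
    if (V <= Vexcl) V <- Vexcl + 0.05 * max(Vexcl, 1e-300)
    # effective per-cluster ln q entering the equal-chemical-potential
    # condition: the last term is d(Vexcl)/dN_p carried through the
    # translational volume of all clusters (excluded-volume crowding), so
    # that mu_p = dA/dN_p exactly and G is variational at the fixed point
    n_c_cur <- sum(en)
    lq <- base$lq0 + log(V - Vexcl) + cmf / V -
      n_c_cur * bvol / (V - Vexcl)
    sol <- .solve_pops(lq, i, log_i, 1L, target, s_warm)
    if (is.null(sol)) break
    s_warm <- sol$s
    d_ln <- sol$ln_n - lnn
    # damped successive substitution as a convex combination in linear
    # population space (preserves the monomer balance exactly), computed
    # element-wise in log space to stay safe for minute populations
    m <- pmax(lnn, sol$ln_n)
    lnn_new <- m + log((1 - beta) * exp(lnn - m) + beta * exp(sol$ln_n - m))
    en_new <- exp(lnn_new)
    n_c <- sum(en_new)
    Vexcl_new <- sum(en_new * bvol)
    cand <- volume_candidates(P, T, n_c, n_tot, Vexcl_new, params$amf)
    if (length(cand) == 0L) break         # phase collapse
    V_new <- cand[which.min(abs(log(cand) - log(V)))]
    resid <- max(abs(d_ln), abs(V_new - V) / V)
    if (!is.finite(resid)) break
    if (resid > 4 * resid_prev) beta <- 0.25   # divergent step: damp harder
    chg <- max(abs(lnn_new - lnn), abs(V_new - V) / V)
    lnn <- lnn_new; V <- V_new
    resid_prev <- resid
    if (chg < tol) { converged <- TRUE; break }
  }
  names(lnn) <- base$labels
  Vexcl <- sum(exp(lnn) * bvol)
  lnQ <- if (V > Vexcl) .system_ln_Q(base, params, T, V, lnn) else NA_real_
  G <- -qce_constants$kB * T * lnQ + P * V
  structure(list(temperature = T, pressure = P, volume = V,
                 populations = exp(lnn), ln_populations = lnn,
                 excluded_volume = Vexcl, ln_Q = lnQ, gibbs_energy = G,
                 converged = converged, branch_tag = tag,
                 iterations = iter, sizes = base$i),
            class = "qce_state")
}

#' @export
print.qce_state <- function(x, ...) {
  cat(sprintf("QCE state: T = %.2f K, P = %.4g Pa, V = %.6g m^3 (%s, %s in %d it.)\n",
              x$temperature, x$pressure, x$volume, x$branch_tag,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Select the thermodynamically stable state
#'
#' Returns the converged state of minimal Gibbs energy
#' \eqn{G = -k_B T \ln Q + P V}. Ties (relative Gibbs difference below
#' 1e-9) are resolved toward the larger volume.
#'
#' @param states list of `qce_state` objects.
#' @return the stable `qce_state`.
#' @export
select_stable_state <- function(states) {
  conv <- Filter(function(s) isTRUE(s$converged) && is.finite(s$gibbs_energy),
                 states)
  if (length(conv) == 0L) stop("select_stable_state: no converged state")
  G <- vapply(conv, `[[`, numeric(1), "gibbs_energy")
  V <- vapply(conv, `[[`, numeric(1), "volume")
  gmin <- min(G)
  tie <- which(abs(G - gmin) <= 1e-9 * abs(gmin))
  conv[[tie[which.max(V[tie])]]]
}

# solve gas + liquid (+ optional warm) seeds and pick the stable one
.stable_at <- function(T, P, set, params, warm = NULL) {
  base <- .solver_base(set, params, T)
  states <- list()
  for (br in c("gas", "liquid")) {
    s <- tryCatch(self_consistent_state(T, P, set, params, initial_branch = br,
                                        base = base),
                  error = function(e) NULL)
    if (!is.null(s)) states[[length(states) + 1L]] <- s
  }
  if (!is.null(warm)) {
    s <- tryCatch(self_consistent_state(T, P, set, params, init_state = warm,
                                        base = base),
                  error = function(e) NULL)
    if (!is.null(s)) states[[length(states) + 1L]] <- s
  }
  if (length(states) == 0L || !any(vapply(states, `[[`, logical(1), "converged")))
    stop(sprintf("no branch converged at T = %.3f K, P = %.4g Pa", T, P))
  select_stable_state(states)
}

#' Scan an isobar and locate the vapor--liquid transition
#'
#' Solves the stable state at every temperature of the grid (warm-starting
#' each temperature from the previous stable state in addition to fresh
#' gas and liquid seeds), then locates the phase transition at the largest
#' relative volume jump between adjacent grid points exceeding
#' `jump_threshold`, refined by bisection on the temperature of the
#' branch switch to `refine_tol` kelvin. The transition temperature is
#' reported as the refined bracket midpoint; absence of a jump above the
#' threshold means no transition (not an error).
#'
#' @param set `qce_cluster_set`.
#' @param params `qce_parameters` (grid and pressure are taken from here).
#' @param jump_threshold minimal relative volume jump (default 0.5).
#' @param refine_tol bisection width on T, K (default 0.01).
#' @return A `qce_isobar`: list with `table` (data.frame of T, V, density
#'   etc.), `states` (stable state per grid point),
#'   `transition_temperature` (NA if none), `transition_index`,
#'   `state_below`/`state_above` (states bracketing the refined
#'   transition), and the `set`/`params` used.
#' @export
isobar_scan <- function(set, params, jump_threshold = 0.5, refine_tol = 0.01) {
  Tgrid <- params$temperature_grid
  P <- params$pressure
  states <- vector("list", length(Tgrid))
  warm <- NULL
  for (k in seq_along(Tgrid)) {
    states[[k]] <- .stable_at(Tgrid[k], P, set, params, warm = warm)
    warm <- states[[k]]
  }
  V <- vapply(states, `[[`, numeric(1), "volume")
  trs <- NA_real_; trs_idx <- NA_integer_
  s_below <- NULL; s_above <- NULL
  if (length(Tgrid) > 1L) {
    jump <- abs(diff(V)) / pmin(V[-1L], V[-length(V)])
    k <- which.max(jump)
    if (jump[k] > jump_threshold) {
      trs_idx <- k
      lo <- Tgrid[k]; hi <- Tgrid[k + 1L]
      s_lo <- states[[k]]; s_hi <- states[[k + 1L]]
      while (hi - lo > refine_tol) {
        Tm <- (lo + hi) / 2
        sm <- tryCatch(.stable_at(Tm, P, set, params, warm = s_lo),
                       error = function(e) NULL)
        if (is.null(sm)) break
        # which side of the jump does the midpoint sit on?
        if (abs(log(sm$volume) - log(s_lo$volume)) <
            abs(log(sm$volume) - log(s_hi$volume))) {
          lo <- Tm; s_lo <- sm
        } else {
          hi <- Tm; s_hi <- sm
        }
      }
      trs <- (lo + hi) / 2
      s_below <- s_lo; s_above <- s_hi
    }
  }
  mono_mass <- set[[1L]]$mass * qce_constants$N_A   # kg/mol
  tab <- data.frame(
    temperature = Tgrid,
    volume = V,
    density = params$monomer_amount * mono_mass / V,
    ln_Q = vapply(states, `[[`, numeric(1), "ln_Q"),
    gibbs_energy = vapply(states, `[[`, numeric(1), "gibbs_energy"),
    branch = vapply(states, `[[`, character(1), "branch_tag"),
    converged = vapply(states, `[[`, logical(1), "converged"))
  structure(list(table = tab, states = states,
                 transition_temperature = trs, transition_index = trs_idx,
                 state_below = s_below, state_above = s_above,
                 set = set, params = params),
            class = "qce_isobar")
}

#' @export
print.qce_isobar <- function(x, ...) {
  cat(sprintf("QCE isobar: %d temperatures (%.1f-%.1f K) at %.4g Pa\n",
              nrow(x$table), min(x$table$temperature), max(x$table$temperature),
              x$params$pressure))
  if (is.finite(x$transition_temperature))
    cat(sprintf("  phase transition at T = %.2f K\n", x$transition_temperature))
  else cat("  no phase transition detected\n")
  invisible(x)
}
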