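#' Optimization target for the QCE parameters
#'
#' The two empirical parameters `amf` and `bxv` are fitted so that the
#' computed density at a reference temperature and the computed
#' vapor--liquid transition temperature reproduce reference values
#' (typically experimental ones).
#'
#' @param reference_density target density, kg m^-3.
#' @param reference_temperature temperature of the density target, K
#'   (default 298.15, room temperature).
#' @param reference_transition target transition temperature, K.
#' @param weights two non-negative weights on the squared relative
#'   deviations (density, transition); at least one must be positive.
#' @return list of class `qce_target`.
#' @export
optimization_target <- function(reference_density,
                                reference_temperature = 298.15,
                                reference_transition,
                                weights = c(1, 1)) {
  stopifnot(reference_density > 0, reference_temperature > 0,
            reference_transition > 0, length(weights) == 2L,
            all(weights >= 0), any(weights > 0))
  structure(list(reference_density = reference_density,
                 reference_temperature = reference_temperature,
                 reference_transition = reference_transition,
                 weights = weights),
            class = "qce_target")
}

#' Objective function for the parameter fit
#'
#' Runs a full isobar scan at the trial `(amf, bxv)` and returns
#' \deqn{w_1 \left(\frac{\rho(T_{ref}) - \rho_{ref}}{\rho_{ref}}\right)^2 +
#'       w_2 \left(\frac{T_{trs} - T_{trs,ref}}{T_{trs,ref}}\right)^2.}
#' The density is evaluated by a direct stable-state solve at the
#' reference temperature. A missing transition or a failed scan
#' contributes a penalty of 1e6 instead of raising an error, so the
#' simplex can recover from infeasible vertices.
#'
#' @param amf,bxv trial parameters.
#' @param set `qce_cluster_set`.
#' @param run_params `qce_parameters` template (grid, pressure, amount,
#'   omega0); `amf`/`bxv` are overridden.
#' @param target `qce_target`.
#' @return non-negative objective value.
#' @export
qce_objective <- function(amf, bxv, set, run_params, target) {
  p <- run_params; p$amf <- amf; p$bxv <- bxv
  w <- target$weights
  obj <- 0
  res <- tryCatch({
    dens_term <- 0
    if (w[1] > 0) {
      st <- .stable_at(target$reference_temperature, p$pressure, set, p)
      rho <- mass_density(st, set)
      dens_term <- w[1] * ((rho - target$reference_density) /
                             target$reference_density)^2
    }
    trs_term <- 0
    if (w[2] > 0) {
      iso <- isobar_scan(set, p)
      trs_term <- if (is.finite(iso$transition_temperature))
        w[2] * ((iso$transition_temperature - target$reference_transition) /
                  target$reference_transition)^2
      else 1e6
    }
    dens_term + trs_term
  }, error = function(e) 1e6)
  obj + res
}

# scaled coordinates: comparable step sizes for heterogeneous units
.to_scaled <- function(x) c(x[1] / 2.0, (x[2] - 0.5) / 1.5)
.from_scaled <- function(u) c(2.0 * u[1], 0.5 + 1.5 * u[2])

#' Fit (amf, bxv) by the downhill simplex method
#'
#' Nelder--Mead with the textbook coefficients (reflection 1, expansion 2,
#' contraction 1/2, shrink 1/2) on scaled coordinates
#' `(amf/2, (bxv - 0.5)/1.5)`. Out-of-bounds vertices are evaluated at the
#' clamped point with an added squared-distance penalty, which keeps the
#' simplex inside the admissible box `amf in [0, 2]` J m^3 mol^-2,
#' `bxv in [0.5, 2]` without discontinuities. Converged when the simplex
#' diameter is below 1e-4 in scaled coordinates *and* the objective spread
#' is below 1e-10; the evaluation budget returns the best vertex so far,
#' flagged unconverged. Fully deterministic for identical inputs.
#'
#' @param set `qce_cluster_set`.
#' @param run_params `qce_parameters` template for the objective.
#' @param target `qce_target`.
#' @param initial starting `(amf, bxv)` (default `c(0.1, 1.0)`).
#' @param bounds list with `amf = c(lo, hi)` and `bxv = c(lo, hi)`
#'   (defaults `c(0, 2)` and `c(0.5, 2)`).
#' @param max_eval objective-evaluation budget (default 200).
#' @param step initial simplex edge in scaled coordinates (default 0.1).
#' @return list of class `qce_fit`: `amf`, `bxv`, `objective`,
#'   `n_evaluations`, `converged`, `trace` (data.frame of per-iteration
#'   vertices and objective values).
#' @export
optimize_parameters <- function(set, run_params, target,
                                initial = c(0.1, 1.0),
                                bounds = list(amf = c(0, 2), bxv = c(0.5, 2)),
                                max_eval = 200L, step = 0.1) {
  lo_s <- .to_scaled(c(bounds$amf[1], bounds$bxv[1]))
  hi_s <- .to_scaled(c(bounds$amf[2], bounds$bxv[2]))
  f <- function(x) qce_objective(x[1], x[2], set, run_params, target)
  nm <- .nelder_mead(f, .to_scaled(initial), lo_s, hi_s,
                     max_eval = max_eval, step = step,
                     label = .from_scaled)
  best <- .from_scaled(nm$u_best)
  structure(list(amf = best[1], bxv = best[2], objective = nm$f_best,
                 n_evaluations = nm$n_eval, converged = nm$converged,
                 trace = nm$trace),
            class = "qce_fit")
}

# Downhill simplex in scaled coordinates with box clamping. `f` is called
# on unscaled coordinates (via `label`); vertices outside [lo, hi] are
# evaluated at the clamped point plus a squared-distance penalty.
.nelder_mead <- function(f, u0, lo, hi, max_eval = 200L, step = 0.1,
                         diam_tol = 1e-4, spread_tol = 1e-10,
                         label = identity) {
  n_eval <- 0L
  fwrap <- function(u) {
    uc <- pmin(pmax(u, lo), hi)
    n_eval <<- n_eval + 1L
    f(label(uc)) + sum((u - uc)^2)
  }
  simplex <- rbind(u0, u0 + c(step, 0), u0 + c(0, step))
  fv <- apply(simplex, 1, fwrap)
  trace <- list()
  it <- 0L
  converged <- FALSE
  repeat {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    it <- it + 1L
    xb <- label(pmin(pmax(simplex[1, ], lo), hi))
    trace[[it]] <- data.frame(
      iteration = it, n_evaluations = n_eval,
      par1_best = xb[1], par2_best = xb[2],
      f_best = fv[1], f_worst = fv[3])
    diam <- max(stats::dist(simplex))
    if (diam < diam_tol && (fv[3] - fv[1]) < spread_tol) { converged <- TRUE; break }
    if (n_eval >= max_eval) break
    centroid <- colMeans(simplex[1:2, , drop = FALSE])
    xr <- centroid + (centroid - simplex[3, ])        # reflection (alpha 1)
    fr <- fwrap(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[3, ])  # expansion (gamma 2)
      fe <- if (n_eval < max_eval) fwrap(xe) else Inf
      if (fe < fr) { simplex[3, ] <- xe; fv[3] <- fe }
      else         { simplex[3, ] <- xr; fv[3] <- fr }
    } else if (fr < fv[2]) {
      simplex[3, ] <- xr; fv[3] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[3, ] - centroid)  # contraction (rho 1/2)
      fc <- if (n_eval < max_eval) fwrap(xc) else Inf
      if (fc < fv[3]) { simplex[3, ] <- xc; fv[3] <- fc }
      else {                                            # shrink (sigma 1/2)
        for (k in 2:3) {
          simplex[k, ] <- simplex[1, ] + 0.5 * (simplex[k, ] - simplex[1, ])
          fv[k] <- if (n_eval < max_eval) fwrap(simplex[k, ]) else Inf
        }
      }
    }
  }
  list(u_best = unname(pmin(pmax(simplex[1, ], lo), hi)), f_best = unname(fv[1]),
       n_eval = n_eval, converged = converged,
       trace = do.call(rbind, trace))
}

#' @export
print.qce_fit <- function(x, ...) {
  cat(sprintf("QCE parameter fit: amf = %.4f J m^3 mol^-2, bxv = %.4f\n",
              x$amf, x$bxv))
  cat(sprintf("  objective = %.3e after %d evaluations (%s)\n",
              x$objective, x$n_evaluations,
              if (x$converged) "converged" else "budget exhausted"))
  invisible(x)
}
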