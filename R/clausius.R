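#' Default pressure grid for a Clausius--Clapeyron analysis
#'
#' Geometric grid from 0.095898 bar to 4.7572 bar (9 intermediate points
#' plus the endpoints), in Pa.
#'
#' @return numeric vector of pressures, Pa.
#' @export
default_cc_pressures <- function() {
  exp(seq(log(0.095898 * .u_bar), log(4.7572 * .u_bar), length.out = 11))
}

#' Transition temperatures over a pressure grid
#'
#' Runs one isobar per pressure and collects the detected vapor--liquid
#' transition temperatures. Pressures whose isobar shows no volume jump
#' above the detection threshold are reported with `detected = FALSE` and
#' excluded from any subsequent fit.
#'
#' @param set `qce_cluster_set`.
#' @param params `qce_parameters` (temperature grid reused at every
#'   pressure; its `pressure` field is overridden).
#' @param pressures pressures to scan, Pa (default [default_cc_pressures()]).
#' @return data.frame with columns `pressure` (Pa), `transition` (K),
#'   `detected` (logical).
#' @export
transition_curve <- function(set, params, pressures = default_cc_pressures()) {
  stopifnot(length(pressures) >= 1L, all(pressures > 0))
  rows <- lapply(pressures, function(P) {
    p <- params; p$pressure <- P
    iso <- tryCatch(isobar_scan(set, p), error = function(e) NULL)
    trs <- if (is.null(iso)) NA_real_ else iso$transition_temperature
    data.frame(pressure = P, transition = trs, detected = is.finite(trs))
  })
  out <- do.call(rbind, rows)
  if (sum(out$detected) < 2L)
    stop("transition_curve: fewer than 2 pressures with a detectable transition")
  out
}

#' Vaporization enthalpy from the integrated Clausius--Clapeyron relation
#'
#' Ordinary least squares of \eqn{\ln(P/P^\circ)} on \eqn{1/T_{trs}}
#' (\eqn{P^\circ} = 1 bar). The integrated Clausius--Clapeyron relation
#' treats \eqn{\Delta H_{vap}} as temperature-independent over the fitted
#' range, so the slope is \eqn{-\Delta H_{vap}/R} and
#' \eqn{\Delta H_{vap} = -R \cdot slope}.
#'
#' @param pairs data.frame with columns `pressure` (Pa) and `transition`
#'   (K), e.g. from [transition_curve()]; rows with `detected == FALSE`
#'   are dropped if present.
#' @param P0 reference pressure for the logarithm, Pa (default 1 bar;
#'   changing it shifts the intercept by the log of the ratio and leaves
#'   the slope untouched).
#' @return list of class `qce_cc`: `pairs`, `slope` (K), `intercept`,
#'   `delta_H_vap` (kJ mol^-1), `fit_r_squared`.
#' @export
fit_vaporization_enthalpy <- function(pairs, P0 = 1e5) {
  stopifnot(is.data.frame(pairs), all(c("pressure", "transition") %in% names(pairs)))
  if ("detected" %in% names(pairs)) pairs <- pairs[pairs$detected, , drop = FALSE]
  pairs <- pairs[is.finite(pairs$transition), , drop = FALSE]
  if (nrow(pairs) < 2L)
    stop("fit_vaporization_enthalpy: need at least 2 (P, T) pairs")
  x <- 1 / pairs$transition
  if (max(x) - min(x) <= 0)
    stop("fit_vaporization_enthalpy: degenerate transition temperatures")
  y <- log(pairs$pressure / P0)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (nrow(pairs) > 2L)
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  else 1
  structure(list(pairs = pairs, slope = slope, intercept = intercept,
                 delta_H_vap = -qce_constants$R * slope / 1e3,
                 fit_r_squared = r2),
            class = "qce_cc")
}

#' @export
print.qce_cc <- function(x, ...) {
  cat(sprintf("Clausius-Clapeyron fit over %d pressures:\n", nrow(x$pairs)))
  cat(sprintf("  ln(P/1 bar) = %.4f %+.2f / T,  R^2 = %.6f\n",
              x$intercept, x$slope, x$fit_r_squared))
  cat(sprintf("  Delta H_vap = %.3f kJ/mol\n", x$delta_H_vap))
  invisible(x)
}
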