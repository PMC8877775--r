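#' Read a run-configuration file
#'
#' INI-style key--value file with sections:
#'
#' ```
#' [system]
#' amount 1.0          # total monomer amount, mol
#' pressure 1.01325    # bar
#' tmin 200            # K
#' tmax 560
#' tstep 5
#'
#' [qce]
#' amf 0.2             # J m^3 mol^-2
#' bxv 1.5
#' omega0 0            # cm^-1 rotor cutoff (0 = standard RRHO)
#'
#' [optimizer]
#' density 637.5       # target density, kg m^-3
#' density_temperature 298.15
#' transition 363.4    # target transition temperature, K
#' weight_density 1
#' weight_transition 1
#' max_evaluations 200
#' amf_start 0.1
#' bxv_start 1.0
#'
#' [jobs]
#' job isobar
#' ```
#'
#' `#` starts a comment; `key value` or `key = value` both work. Unknown
#' keys are rejected to catch typos early.
#'
#' @param path path to the configuration file.
#' @return list with `params` (a [qce_parameters()]), `optimizer`
#'   (list or NULL), `job` (character or NULL).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  known <- list(
    system = c("amount", "pressure", "tmin", "tmax", "tstep"),
    qce = c("amf", "bxv", "omega0"),
    optimizer = c("density", "density_temperature", "transition",
                  "weight_density", "weight_transition", "max_evaluations",
                  "amf_start", "bxv_start"),
    jobs = "job")
  sec <- NULL
  vals <- list()
  for (ln in lines) {
    h <- regmatches(ln, regexec("^\\[([a-z]+)\\]$", ln))[[1]]
    if (length(h) == 2L) {
      sec <- h[2]
      if (!sec %in% names(known)) stop("unknown config section [", sec, "]")
      next
    }
    if (is.null(sec)) stop("config: content before first section: '", ln, "'")
    toks <- strsplit(gsub("=", " ", ln, fixed = TRUE), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    key <- tolower(toks[1])
    if (!key %in% known[[sec]])
      stop("config: unknown key '", key, "' in section [", sec, "]")
    vals[[sec]][[key]] <- if (sec == "jobs") toks[2] else as.numeric(toks[2])
  }
  sv <- function(sec, key, default) {
    v <- vals[[sec]][[key]]
    if (is.null(v)) default else v
  }
  params <- qce_parameters(
    amf = sv("qce", "amf", 0),
    bxv = sv("qce", "bxv", 1),
    omega0 = sv("qce", "omega0", 0),
    monomer_amount = sv("system", "amount", 1),
    temperature_grid = seq(sv("system", "tmin", 200),
                           sv("system", "tmax", 560),
                           by = sv("system", "tstep", 5)),
    pressure = sv("system", "pressure", 1.01325) * .u_bar)
  list(params = params, optimizer = vals$optimizer, job = vals$jobs$job)
}

# atomic write: temp file in the target directory, then rename
.write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot move temporary file onto ", path)
  invisible(path)
}

.write_csv_atomic <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  .write_atomic(function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE), path)
}

.write_json_atomic <- function(x, path) {
  .write_atomic(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"), path)
}

#' Run a QCE job
#'
#' Dispatcher behind the command-line interface. Jobs:
#'
#' * `isobar` — temperature scan at one pressure; writes `isobar.csv`
#'   (T, V, density, lnQ, G, H, S, per-cluster populations) and
#'   `isobar_summary.json` (transition temperature, convergence counts).
#' * `pkw` — isobar plus the ionic product per temperature; writes
#'   `pkw.csv`.
#' * `cc` — transition curve over a pressure grid and the
#'   Clausius--Clapeyron fit; writes `cc.json` and `cc_fit.csv`.
#' * `optimize` — downhill-simplex fit of `(amf, bxv)`; writes
#'   `optimize.json` and `optimize_trace.csv`.
#' * `fixtures` — writes the built-in synthetic cluster-set descriptor
#'   files into the output directory.
#'
#' All outputs are written atomically (temporary file plus rename) with 12
#' significant digits, so repeated runs into clean directories are
#' byte-identical.
#'
#' @param job one of `"isobar"`, `"pkw"`, `"cc"`, `"optimize"`,
#'   `"fixtures"`.
#' @param clusters path to a cluster-set descriptor file (not needed for
#'   `fixtures`).
#' @param config path to a run-configuration file (optional; flags
#'   override).
#' @param out output directory (created if missing).
#' @param overrides named list overriding single parameters (`amf`, `bxv`,
#'   `omega0`, `pressure` in Pa, `tmin`, `tmax`, `tstep`, `amount`).
#' @param quiet suppress progress messages.
#' @return invisibly, 0 on success (errors are signalled as conditions).
#' @export
run_job <- function(job = c("isobar", "pkw", "cc", "optimize", "fixtures"),
                    clusters = NULL, config = NULL, out = ".",
                    overrides = list(), quiet = FALSE) {
  job <- match.arg(job)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  cfg <- if (!is.null(config)) read_run_config(config)
         else list(params = qce_parameters(), optimizer = NULL)
  params <- cfg$params
  grid_keys <- c(tmin = NA, tmax = NA, tstep = NA)
  for (k in names(overrides)) {
    v <- overrides[[k]]
    if (k %in% c("amf", "bxv", "omega0", "pressure")) params[[k]] <- v
    else if (k == "amount") params$monomer_amount <- v
    else if (k %in% names(grid_keys)) grid_keys[k] <- v
    else stop("unknown override '", k, "'")
  }
  if (any(!is.na(grid_keys))) {
    g <- params$temperature_grid
    lo <- if (!is.na(grid_keys["tmin"])) grid_keys[["tmin"]] else min(g)
    hi <- if (!is.na(grid_keys["tmax"])) grid_keys[["tmax"]] else max(g)
    by <- if (!is.na(grid_keys["tstep"])) grid_keys[["tstep"]]
          else if (length(g) > 1L) g[2] - g[1] else 1
    params$temperature_grid <- seq(lo, hi, by = by)
  }
  params <- do.call(qce_parameters, params)   # re-validate after overrides

  if (job == "fixtures") {
    write_cluster_set(make_monomer_only(), file.path(out, "monomer_only.qce"))
    write_cluster_set(make_monomer_dimer(), file.path(out, "monomer_dimer.qce"))
    write_cluster_set(make_pseudo_water(), file.path(out, "pseudo_water.qce"))
    say("wrote monomer_only.qce, monomer_dimer.qce, pseudo_water.qce to ", out)
    return(invisible(0L))
  }

  if (is.null(clusters)) stop("job '", job, "' needs --clusters")
  set <- read_cluster_set(clusters)

  if (job %in% c("isobar", "pkw")) {
    iso <- isobar_scan(set, params)
    tab <- isobar_table(iso)
    nonconv <- sum(!tab$converged)
    if (nonconv > 0)
      say(nonconv, " grid point(s) not converged (flagged in output)")
    if (job == "isobar") {
      .write_csv_atomic(tab, file.path(out, "isobar.csv"))
      .write_json_atomic(list(
        pressure_Pa = params$pressure,
        transition_temperature_K = if (is.finite(iso$transition_temperature))
          iso$transition_temperature else NA,
        n_temperatures = nrow(tab),
        n_unconverged = nonconv), file.path(out, "isobar_summary.json"))
      say("transition: ", format(iso$transition_temperature))
    } else {
      ion <- t(vapply(iso$states, function(s) {
        ipr <- ionic_product(s, set)
        c(c_ion = ipr$c_ion, Kw = ipr$Kw, pKw = ipr$pKw)
      }, numeric(3)))
      .write_csv_atomic(cbind(tab[, c("temperature", "volume", "density")],
                              as.data.frame(ion)),
                        file.path(out, "pkw.csv"))
    }
    return(invisible(0L))
  }

  if (job == "cc") {
    tc <- transition_curve(set, params)
    fit <- fit_vaporization_enthalpy(tc)
    .write_json_atomic(list(
      pairs = tc, slope_K = fit$slope, intercept = fit$intercept,
      delta_H_vap_kJ_mol = fit$delta_H_vap,
      fit_r_squared = fit$fit_r_squared), file.path(out, "cc.json"))
    line <- data.frame(inv_T = 1 / tc$transition[tc$detected])
    line$ln_P_fit <- fit$intercept + fit$slope * line$inv_T
    .write_csv_atomic(line, file.path(out, "cc_fit.csv"))
    say(sprintf("Delta H_vap = %.3f kJ/mol", fit$delta_H_vap))
    return(invisible(0L))
  }

  # optimize
  oc <- cfg$optimizer
  if (is.null(oc) || is.null(oc$density) || is.null(oc$transition))
    stop("optimize job needs [optimizer] section with 'density' and 'transition'")
  tgt <- optimization_target(
    reference_density = oc$density,
    reference_temperature = if (!is.null(oc$density_temperature))
      oc$density_temperature else 298.15,
    reference_transition = oc$transition,
    weights = c(if (!is.null(oc$weight_density)) oc$weight_density else 1,
                if (!is.null(oc$weight_transition)) oc$weight_transition else 1))
  fit <- optimize_parameters(
    set, params, tgt,
    initial = c(if (!is.null(oc$amf_start)) oc$amf_start else 0.1,
                if (!is.null(oc$bxv_start)) oc$bxv_start else 1.0),
    max_eval = if (!is.null(oc$max_evaluations)) oc$max_evaluations else 200L)
  .write_json_atomic(list(amf = fit$amf, bxv = fit$bxv,
                          objective = fit$objective,
                          n_evaluations = fit$n_evaluations,
                          converged = fit$converged),
                     file.path(out, "optimize.json"))
  .write_csv_atomic(fit$trace, file.path(out, "optimize_trace.csv"))
  say(sprintf("amf = %.4f, bxv = %.4f (%s)", fit$amf, fit$bxv,
              if (fit$converged) "converged" else "budget exhausted"))
  invisible(0L)
}
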