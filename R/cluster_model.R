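#' Construct a single cluster record
#'
#' A cluster record bundles the quantum-chemical descriptors of one cluster:
#' its composition (number of monomers), adiabatic electronic association
#' energy, harmonic wavenumbers, principal moments of inertia, volume, mass,
#' rotational symmetry number, and the number of separated ion pairs it
#' contains. All arguments are in SI units; the descriptor file format (see
#' [read_cluster_set()]) uses chemistry-friendly units and converts on read.
#'
#' @param label short unique identifier.
#' @param monomer_count number of monomers in the cluster (\eqn{i \ge 1}).
#' @param energy adiabatic electronic energy relative to `monomer_count`
#'   separated monomers, J per mole of cluster (association energy;
#'   negative for bound clusters, 0 for the monomer). Zero-point energy is
#'   *not* included here; it is carried by the vibrational partition
#'   function.
#' @param wavenumbers harmonic vibrational wavenumbers, cm^-1, all > 0
#'   (imaginary modes are rejected). May be empty for a monatomic species.
#' @param inertia principal moments of inertia, kg m^2: length 3 for a
#'   nonlinear species, length 1 with `linear = TRUE`, or `NULL` for a
#'   monatomic species.
#' @param linear logical; `TRUE` for a linear species (one distinct moment).
#' @param mean_inertia average moment of inertia used by the hindered-rotor
#'   partition function, kg m^2. Defaults to the arithmetic mean of
#'   `inertia`.
#' @param sigma rotational symmetry number (positive integer, default 1).
#' @param volume cluster volume, m^3 per cluster.
#' @param mass total cluster mass, kg per cluster.
#' @param ion_pairs non-negative integer count of separated ion pairs
#'   (0 for regular clusters).
#' @param natoms optional atom count; if supplied, the mode count is checked
#'   against 3*natoms - 6 (nonlinear) or 3*natoms - 5 (linear).
#' @return An object of class `qce_cluster`.
#' @export
cluster_record <- function(label, monomer_count, energy, wavenumbers = numeric(),
                           inertia = NULL, linear = FALSE, mean_inertia = NULL,
                           sigma = 1L, volume, mass, ion_pairs = 0L,
                           natoms = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  monomer_count <- as.integer(monomer_count)
  if (is.na(monomer_count) || monomer_count < 1L)
    stop("cluster '", label, "': monomer_count must be a positive integer")
  if (!is.finite(energy))
    stop("cluster '", label, "': energy must be finite")
  wavenumbers <- as.numeric(wavenumbers)
  if (any(!is.finite(wavenumbers)) || any(wavenumbers <= 0))
    stop("cluster '", label, "': all wavenumbers must be positive and finite",
         " (offending modes: ",
         paste(which(!(is.finite(wavenumbers) & wavenumbers > 0)), collapse = ", "),
         ")")
  if (!is.null(inertia)) {
    inertia <- as.numeric(inertia)
    nexp <- if (linear) 1L else 3L
    if (length(inertia) != nexp)
      stop("cluster '", label, "': expected ", nexp, " moment(s) of inertia, got ",
           length(inertia))
    if (any(!is.finite(inertia)) || any(inertia <= 0))
      stop("cluster '", label, "': moments of inertia must be positive")
  } else if (length(wavenumbers) > 0 && linear) {
    stop("cluster '", label, "': linear species needs one moment of inertia")
  }
  if (is.null(mean_inertia) && !is.null(inertia)) mean_inertia <- mean(inertia)
  if (!is.null(mean_inertia)) {
    mean_inertia <- as.numeric(mean_inertia)
    if (!is.finite(mean_inertia) || mean_inertia <= 0)
      stop("cluster '", label, "': mean_inertia must be positive")
  }
  sigma <- as.integer(sigma)
  if (is.na(sigma) || sigma < 1L)
    stop("cluster '", label, "': sigma must be a positive integer")
  if (!is.finite(volume) || volume <= 0)
    stop("cluster '", label, "': volume must be positive")
  if (!is.finite(mass) || mass <= 0)
    stop("cluster '", label, "': mass must be positive")
  ion_pairs <- as.integer(ion_pairs)
  if (is.na(ion_pairs) || ion_pairs < 0L)
    stop("cluster '", label, "': ion_pairs must be a non-negative integer")
  if (!is.null(natoms)) {
    natoms <- as.integer(natoms)
    nmodes_exp <- if (natoms == 1L) 0L else if (linear) 3L * natoms - 5L else 3L * natoms - 6L
    if (length(wavenumbers) != nmodes_exp)
      stop("cluster '", label, "': expected ", nmodes_exp, " modes for ",
           natoms, " atoms, got ", length(wavenumbers))
  }
  structure(
    list(label = label, monomer_count = monomer_count, energy = energy,
         wavenumbers = wavenumbers, inertia = inertia, linear = linear,
         mean_inertia = mean_inertia, sigma = sigma, volume = volume,
         mass = mass, ion_pairs = ion_pairs),
    class = "qce_cluster")
}

#' Construct and validate a cluster set
#'
#' A cluster set is the complete input to a QCE calculation: a list of
#' cluster records containing exactly one monomer (`monomer_count == 1`).
#' Energies are stored as association energies relative to separated
#' monomers; if the monomer record carries a nonzero (absolute) energy,
#' all energies are re-referenced at construction time
#' (`E_assoc = E - i * E_monomer`), which avoids the catastrophic
#' cancellation that absolute electronic energies would incur downstream.
#'
#' @param records list of [cluster_record()] objects.
#' @return An object of class `qce_cluster_set` (a validated list of
#'   records with the monomer first).
#' @export
cluster_set <- function(records) {
  if (inherits(records, "qce_cluster")) records <- list(records)
  stopifnot(is.list(records), length(records) >= 1L)
  ok <- vapply(records, inherits, logical(1), "qce_cluster")
  if (!all(ok)) stop("all elements must be cluster_record objects")
  labels <- vapply(records, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate cluster labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  sizes <- vapply(records, `[[`, integer(1), "monomer_count")
  imon <- which(sizes == 1L)
  if (length(imon) == 0L) stop("no monomer: cluster set must contain exactly one record with monomer_count = 1")
  if (length(imon) > 1L) stop("multiple monomers: ", paste(labels[imon], collapse = ", "))
  # re-reference energies to the monomer (association-energy convention)
  e_mon <- records[[imon]]$energy
  if (e_mon != 0) {
    records <- lapply(records, function(r) {
      r$energy <- r$energy - r$monomer_count * e_mon
      r
    })
  }
  # monomer first, then by size then label for a stable order
  ord <- order(sizes != 1L, sizes, labels)
  records <- records[ord]
  m_mass <- records[[1L]]$mass
  for (r in records[-1L]) {
    expected <- r$monomer_count * m_mass
    if (abs(r$mass - expected) > 1e-9 * expected)
      stop("cluster '", r$label, "': mass ", r$mass,
           " inconsistent with monomer_count * monomer mass (", expected, ")")
  }
  structure(records, class = "qce_cluster_set")
}

#' @export
print.qce_cluster_set <- function(x, ...) {
  cat("QCE cluster set:", length(x), "clusters\n")
  df <- as.data.frame(x)
  print(df[, c("label", "monomer_count", "energy_kJmol", "n_modes", "ion_pairs")])
  invisible(x)
}

#' @export
as.data.frame.qce_cluster_set <- function(x, ...) {
  data.frame(
    label = vapply(x, `[[`, character(1), "label"),
    monomer_count = vapply(x, `[[`, integer(1), "monomer_count"),
    energy_kJmol = vapply(x, `[[`, numeric(1), "energy") / .u_kJmol,
    n_modes = vapply(x, function(r) length(r$wavenumbers), integer(1)),
    sigma = vapply(x, `[[`, integer(1), "sigma"),
    volume_A3 = vapply(x, `[[`, numeric(1), "volume") / .u_A3,
    ion_pairs = vapply(x, `[[`, integer(1), "ion_pairs"),
    stringsAsFactors = FALSE)
}

#' QCE run parameters
#'
#' @param amf mean-field parameter, J m^3 mol^-2 (attractive intercluster
#'   energy scales as `-amf * i * rho` with `rho` the monomer density).
#'   Must be >= 0.
#' @param bxv excluded-volume scaling (dimensionless, > 0); the accessible
#'   translational volume is `V - bxv * sum(N_p * v_p)`.
#' @param omega0 hindered-rotor cutoff wavenumber, cm^-1; 0 disables the
#'   mRRHO treatment (pure rigid-rotor--harmonic-oscillator).
#' @param monomer_amount total amount of monomers, mol (> 0).
#' @param temperature_grid strictly increasing temperatures, K.
#' @param pressure external pressure, Pa.
#' @return An object of class `qce_parameters`. The special case
#'   `amf = 0, bxv = 1` is the parameter-free cluster-gas model (QCE(0)).
#' @export
qce_parameters <- function(amf = 0, bxv = 1, omega0 = 0,
                           monomer_amount = 1,
                           temperature_grid = seq(200, 500, by = 1),
                           pressure = 1e5) {
  stopifnot(is.finite(amf), amf >= 0,
            is.finite(bxv), bxv > 0,
            is.finite(omega0), omega0 >= 0,
            is.finite(monomer_amount), monomer_amount > 0,
            is.finite(pressure), pressure > 0)
  temperature_grid <- as.numeric(temperature_grid)
  if (length(temperature_grid) < 1L || any(!is.finite(temperature_grid)) ||
      any(temperature_grid <= 0) ||
      (length(temperature_grid) > 1L && any(diff(temperature_grid) <= 0)))
    stop("temperature_grid must be positive and strictly increasing")
  structure(list(amf = amf, bxv = bxv, omega0 = omega0,
                 monomer_amount = monomer_amount,
                 temperature_grid = temperature_grid,
                 pressure = pressure),
            class = "qce_parameters")
}

# ---- descriptor file I/O ---------------------------------------------------

.cluster_keys <- c("composition", "energy", "frequencies", "inertia",
                   "mean_inertia", "linear", "sigma", "volume", "mass",
                   "ion_pairs", "natoms")

#' Read a cluster-set descriptor file
#'
#' The descriptor format is UTF-8 text with one block per cluster,
#' introduced by `[cluster <label>]`. Recognized keys (values separated by
#' whitespace, optionally after `=`):
#'
#' * `composition` — monomer count (integer, required)
#' * `energy` — adiabatic electronic energy, kJ per mole of cluster
#'   (association energy with monomer = 0, or absolute; re-referenced on
#'   load)
#' * `frequencies` — harmonic wavenumbers in cm^-1; may span several lines
#' * `inertia` — three principal moments in amu Angstrom^2 (one with
#'   `linear 1`)
#' * `mean_inertia` — optional override, amu Angstrom^2 (default:
#'   arithmetic mean of `inertia`)
#' * `sigma` — rotational symmetry number (default 1)
#' * `volume` — cluster volume in Angstrom^3 (required)
#' * `mass` — cluster mass in amu (required for the monomer; defaults to
#'   `composition` times the monomer mass elsewhere)
#' * `ion_pairs` — separated ion pairs in the cluster (default 0)
#' * `natoms` — optional atom count for a mode-count consistency check
#'
#' Lines starting with `#` and blank lines are ignored. Values are
#' converted to SI on load and all [cluster_set()] invariants are checked.
#'
#' @param path path to the descriptor file.
#' @return A validated `qce_cluster_set`.
#' @export
read_cluster_set <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  blocks <- list()
  cur_label <- NULL; cur <- NULL; cur_key <- NULL
  flush <- function() {
    if (!is.null(cur_label)) blocks[[length(blocks) + 1L]] <<- list(label = cur_label, kv = cur)
  }
  for (ln in lines) {
    hdr <- regmatches(ln, regexec("^\\[cluster[ \t]+([^]]+)\\]$", ln))[[1]]
    if (length(hdr) == 2L) {
      flush()
      cur_label <- trimws(hdr[2]); cur <- list(); cur_key <- NULL
      next
    }
    if (is.null(cur_label))
      stop("parse error: content before first [cluster ...] block: '", ln, "'")
    toks <- strsplit(gsub("=", " ", ln, fixed = TRUE), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (tolower(toks[1]) %in% .cluster_keys) {
      cur_key <- tolower(toks[1])
      cur[[cur_key]] <- c(cur[[cur_key]], toks[-1])
    } else if (!is.null(cur_key)) {
      cur[[cur_key]] <- c(cur[[cur_key]], toks)  # continuation line
    } else {
      stop("parse error in [cluster ", cur_label, "]: unrecognized key '",
           toks[1], "'")
    }
  }
  flush()
  if (length(blocks) == 0L) stop("no [cluster ...] blocks found in ", path)

  num <- function(kv, key, label, n = NULL, required = TRUE, default = NULL) {
    v <- kv[[key]]
    if (is.null(v)) {
      if (required) stop("cluster '", label, "': missing mandatory field '", key, "'")
      return(default)
    }
    x <- suppressWarnings(as.numeric(v))
    if (any(is.na(x)))
      stop("cluster '", label, "': non-numeric value for '", key, "'")
    if (!is.null(n) && length(x) != n)
      stop("cluster '", label, "': '", key, "' expects ", n, " value(s), got ", length(x))
    x
  }

  # first pass: find monomer mass
  records0 <- lapply(blocks, function(b) {
    kv <- b$kv; label <- b$label
    list(label = label, kv = kv,
         composition = as.integer(num(kv, "composition", label, n = 1L)),
         mass = num(kv, "mass", label, n = 1L, required = FALSE))
  })
  comp <- vapply(records0, `[[`, integer(1), "composition")
  imon <- which(comp == 1L)
  if (length(imon) != 1L)
    stop(if (length(imon) == 0L) "no monomer: " else "multiple monomers: ",
         "descriptor file must contain exactly one block with composition = 1")
  m_mass_amu <- records0[[imon]]$mass
  if (is.null(m_mass_amu))
    stop("cluster '", records0[[imon]]$label, "': monomer block must carry 'mass' (amu)")

  records <- lapply(records0, function(r0) {
    kv <- r0$kv; label <- r0$label
    linear <- !is.null(kv$linear) && num(kv, "linear", label, n = 1L) != 0
    inertia <- num(kv, "inertia", label, required = FALSE)
    mass_amu <- if (is.null(r0$mass)) r0$composition * m_mass_amu else r0$mass
    mi <- num(kv, "mean_inertia", label, n = 1L, required = FALSE)
    cluster_record(
      label = label,
      monomer_count = r0$composition,
      energy = num(kv, "energy", label, n = 1L) * .u_kJmol,
      wavenumbers = num(kv, "frequencies", label, required = FALSE, default = numeric()),
      inertia = if (!is.null(inertia)) inertia * .u_amuA2,
      linear = linear,
      mean_inertia = if (!is.null(mi)) mi * .u_amuA2,
      sigma = num(kv, "sigma", label, n = 1L, required = FALSE, default = 1),
      volume = num(kv, "volume", label, n = 1L) * .u_A3,
      mass = mass_amu * qce_constants$amu,
      ion_pairs = num(kv, "ion_pairs", label, n = 1L, required = FALSE, default = 0),
      natoms = num(kv, "natoms", label, n = 1L, required = FALSE))
  })
  cluster_set(records)
}

#' Write a cluster-set descriptor file
#'
#' Inverse of [read_cluster_set()]: writes a descriptor file that reads
#' back identically (all fields to 12 significant digits). Refuses to
#' write sets containing non-finite values.
#'
#' @param set a `qce_cluster_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cluster_set <- function(set, path) {
  stopifnot(inherits(set, "qce_cluster_set"))
  fmt <- function(x) sprintf("%.12g", x)
  out <- character()
  for (r in set) {
    vals <- c(r$energy, r$wavenumbers, r$volume, r$mass,
              if (!is.null(r$inertia)) r$inertia,
              if (!is.null(r$mean_inertia)) r$mean_inertia)
    if (any(!is.finite(vals)))
      stop("cluster '", r$label, "': non-finite value; refusing to write")
    out <- c(out, sprintf("[cluster %s]", r$label),
             paste("composition", r$monomer_count),
             paste("energy", fmt(r$energy / .u_kJmol)))
    if (length(r$wavenumbers) > 0) {
      wlines <- tapply(fmt(r$wavenumbers),
                       (seq_along(r$wavenumbers) - 1L) %/% 8L,
                       paste, collapse = " ")
      out <- c(out, paste("frequencies", wlines[1]),
               if (length(wlines) > 1L) paste(" ", wlines[-1]))
    }
    if (!is.null(r$inertia))
      out <- c(out, paste("inertia", paste(fmt(r$inertia / .u_amuA2), collapse = " ")))
    if (r$linear) out <- c(out, "linear 1")
    if (!is.null(r$mean_inertia))
      out <- c(out, paste("mean_inertia", fmt(r$mean_inertia / .u_amuA2)))
    out <- c(out,
             paste("sigma", r$sigma),
             paste("volume", fmt(r$volume / .u_A3)),
             paste("mass", fmt(r$mass / qce_constants$amu)),
             paste("ion_pairs", r$ion_pairs),
             "")
  }
  con <- try(file(path, open = "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open '", path, "' for writing")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
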