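#' @useDynLib idplink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef kmeans lm mad median nls.control pgamma
#'   predict quantile rnorm sd setNames t.test vcov
#' @importFrom utils read.csv write.csv packageVersion
NULL

# ---------------------------------------------------------------------------
# Domain types. Every downstream module consumes only these in-memory
# containers; on-disk formats stop at this file. All q values are held in
# nm^-1 internally (Angstrom^-1 input is converted on load, factor 10).
# ---------------------------------------------------------------------------

#' One reduced 1D SAXS profile
#'
#' @param q momentum transfer, nm^-1; finite, non-negative, strictly
#'   increasing.
#' @param intensity scattered intensity, arbitrary units; same length as `q`.
#' @param sigma optional intensity standard errors (strictly positive, same
#'   length); `NULL` when the reduction did not propagate errors, in which
#'   case downstream fits fall back to unweighted least squares.
#' @param label free-text label carried through reports.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) == 0L) stop("empty profile")
  if (!all(is.finite(q))) stop("q values must be finite")
  if (any(q < 0)) stop("q values must be non-negative")
  if (any(diff(q) <= 0)) stop("q values must be strictly increasing")
  if (length(intensity) != length(q))
    stop("intensity length (", length(intensity),
         ") does not match q length (", length(q), ")")
  if (!all(is.finite(intensity))) stop("intensity values must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length does not match q")
    if (!all(is.finite(sigma)) || any(sigma <= 0))
      stop("sigma values must be finite and strictly positive")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label)[1]),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %s: %d points, q in [%.4g, %.4g] nm^-1, %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "no sigma" else "with sigma"))
  invisible(x)
}

#' Time-ordered SAXS frame series (batch repeats or SEC-SAXS elution)
#'
#' @param frames list of [saxs_profile()] objects sharing one q grid
#'   (relative tolerance 1e-9).
#' @param times frame acquisition times, s, strictly increasing. Defaults to
#'   `0, 1, 2, ...`.
#' @param uv optional data frame with columns `time` (s) and `a280` (AU),
#'   the in-line UV-absorbance trace of a SEC-SAXS run.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, times = NULL, uv = NULL) {
  if (!is.list(frames) || length(frames) == 0L) stop("frames must be a non-empty list")
  if (!all(vapply(frames, inherits, logical(1), "saxs_profile")))
    stop("every frame must be a saxs_profile")
  q0 <- frames[[1]]$q
  for (i in seq_along(frames)) {
    qi <- frames[[i]]$q
    if (length(qi) != length(q0) ||
        any(abs(qi - q0) > 1e-9 * pmax(abs(q0), 1)))
      stop("frame ", i, " is not on the common q grid")
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  times <- as.numeric(times)
  if (length(times) != length(frames)) stop("times length must match frames")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(uv)) {
    uv <- as.data.frame(uv)
    names(uv)[1:2] <- c("time", "a280")
    if (any(uv$time < min(times)) || any(uv$time > max(times)))
      warning("UV trace extends outside the frame time span")
  }
  structure(list(frames = frames, times = times, uv = uv),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames, %d q-points, %s UV trace\n",
              length(x$frames), length(x$frames[[1]]$q),
              if (is.null(x$uv)) "no" else "with"))
  invisible(x)
}

#' One well's kinetic trace (ThT fluorescence or turbidity vs time)
#'
#' @param time hours, strictly increasing, at least 4 points.
#' @param signal fluorescence/absorbance, arbitrary units, finite.
#' @param condition condition label (mutant, inducer, ...).
#' @param replicate integer replicate id within the condition.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, signal, condition = "", replicate = 1L) {
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) < 4L) stop("a kinetic trace needs at least 4 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (length(signal) != length(time)) stop("signal length must match time")
  if (!all(is.finite(signal))) stop("signal must be finite")
  structure(list(time = time, signal = signal,
                 condition = as.character(condition)[1],
                 replicate = as.integer(replicate)[1]),
            class = "kinetic_trace")
}

#' Endpoint turbidity plate (absorbance at 500 nm vs protein concentration)
#'
#' @param concentration_uM protein concentration per well, uM, non-negative.
#' @param replicate replicate id per well.
#' @param absorbance absorbance at 500 nm, AU.
#' @return An object of class `plate_data` (a validated data frame).
#' @export
plate_data <- function(concentration_uM, replicate, absorbance) {
  d <- data.frame(concentration_uM = as.numeric(concentration_uM),
                  replicate = as.integer(replicate),
                  absorbance = as.numeric(absorbance))
  if (any(d$concentration_uM < 0)) stop("concentrations must be non-negative")
  if (!all(is.finite(d$absorbance))) stop("absorbances must be finite")
  class(d) <- c("plate_data", class(d))
  d
}

#' Drift-tube instrument constants
#'
#' Defaults are the geometry and operating point of a helium drift tube:
#' length 78.1 cm, 297 K, 3.89 Torr.
#'
#' @param drift_length_cm drift-tube length L, cm.
#' @param temperature_K drift-gas temperature T, K.
#' @param pressure_Torr drift-gas pressure p, Torr.
#' @param charge ion charge state z (positive integer).
#' @param ion_mass_da ion mass, Da.
#' @param buffer_gas_mass_da buffer-gas mass, Da (default helium).
#' @return A list of class `ims_instrument`.
#' @export
ims_instrument <- function(drift_length_cm = 78.1, temperature_K = 297,
                           pressure_Torr = 3.89, charge = 1L,
                           ion_mass_da = NA_real_,
                           buffer_gas_mass_da = 4.002602) {
  stopifnot(drift_length_cm > 0, temperature_K > 0, pressure_Torr > 0,
            charge >= 1)
  structure(list(drift_length_cm = drift_length_cm,
                 temperature_K = temperature_K,
                 pressure_Torr = pressure_Torr,
                 charge = as.integer(charge),
                 ion_mass_da = ion_mass_da,
                 buffer_gas_mass_da = buffer_gas_mass_da),
            class = "ims_instrument")
}

#' Step-field ion-mobility data: arrival-time distributions by drift voltage
#'
#' @param records list; each element a list with `delta_v` (drift voltage
#'   difference, V), `arrival_times` (tA grid, ms, positive) and `counts`
#'   (intensity per tA bin).
#' @param instrument an [ims_instrument()].
#' @param min_voltages smallest number of distinct voltages accepted; the
#'   step-field protocol uses five, simple two-point regression needs two.
#' @return An object of class `step_field_data`.
#' @export
step_field_data <- function(records, instrument, min_voltages = 2L) {
  if (!is.list(records) || length(records) < min_voltages)
    stop("need at least ", min_voltages, " voltage records")
  dv <- vapply(records, function(r) as.numeric(r$delta_v), numeric(1))
  if (anyDuplicated(dv)) stop("drift voltages must be distinct")
  for (r in records) {
    if (any(r$arrival_times <= 0)) stop("arrival times must be positive")
    if (length(r$arrival_times) != length(r$counts))
      stop("arrival_times and counts lengths differ")
  }
  if (!inherits(instrument, "ims_instrument"))
    stop("instrument must be an ims_instrument")
  structure(list(records = records[order(dv)], instrument = instrument),
            class = "step_field_data")
}

#' Analysis configuration
#'
#' One bag of tunables shared by the pipeline stages. Defaults follow the
#' tau187 study conditions: molar extinction coefficient 2800 M^-1 cm^-1,
#' molecular weight 20570 Da.
#'
#' @param q_unit unit of q in input files, `"nm^-1"` or `"A^-1"` (converted
#'   to nm^-1 on load).
#' @param guinier_qmin,guinier_qmax Guinier fitting-region bounds, nm^-1;
#'   `NA` means use the default low-q region (lowest 40 points).
#' @param n_bins histogram bin count for the Guinier-window histogram.
#' @param outlier_threshold frame-rejection threshold in sd units of the
#'   chi-squared distance distribution.
#' @param guinier_limit largest admissible qmax*Rg for a Guinier window
#'   (`NA` disables the filter).
#' @param min_window smallest Guinier window length, points.
#' @param epsilon molar extinction coefficient at 280 nm, M^-1 cm^-1.
#' @param mw_da protein molecular weight, Da.
#' @param uv_path_cm UV flow-cell path length, cm.
#' @param bead_spacing_nm lattice-unit to nm conversion for chain ensembles
#'   (default 0.38 nm, the Calpha-Calpha distance).
#' @param seed base random seed for stochastic stages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(q_unit = c("nm^-1", "A^-1"),
                            guinier_qmin = NA_real_, guinier_qmax = NA_real_,
                            n_bins = 50L, outlier_threshold = 2,
                            guinier_limit = 1.3, min_window = 6L,
                            epsilon = 2800, mw_da = 20570, uv_path_cm = 1,
                            bead_spacing_nm = 0.38, seed = 1L) {
  q_unit <- match.arg(q_unit)
  stopifnot(n_bins >= 1, outlier_threshold > 0, min_window >= 3,
            epsilon > 0, mw_da > 0, uv_path_cm > 0, bead_spacing_nm > 0)
  if (!is.na(guinier_limit)) stopifnot(guinier_limit > 0)
  structure(list(q_unit = q_unit, guinier_qmin = guinier_qmin,
                 guinier_qmax = guinier_qmax, n_bins = as.integer(n_bins),
                 outlier_threshold = outlier_threshold,
                 guinier_limit = guinier_limit,
                 min_window = as.integer(min_window), epsilon = epsilon,
                 mw_da = mw_da, uv_path_cm = uv_path_cm,
                 bead_spacing_nm = bead_spacing_nm, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail loudly before any computation.
#'
#' @param path YAML file whose keys mirror the [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

# ---------------------------------------------------------------------------
# Readers
# ---------------------------------------------------------------------------

#' Read a reduced 1D SAXS profile (.dat convention)
#'
#' Whitespace- or comma-delimited text with columns q, I(q) and optionally
#' sigma(q); lines starting with `#` are comments. Rows containing
#' non-finite values are dropped (count reported via a message).
#'
#' @param path file path.
#' @param q_unit `"nm^-1"` (default) or `"A^-1"`; Angstrom^-1 input is
#'   multiplied by 10 on load so the in-memory q is always nm^-1.
#' @param label profile label; defaults to the file name.
#' @return A [saxs_profile()].
#' @export
read_saxs_profile <- function(path, q_unit = c("nm^-1", "A^-1"),
                              label = basename(path)) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[[:space:],]+")[[1]]
    if (!(length(fields) %in% c(2L, 3L)))
      stop("line ", i, ": expected 2 or 3 columns, got ", length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    # a field may be NA only if it literally spells a missing/non-finite value
    bad <- is.na(vals) & !grepl("^(?i)(na|nan|[-+]?inf)$", fields, perl = TRUE)
    if (any(bad))
      stop("line ", i, ": malformed numeric field '", fields[bad][1], "'")
    vals
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("inconsistent column counts in ", path)
  m <- do.call(rbind, rows)
  keep <- apply(is.finite(m), 1L, all)
  if (any(!keep))
    message("read_saxs_profile: dropped ", sum(!keep),
            " row(s) with non-finite values")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no finite data rows in ", path)
  q <- m[, 1]
  if (q_unit == "A^-1") q <- q * 10
  saxs_profile(q, m[, 2],
               sigma = if (ncol(m) == 3L) m[, 3] else NULL,
               label = label)
}

#' Read a SAXS frame series
#'
#' Two layouts are accepted. A wide CSV: first column q, one intensity
#' column per frame (column order = acquisition order). Or a manifest CSV
#' with columns `file` (per-frame .dat path, relative to the manifest) and
#' optionally `time` (s); manifest row numbers are 1-based.
#'
#' @param frames_path wide CSV or manifest CSV.
#' @param uv_path optional 2-column CSV (time s, A280 AU).
#' @param q_unit q unit of the frame files (see [read_saxs_profile()]).
#' @param times optional frame times overriding the defaults.
#' @return A [frame_series()].
#' @export
read_frame_series <- function(frames_path, uv_path = NULL,
                              q_unit = c("nm^-1", "A^-1"), times = NULL) {
  q_unit <- match.arg(q_unit)
  head1 <- readLines(frames_path, n = 1L)
  is_manifest <- grepl("file", head1, ignore.case = TRUE)
  if (is_manifest) {
    man <- read.csv(frames_path, stringsAsFactors = FALSE)
    paths <- file.path(dirname(frames_path), man$file)
    frames <- lapply(paths, read_saxs_profile, q_unit = q_unit)
    if (is.null(times) && "time" %in% names(man)) times <- man$time
  } else {
    d <- read.csv(frames_path, check.names = FALSE)
    if (ncol(d) < 2L) stop("wide frame CSV needs a q column plus frames")
    q <- d[[1]]
    if (q_unit == "A^-1") q <- q * 10
    frames <- lapply(seq_len(ncol(d) - 1L), function(j)
      saxs_profile(q, d[[j + 1L]], label = names(d)[j + 1L]))
  }
  uv <- NULL
  if (!is.null(uv_path)) {
    u <- read.csv(uv_path)
    uv <- data.frame(time = as.numeric(u[[1]]), a280 = as.numeric(u[[2]]))
  }
  frame_series(frames, times = times, uv = uv)
}

#' Read a long-format kinetic plate CSV into kinetic traces
#'
#' Expected columns: `condition`, `replicate`, `time_h`, `signal`.
#'
#' @param path CSV path.
#' @return A list of [kinetic_trace()] objects, one per (condition,
#'   replicate) pair.
#' @export
read_kinetic_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "time_h", "signal")
  if (!all(need %in% names(d)))
    stop("kinetic CSV must have columns ", paste(need, collapse = ", "))
  sp <- split(d, interaction(d$condition, d$replicate, drop = TRUE))
  unname(lapply(sp, function(g) {
    g <- g[order(g$time_h), ]
    kinetic_trace(g$time_h, g$signal, condition = g$condition[1],
                  replicate = g$replicate[1])
  }))
}

#' Read an endpoint turbidity plate CSV
#'
#' Expected columns: `concentration_uM`, `replicate`, `absorbance`.
#'
#' @param path CSV path.
#' @return A [plate_data()].
#' @export
read_plate_csv <- function(path) {
  d <- read.csv(path)
  need <- c("concentration_uM", "replicate", "absorbance")
  if (!all(need %in% names(d)))
    stop("plate CSV must have columns ", paste(need, collapse = ", "))
  plate_data(d$concentration_uM, d$replicate, d$absorbance)
}

#' Read step-field ion-mobility CSV
#'
#' Expected columns: `delta_v`, `t_a_ms`, `intensity` (long format, one row
#' per arrival-time bin).
#'
#' @param path CSV path.
#' @param instrument an [ims_instrument()].
#' @return A [step_field_data()].
#' @export
read_stepfield_csv <- function(path, instrument) {
  d <- read.csv(path)
  need <- c("delta_v", "t_a_ms", "intensity")
  if (!all(need %in% names(d)))
    stop("step-field CSV must have columns ", paste(need, collapse = ", "))
  recs <- lapply(split(d, d$delta_v), function(g) {
    g <- g[order(g$t_a_ms), ]
    list(delta_v = g$delta_v[1], arrival_times = g$t_a_ms,
         counts = g$intensity)
  })
  step_field_data(unname(recs), instrument)
}

# ---------------------------------------------------------------------------
# Result records: flat JSON, exact numeric round-trip
# ---------------------------------------------------------------------------

#' Write any fit-result record to JSON
#'
#' Numbers are written at full precision (`digits = NA`) so a read-back
#' reproduces every finite double bit-exactly. The package version is
#' stamped into the record.
#'
#' @param result a result object (any of the fit-result classes, or a plain
#'   named list).
#' @param path output path; the directory must exist.
#' @return Invisibly, the path.
#' @export
write_result <- function(result, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  payload <- unclass(result)
  payload$.class <- class(result)[1]
  payload$.software_version <- as.character(packageVersion("idplink"))
  # digits = I(17): 17 significant digits round-trip any finite double
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a result record written by [write_result()]
#'
#' @param path JSON path.
#' @return The result object with its original class restored.
#' @export
read_result <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  structure(payload, class = cls)
}
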