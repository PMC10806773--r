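# End-to-end composition of the stages over an input directory laid out in
# the package's on-disk conventions. Stages whose inputs are absent are
# skipped with a logged reason; a manifest records the configuration,
# input hashes, seed and what ran.

stage_seed <- function(base_seed, stage) {
  # stable per-stage seed: base + a small hash of the stage name, kept
  # inside 32-bit integer range
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(base_seed) * 1009 + h) %% 2147483647)
}

#' Run the full analysis pipeline over a directory
#'
#' Expected layout under `input_dir` (all optional except `batch/`):
#' \describe{
#'   \item{`batch/<condition>.dat`}{reduced, buffer-subtracted batch SAXS
#'     profiles; each gets a Guinier Rg and a Flory-exponent fit}
#'   \item{`secsaxs/frames.csv` + `secsaxs/uv.csv`}{SEC-SAXS wide frame
#'     CSV and UV trace; yields the second virial coefficient}
#'   \item{`tht.csv`}{long-format kinetic plate; yields halftimes}
#'   \item{`plate.csv`}{endpoint turbidity plate; yields Csat}
#'   \item{`ims/<condition>.csv`}{step-field ion-mobility data; yields CCS
#'     (requires `ims/<condition>.yaml` instrument sidecars, or the
#'     defaults are used with `ion_mass_da = config$mw_da`)}
#' }
#' When at least three conditions end up with both an Rg and a halftime,
#' the cross-condition regression and elbow check run too.
#'
#' @param config an [analysis_config()].
#' @param input_dir input directory.
#' @param output_dir output directory (created if missing); one JSON per
#'   result plus `manifest.json`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, input_dir, output_dir) {
  if (!inherits(config, "analysis_config")) stop("config must be an analysis_config")
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  ran <- character(0); skipped <- list()
  summary_rows <- list()

  batch <- sort(Sys.glob(file.path(input_dir, "batch", "*.dat")))
  if (length(batch)) {
    ran <- c(ran, "rg", "flory")
    for (f in batch) {
      cond <- sub("\\.dat$", "", basename(f))
      prof <- read_saxs_profile(f, q_unit = config$q_unit)
      gr <- tryCatch(guinier_rg(prof, min_len = config$min_window,
                                guinier_limit = config$guinier_limit,
                                n_bins = config$n_bins),
                     error = function(e) e)
      fl <- tryCatch(fit_mff(prof), error = function(e) e)
      if (!inherits(gr, "error"))
        write_result(gr[c("rg", "rg_uncertainty", "i0", "n_windows",
                          "quality_flag")],
                     file.path(output_dir, paste0(cond, "_guinier.json")))
      if (!inherits(fl, "error"))
        write_result(fl, file.path(output_dir, paste0(cond, "_flory.json")))
      summary_rows[[cond]] <- data.frame(
        condition = cond,
        rg_nm = if (inherits(gr, "error")) NA_real_ else gr$rg,
        nu = if (inherits(fl, "error") || fl$unreliable) NA_real_ else fl$nu,
        t_half_h = NA_real_, c_sat_um = NA_real_)
      note("batch %s: rg %s, flory %s", cond,
           if (inherits(gr, "error")) conditionMessage(gr) else "ok",
           if (inherits(fl, "error")) conditionMessage(fl) else "ok")
    }
  } else skipped$rg <- "no batch profiles found"

  fcsv <- file.path(input_dir, "secsaxs", "frames.csv")
  ucsv <- file.path(input_dir, "secsaxs", "uv.csv")
  if (file.exists(fcsv) && file.exists(ucsv)) {
    ran <- c(ran, "a2")
    series <- read_frame_series(fcsv, ucsv, q_unit = config$q_unit)
    sel <- select_sec_frames(series, "auto", threshold_frac = 0.1)
    pts <- extract_i0_series(series, sel$sample_idx, sel$buffer_idx, config)
    vf <- fit_virial(pts, config$mw_da)
    write_result(vf, file.path(output_dir, "virial.json"))
    note("a2: %g cm^3 mol g^-2 from %d points", vf$a2, vf$n_points)
  } else skipped$a2 <- "no secsaxs/frames.csv + uv.csv"

  tht_path <- file.path(input_dir, "tht.csv")
  if (file.exists(tht_path)) {
    ran <- c(ran, "tht")
    traces <- read_kinetic_csv(tht_path)
    fits <- lapply(traces, function(tr)
      fit_sigmoid(tryCatch(normalize_trace(tr), error = function(e) tr)))
    stats <- halftime_stats(fits)
    write.csv(stats, file.path(output_dir, "halftimes.csv"),
              row.names = FALSE)
    for (i in seq_len(nrow(stats))) {
      cond <- stats$condition[i]
      if (cond %in% names(summary_rows))
        summary_rows[[cond]]$t_half_h <- stats$t_half_mean[i]
      else summary_rows[[cond]] <- data.frame(
        condition = cond, rg_nm = NA_real_, nu = NA_real_,
        t_half_h = stats$t_half_mean[i], c_sat_um = NA_real_)
    }
    note("tht: %d condition(s)", nrow(stats))
  } else skipped$tht <- "no tht.csv"

  plate_path <- file.path(input_dir, "plate.csv")
  if (file.exists(plate_path)) {
    ran <- c(ran, "csat")
    cs <- determine_csat(read_plate_csv(plate_path))
    write_result(cs, file.path(output_dir, "csat.json"))
    note("csat: %s", if (cs$detected) paste(cs$c_sat, "uM") else "none detected")
  } else skipped$csat <- "no plate.csv"

  ims_files <- sort(Sys.glob(file.path(input_dir, "ims", "*.csv")))
  if (length(ims_files)) {
    ran <- c(ran, "ccs")
    for (f in ims_files) {
      cond <- sub("\\.csv$", "", basename(f))
      inst <- ims_instrument(ion_mass_da = config$mw_da)
      res <- ccs_pipeline(read_stepfield_csv(f, inst))
      write_result(res[c("k0", "t0_ms", "ccs", "ccs_uncertainty_rel",
                         "scale_factor_a")],
                   file.path(output_dir, paste0(cond, "_ccs.json")))
      note("ccs %s: %.4g A^2", cond, res$ccs)
    }
  } else skipped$ccs <- "no ims/*.csv"

  if (length(summary_rows)) {
    summary <- do.call(rbind, summary_rows)
    write.csv(summary, file.path(output_dir, "summary.csv"),
              row.names = FALSE)
    ok <- !is.na(summary$rg_nm) & !is.na(summary$t_half_h)
    if (sum(ok) >= 3L) {
      ran <- c(ran, "correlate")
      cr <- regress(summary$rg_nm, summary$t_half_h,
                    labels = summary$condition)
      write_result(cr[c("slope", "intercept", "r_squared", "n")],
                   file.path(output_dir, "correlation_thalf_rg.json"))
      if (sum(ok) >= 4L) {
        ek <- elbow_k(scale(cbind(summary$rg_nm[ok], summary$t_half_h[ok])),
                      k_max = min(5L, sum(ok) - 1L),
                      seed = stage_seed(config$seed, "elbow"))
        write_result(ek[c("k", "wcss", "no_strong_elbow", "rule")],
                     file.path(output_dir, "elbow.json"))
      }
      note("correlate: R^2 = %.3f over %d conditions", cr$r_squared, cr$n)
    } else skipped$correlate <- "fewer than 3 conditions with Rg and halftime"
  }

  inputs <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  # outputs may be nested under the input directory; they are not inputs
  out_norm <- normalizePath(output_dir)
  inputs <- inputs[!startsWith(normalizePath(inputs), out_norm)]
  manifest <- list(
    command = "run_pipeline",
    config = unclass(config),
    input_hashes = as.list(tools::md5sum(inputs)),
    software_version = as.character(packageVersion("idplink")),
    seed = config$seed,
    stages_run = unique(ran),
    stages_skipped = skipped,
    log = log,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
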