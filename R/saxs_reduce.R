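# Frame quality control, averaging, buffer subtraction and UV-to-
# concentration conversion, for batch repeats and SEC-SAXS elutions.

#' Reject outlier frames by their chi-squared distance to the mean frame
#'
#' Each frame gets a distance `d_i = sum_q (I_i(q) - Ibar(q))^2 / s_i(q)^2`
#' to the pointwise mean of all frames (unweighted squared distance when no
#' sigma is available). A frame is rejected iff its distance deviates from
#' the mean distance by more than `threshold_sigmas` standard deviations.
#' The sweep is single-pass: the mean frame and the distance statistics are
#' computed once, from all frames. When the distances have zero dispersion
#' (e.g. identical frames) no frame is rejected.
#'
#' @param frames list of [saxs_profile()] objects on a common q grid, or a
#'   [frame_series()].
#' @param threshold_sigmas rejection threshold in sd units (default 2).
#' @param weighted use sigma weighting when sigma is present (default);
#'   `FALSE` forces the unweighted distance.
#' @param iterative re-run the sweep on the kept set until stable
#'   (off by default; the single pass is the reference behaviour).
#' @return An object of class `reduction_report` with fields
#'   `distances`, `kept`, `rejected`, `mean_distance`, `sd_distance`.
#' @export
reject_outlier_frames <- function(frames, threshold_sigmas = 2,
                                  weighted = TRUE, iterative = FALSE) {
  if (inherits(frames, "frame_series")) frames <- frames$frames
  if (length(frames) < 3L) stop("need at least 3 frames for outlier rejection")
  n <- length(frames)
  imat <- vapply(frames, function(f) f$intensity,
                 numeric(length(frames[[1]]$q)))
  has_sigma <- weighted && all(vapply(frames, function(f) !is.null(f$sigma),
                                      logical(1)))
  sweep_once <- function(idx) {
    ibar <- rowMeans(imat[, idx, drop = FALSE])
    d <- vapply(idx, function(i) {
      r2 <- (imat[, i] - ibar)^2
      if (has_sigma) sum(r2 / frames[[i]]$sigma^2) else sum(r2)
    }, numeric(1))
    mu <- mean(d); s <- sd(d)
    keep <- if (is.na(s) || s == 0) rep(TRUE, length(idx))
            else abs(d - mu) <= threshold_sigmas * s
    list(d = d, mu = mu, s = if (is.na(s)) 0 else s, keep = keep)
  }
  idx <- seq_len(n)
  sw <- sweep_once(idx)
  kept <- idx[sw$keep]
  if (iterative) {
    repeat {
      sw2 <- sweep_once(kept)
      kept2 <- kept[sw2$keep]
      if (length(kept2) == length(kept) || length(kept2) < 3L) break
      kept <- kept2
    }
  }
  structure(list(distances = sw$d, kept = kept,
                 rejected = setdiff(idx, kept),
                 mean_distance = sw$mu, sd_distance = sw$s,
                 threshold_sigmas = threshold_sigmas,
                 weighted = has_sigma, n_frames = n),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> %d frames: %d kept, %d rejected (%.3g sigma rule)\n",
              x$n_frames, length(x$kept), length(x$rejected),
              x$threshold_sigmas))
  invisible(x)
}

#' Average a set of frames into one profile
#'
#' Pointwise mean intensity. The sigma of the average is the propagated
#' standard error: `sqrt(mean(sigma^2)/n)` when per-frame sigmas exist,
#' otherwise the pointwise sample sd divided by `sqrt(n)`.
#'
#' @param frames list of [saxs_profile()] objects or a [frame_series()].
#' @param kept indices of frames to average (default all).
#' @return A [saxs_profile()].
#' @export
average_frames <- function(frames, kept = seq_along(frames)) {
  if (inherits(frames, "frame_series")) frames <- frames$frames
  if (length(kept) == 0L) stop("no frames to average")
  sel <- frames[kept]
  q <- sel[[1]]$q
  imat <- vapply(sel, function(f) f$intensity, numeric(length(q)))
  imat <- matrix(imat, nrow = length(q))
  n <- length(sel)
  m <- rowMeans(imat)
  has_sigma <- all(vapply(sel, function(f) !is.null(f$sigma), logical(1)))
  sigma <- if (has_sigma) {
    smat <- matrix(vapply(sel, function(f) f$sigma, numeric(length(q))),
                   nrow = length(q))
    sqrt(rowMeans(smat^2) / n)
  } else if (n >= 2L) {
    apply(imat, 1L, sd) / sqrt(n)
  } else NULL
  if (!is.null(sigma) && any(sigma <= 0)) sigma <- NULL  # degenerate (identical frames)
  saxs_profile(q, m, sigma = sigma, label = "averaged")
}

#' Subtract a buffer profile from a sample profile
#'
#' Intensities subtract; sigmas add in quadrature.
#'
#' @param sample_avg,buffer_avg [saxs_profile()] objects on identical q
#'   grids.
#' @return A [saxs_profile()].
#' @export
subtract_buffer <- function(sample_avg, buffer_avg) {
  if (length(sample_avg$q) != length(buffer_avg$q) ||
      any(abs(sample_avg$q - buffer_avg$q) >
          1e-9 * pmax(abs(sample_avg$q), 1)))
    stop("sample and buffer q grids differ")
  sigma <- if (!is.null(sample_avg$sigma) && !is.null(buffer_avg$sigma))
    sqrt(sample_avg$sigma^2 + buffer_avg$sigma^2) else NULL
  saxs_profile(sample_avg$q, sample_avg$intensity - buffer_avg$intensity,
               sigma = sigma,
               label = paste0(sample_avg$label, " - buffer"))
}

#' Select sample and buffer frames of a SEC-SAXS elution
#'
#' In `auto` mode the UV trace is interpolated onto the frame times; sample
#' frames are those with UV at least `threshold_frac` of the way from
#' baseline to peak (default half-max, the choice for frame averaging; the
#' virial analysis widens it to sweep a larger concentration range), and
#' buffer frames are the contiguous block (default 10 frames) immediately
#' preceding the peak onset -- the placement that gives the cleanest buffer
#' subtraction. `manual` mode passes explicit index lists through.
#'
#' @param series a [frame_series()] (UV required in auto mode).
#' @param mode `"auto"` or `"manual"`.
#' @param sample_idx,buffer_idx explicit 1-based frame indices for manual
#'   mode.
#' @param buffer_block buffer block length for auto mode.
#' @param threshold_frac fraction of (peak - baseline) above baseline a
#'   frame's UV must reach to count as a sample frame.
#' @return A list with `sample_idx` and `buffer_idx`.
#' @export
select_sec_frames <- function(series, mode = c("auto", "manual"),
                              sample_idx = NULL, buffer_idx = NULL,
                              buffer_block = 10L, threshold_frac = 0.5) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(sample_idx) || is.null(buffer_idx))
      stop("manual mode requires sample_idx and buffer_idx")
    return(list(sample_idx = as.integer(sample_idx),
                buffer_idx = as.integer(buffer_idx)))
  }
  if (is.null(series$uv)) stop("auto mode requires a UV trace")
  uvf <- approx(series$uv$time, series$uv$a280, xout = series$times,
                rule = 2)$y
  # baseline from the lowest quartile of frames: robust even when the
  # elution peak occupies a large share of the series
  low <- sort(uvf)[seq_len(max(3L, length(uvf) %/% 4L))]
  baseline <- median(low)
  noise <- mad(low)
  peak <- max(uvf)
  if (peak - baseline <= 3 * noise || peak - baseline <= 0)
    stop("no UV peak detected above 3x baseline noise")
  thr <- baseline + threshold_frac * (peak - baseline)
  sample_idx <- which(uvf >= thr)
  # buffer block ends where protein signal first rises above the baseline
  # (3x noise, floored at 1% of the peak height), not at the sample
  # threshold: frames on the elution shoulder must not pollute the buffer
  rise <- baseline + max(3 * noise, 0.01 * (peak - baseline))
  onset <- min(which(uvf > rise))
  buffer_idx <- seq.int(max(1L, onset - buffer_block), onset - 1L)
  if (onset <= 1L) stop("no buffer frames before the UV peak")
  list(sample_idx = sample_idx, buffer_idx = buffer_idx)
}

#' Convert UV absorbance at 280 nm to protein concentration
#'
#' Beer-Lambert: `c = A280 / (epsilon * path)`. Negative absorbances
#' (baseline noise) are clamped to zero with a warning.
#'
#' @param a280 absorbance values, AU.
#' @param epsilon molar extinction coefficient, M^-1 cm^-1 (default 2800).
#' @param path_cm path length, cm.
#' @return Concentration in mol/L.
#' @seealso [molar_to_gcm3()] for the mass-concentration mirror used by the
#'   virial fit.
#' @export
uv_to_concentration <- function(a280, epsilon = 2800, path_cm = 1) {
  stopifnot(epsilon > 0, path_cm > 0)
  if (any(a280 < 0)) {
    warning("negative absorbance clamped to 0 (baseline noise)")
    a280 <- pmax(a280, 0)
  }
  a280 / (epsilon * path_cm)
}

#' Convert molar concentration to g/cm^3
#'
#' @param c_molar concentration, mol/L.
#' @param mw_da molecular weight, Da.
#' @return Concentration in g/cm^3.
#' @export
molar_to_gcm3 <- function(c_molar, mw_da) c_molar * mw_da / 1000
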