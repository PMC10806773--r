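# Second virial coefficient from SEC-SAXS. Across the elution peak the
# protein concentration sweeps continuously; pairing each frame's
# extrapolated forward intensity I(0, c) with the time-aligned UV-derived
# concentration yields a (c, I0) series governed by the single-contact
# virial relation K c / I(0, c) = 1/Mw + 2 A2 c.

#' Extract the per-frame (concentration, forward-intensity) series
#'
#' For every sample frame: subtract the averaged buffer, Guinier-fit the
#' low-q region for I(0), and pair it with the UV concentration
#' interpolated at the frame time (an optional lag shifts the UV trace to
#' compensate detector dead volume). Frames whose concentration falls
#' below 3x the UV baseline noise (estimated from the buffer frames) are
#' dropped with a warning.
#'
#' @param series a [frame_series()] with UV trace.
#' @param sample_idx,buffer_idx frame indices from [select_sec_frames()].
#' @param config an [analysis_config()] (extinction coefficient, Mw, path).
#' @param lag_s UV-to-frame time lag, s (UV time + lag matches frame time).
#' @param low_q_points number of lowest-q points for the per-frame Guinier
#'   fit.
#' @param bins group frames into at most this many concentration bins
#'   before fitting (`NULL` keeps per-frame points).
#' @return A data frame of class `conc_series` with columns `c_gcm3`,
#'   `c_uM`, `i0`, `i0_err`.
#' @export
extract_i0_series <- function(series, sample_idx, buffer_idx,
                              config = analysis_config(), lag_s = 0,
                              low_q_points = 20L, bins = NULL) {
  if (is.null(series$uv)) stop("A2 analysis requires a UV trace")
  buffer_avg <- average_frames(series$frames, buffer_idx)
  uv_t <- series$uv$time + lag_s
  uv_at <- function(t) approx(uv_t, series$uv$a280, xout = t, rule = 2)$y
  a_buf <- uv_at(series$times[buffer_idx])
  uv_noise <- max(sd(a_buf), 1e-12)
  rows <- lapply(sample_idx, function(i) {
    a280 <- uv_at(series$times[i])
    c_molar <- uv_to_concentration(max(a280, 0), config$epsilon,
                                   config$uv_path_cm)
    if (a280 < 3 * uv_noise) return(NULL)
    sub <- subtract_buffer(series$frames[[i]], buffer_avg)
    npt <- min(low_q_points, length(sub$q))
    gf <- guinier_fit(sub, 1L, npt)
    if (!gf$valid) return(NULL)
    data.frame(c_gcm3 = molar_to_gcm3(c_molar, config$mw_da),
               c_uM = c_molar * 1e6, i0 = gf$i0,
               i0_err = if (!is.null(sub$sigma)) gf$stderr_i0 else NA_real_)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " frame(s) dropped (concentration below 3x UV noise ",
            "or invalid Guinier fit)")
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no usable (c, I0) pairs extracted")
  if (!is.null(bins) && nrow(out) > bins) {
    cut_id <- cut(out$c_gcm3, breaks = bins, labels = FALSE)
    out <- do.call(rbind, lapply(split(out, cut_id), function(g)
      data.frame(c_gcm3 = mean(g$c_gcm3), c_uM = mean(g$c_uM),
                 i0 = mean(g$i0),
                 i0_err = if (nrow(g) > 1) sd(g$i0) / sqrt(nrow(g))
                          else g$i0_err[1])))
  }
  rownames(out) <- NULL
  class(out) <- c("conc_series", class(out))
  out
}

#' Fit the virial relation to a (c, I0) series
#'
#' The relation `K c / I(0, c) = 1/Mw + 2 A2 c` is fitted in the
#' operational form `c / I0 = alpha + beta c` by (weighted) linear least
#' squares, whence `A2 = beta / (2 alpha Mw)` and the lumped instrument
#' constant `K = 1 / (alpha Mw)`. The estimate is invariant to any global
#' rescaling of the intensities (K absorbs the scale). Positive A2 means
#' net repulsive interparticle interactions; negative, attractive.
#'
#' @param points a `conc_series` from [extract_i0_series()], or any data
#'   frame with columns `c_gcm3` and `i0` (optional `i0_err`).
#' @param mw molecular weight, Da.
#' @return An object of class `virial_fit` with fields `a2`
#'   (cm^3 mol g^-2), `a2_err`, `k_const`, `mw_used`, `n_points`, `chi2`,
#'   `alpha`, `beta`.
#' @export
fit_virial <- function(points, mw) {
  stopifnot(mw > 0)
  pts <- points[points$c_gcm3 > 0 & points$i0 > 0, , drop = FALSE]
  cs <- unique(pts$c_gcm3)
  if (length(cs) < 3L)
    stop("need >= 3 distinct concentrations (got ", length(cs), ")")
  span <- max(cs) / min(cs)
  if (span < 2)
    stop(sprintf("concentration span too small (max/min = %.2f, need >= 2)",
                 span))
  y <- pts$c_gcm3 / pts$i0
  # propagate i0 error into y when available: sd(y) = c * i0_err / i0^2
  w <- if (!is.null(pts$i0_err) && all(is.finite(pts$i0_err)) &&
           all(pts$i0_err > 0))
    (pts$i0^2 / (pts$c_gcm3 * pts$i0_err))^2 else NULL
  fit <- if (is.null(w)) lm(y ~ pts$c_gcm3) else
    lm(y ~ pts$c_gcm3, weights = w)
  alpha <- coef(fit)[[1]]; beta <- coef(fit)[[2]]
  V <- suppressWarnings(vcov(fit))  # zero-noise series fit exactly
  a2 <- beta / (2 * alpha * mw)
  # first-order propagation of (alpha, beta) covariance into A2
  grad <- c(-beta / (2 * alpha^2 * mw), 1 / (2 * alpha * mw))
  a2_err <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(a2 = a2, a2_err = a2_err, k_const = 1 / (alpha * mw),
                 mw_used = mw, n_points = nrow(pts),
                 chi2 = sum(residuals(fit)^2 *
                              (if (is.null(w)) 1 else w)),
                 alpha = alpha, beta = beta),
            class = "virial_fit")
}

#' @export
print.virial_fit <- function(x, ...) {
  cat(sprintf("<virial_fit> A2 = %.4g +/- %.2g cm^3 mol g^-2 (%s, n = %d)\n",
              x$a2, x$a2_err,
              if (x$a2 > 0) "repulsive" else "attractive/neutral",
              x$n_points))
  invisible(x)
}

#' @importFrom stats residuals
NULL
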