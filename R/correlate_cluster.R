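# Cross-condition statistics: simple OLS regressions between the
# per-condition observables (halftime vs Rg, Csat vs Rg, nu vs Rg, ...)
# and an elbow-method check on the minimum cluster count of the scatter.

#' Ordinary least-squares regression across conditions
#'
#' Conditions with undefined values (e.g. a non-aggregating condition has
#' no halftime; a condition without detected LLPS has no Csat) are
#' excluded, and the exclusions are recorded with their reasons rather
#' than silently dropped. No measurement-error-in-x correction is applied.
#'
#' @param x,y numeric vectors (same length), one value per condition.
#' @param labels optional condition labels.
#' @param exclusions named character vector `label = reason` of conditions
#'   to drop before fitting; conditions with `NA` in x or y are excluded
#'   automatically with reason `"undefined value"`.
#' @return An object of class `correlation_result` with fields `slope`,
#'   `intercept`, `r_squared`, `n`, `excluded` (data frame label/reason),
#'   `points`.
#' @export
regress <- function(x, y, labels = NULL, exclusions = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (is.null(labels)) labels <- as.character(seq_along(x))
  excl <- data.frame(label = character(0), reason = character(0))
  drop <- rep(FALSE, length(x))
  if (!is.null(exclusions)) {
    hit <- labels %in% names(exclusions)
    drop <- drop | hit
    excl <- rbind(excl, data.frame(label = labels[hit],
                                   reason = unname(exclusions[labels[hit]])))
  }
  undef <- (!drop) & (is.na(x) | is.na(y))
  if (any(undef))
    excl <- rbind(excl, data.frame(label = labels[undef],
                                   reason = "undefined value"))
  drop <- drop | undef
  xs <- x[!drop]; ys <- y[!drop]
  if (length(xs) < 3L)
    stop("fewer than 3 points remain after exclusions")
  fit <- lm(ys ~ xs)
  sstot <- sum((ys - mean(ys))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(residuals(fit)^2) / sstot
  structure(list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
                 r_squared = r2, n = length(xs), excluded = excl,
                 points = data.frame(label = labels[!drop], x = xs, y = ys)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> y = %.4g x + %.4g, R^2 = %s, n = %d (%d excluded)\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "undefined" else
                sprintf("%.3f", x$r_squared),
              x$n, nrow(x$excluded)))
  invisible(x)
}

#' Elbow-method cluster-count check
#'
#' k-means (10 restarts per k, fixed seed) for k = 1..k_max; the selected
#' k maximizes the discrete curvature (second difference) of the
#' within-cluster sum of squares curve, ties broken toward smaller k.
#' The flag `no_strong_elbow` is set when the curvature at the selected k
#' does not exceed `strength_min` times the residual WCSS there: a smooth
#' featureless decay (single cloud, WCSS ~ 1/k) always has positive
#' curvature, but only a genuine elbow has curvature large compared to
#' what is left to explain.
#'
#' @param points numeric matrix (rows = conditions) or data frame.
#' @param k_max largest k to try (>= 2); needs at least `k_max + 1` rows.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart restarts per k (default 10).
#' @param strength_min elbow-strength threshold (curvature / residual
#'   WCSS at the selected k) below which the flag is set.
#' @return An object of class `elbow_result` with fields `k`, `wcss`
#'   (named vector over k), `curvature`, `no_strong_elbow`, `rule`.
#' @export
elbow_k <- function(points, k_max, seed = 1L, nstart = 10L,
                    strength_min = 1) {
  m <- as.matrix(points)
  if (k_max < 2L) stop("k_max must be >= 2")
  n_distinct <- nrow(unique(m))
  if (n_distinct < k_max + 1L) {
    warning("only ", n_distinct, " distinct points; truncating k range")
    k_max <- max(2L, n_distinct - 1L)
  }
  wcss <- with_seed(seed, vapply(seq_len(k_max), function(k) {
    if (k == 1L) sum(scale(m, scale = FALSE)^2)
    else kmeans(m, centers = k, nstart = nstart, iter.max = 50L)$tot.withinss
  }, numeric(1)))
  # enforce monotonicity defensively: a worse local optimum at larger k is
  # replaced by the smaller-k value
  wcss <- cummin(wcss)
  if (k_max >= 3L) {
    curv <- diff(diff(wcss))                 # indexed by k = 2..k_max-1
    k_sel <- which.max(curv) + 1L            # first max <=> smallest k on ties
    no_elbow <- max(curv) < strength_min * max(wcss[k_sel],
                                               1e-12 * wcss[1])
  } else {
    curv <- numeric(0); k_sel <- 1L; no_elbow <- TRUE
  }
  structure(list(k = as.integer(k_sel), wcss = setNames(wcss, seq_len(k_max)),
                 curvature = curv, no_strong_elbow = no_elbow,
                 rule = "argmax of second difference of WCSS"),
            class = "elbow_result")
}

#' @export
print.elbow_result <- function(x, ...) {
  cat(sprintf("<elbow_result> selected k = %d (%s)%s\n", x$k, x$rule,
              if (x$no_strong_elbow) " [no strong elbow]" else ""))
  invisible(x)
}
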