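# ThT aggregation kinetics: normalization, three-parameter sigmoid fit
# s(t) = F / (1 + exp(-k (t - t_half))), replicate halftime statistics.

#' Normalize a kinetic trace between 0 and 1
#'
#' `(signal - min) / (max - min)` using the trace's own extrema. For a
#' non-aggregating trace (flat signal) pass `reference_max` -- typically
#' the plateau of an aggregating condition -- and the trace is scaled as
#' `(signal - min) / (reference_max - min)` instead.
#'
#' @param trace a [kinetic_trace()].
#' @param reference_max external maximum for flat traces.
#' @return A normalized [kinetic_trace()].
#' @export
normalize_trace <- function(trace, reference_max = NULL) {
  lo <- min(trace$signal); hi <- max(trace$signal)
  if (is.null(reference_max)) {
    if (hi - lo <= .Machine$double.eps * max(abs(hi), 1))
      stop("flat trace: cannot normalize without reference_max")
    denom <- hi - lo
  } else {
    denom <- reference_max - lo
    if (denom <= 0) stop("reference_max must exceed the trace minimum")
  }
  kinetic_trace(trace$time, (trace$signal - lo) / denom,
                condition = trace$condition, replicate = trace$replicate)
}

#' Fit the three-parameter aggregation sigmoid to a trace
#'
#' `s(t) = F / (1 + exp(-k (t - t_half)))`, fitted by Levenberg-Marquardt
#' least squares. Initial values come from the data: F = max signal,
#' t_half = first crossing of half-max, k = 4 / (t90 - t10). Failure modes
#' (optimizer failure, k <= 0, t_half escaping the observed window) set
#' `converged = FALSE` instead of raising, so a batch of wells never
#' aborts on one non-aggregating trace.
#'
#' @param trace a (normally normalized) [kinetic_trace()].
#' @return An object of class `sigmoid_fit` with fields `f`, `k`,
#'   `t_half`, their standard errors, `converged`, `condition`,
#'   `replicate`.
#' @export
fit_sigmoid <- function(trace) {
  t <- trace$time; s <- trace$signal
  f0 <- max(s)
  half <- f0 / 2
  above <- which(s >= half)
  t_half0 <- if (length(above)) t[min(above)] else median(t)
  t10 <- t[which(s >= 0.1 * f0)[1]]
  t90i <- which(s >= 0.9 * f0)
  t90 <- if (length(t90i)) t[t90i[1]] else max(t)
  k0 <- if (is.finite(t90 - t10) && t90 > t10) 4 / (t90 - t10) else
    4 / diff(range(t))
  fail <- structure(list(f = NA_real_, k = NA_real_, t_half = NA_real_,
                         f_stderr = NA_real_, k_stderr = NA_real_,
                         t_half_stderr = NA_real_, converged = FALSE,
                         condition = trace$condition,
                         replicate = trace$replicate),
                    class = "sigmoid_fit")
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(f = f0, k = k0, t_half = t_half0),
                       fn = function(p)
                         s - p[1] / (1 + exp(-p[2] * (t - p[3]))),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
  p <- coef(fit)
  if (!is.finite(p["k"]) || p["k"] <= 0 ||
      p["t_half"] < min(t) || p["t_half"] > max(t)) return(fail)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(f = unname(p["f"]), k = unname(p["k"]),
                 t_half = unname(p["t_half"]),
                 f_stderr = unname(se[1]), k_stderr = unname(se[2]),
                 t_half_stderr = unname(se[3]), converged = TRUE,
                 condition = trace$condition, replicate = trace$replicate),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<sigmoid_fit> %s rep %d: F = %.3g, k = %.3g /h, t1/2 = %.2f h\n",
                x$condition, x$replicate, x$f, x$k, x$t_half))
  else
    cat(sprintf("<sigmoid_fit> %s rep %d: NOT CONVERGED\n",
                x$condition, x$replicate))
  invisible(x)
}

#' Replicate halftime statistics per condition
#'
#' Each replicate is fitted independently; the reported halftime is the
#' arithmetic mean over converged replicates and its error bar the sample
#' sd. Conditions with zero converged replicates are marked
#' `"no aggregation observed"`.
#'
#' @param fits list of [fit_sigmoid()] results (any mix of conditions).
#' @return A data frame with columns `condition`, `t_half_mean`,
#'   `t_half_sd`, `n_converged`, `n_failed`, `note`.
#' @export
halftime_stats <- function(fits) {
  conds <- vapply(fits, `[[`, character(1), "condition")
  do.call(rbind, lapply(unique(conds), function(cc) {
    ff <- fits[conds == cc]
    ok <- Filter(function(f) isTRUE(f$converged), ff)
    if (length(ok) == 0L)
      return(data.frame(condition = cc, t_half_mean = NA_real_,
                        t_half_sd = NA_real_, n_converged = 0L,
                        n_failed = length(ff),
                        note = "no aggregation observed"))
    th <- vapply(ok, `[[`, numeric(1), "t_half")
    data.frame(condition = cc, t_half_mean = mean(th),
               t_half_sd = if (length(th) > 1L) sd(th) else 0,
               n_converged = length(ok),
               n_failed = length(ff) - length(ok),
               note = if (length(th) == 1L) "single replicate" else "")
  }))
}
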