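# LLPS saturation concentration from endpoint turbidity plates. The
# absorbances at the low concentrations where no phase separation occurs
# define a pooled baseline; each higher concentration is compared to that
# baseline with a t test and the lowest concentration with p < alpha is
# the saturation concentration.

#' Determine the LLPS saturation concentration by the t-test ladder
#'
#' Absorbances at the baseline concentrations (default 0, 4, 8, 12 uM) are
#' pooled into one baseline sample. Each higher tested concentration, in
#' increasing order, is compared to the baseline by a two-sample t test
#' (two-sided Welch by default). The saturation concentration is the
#' lowest one with `p < alpha`; when none reaches significance the result
#' is `"none detected"` (e.g. the onset exceeds the tested range). No
#' multiple-testing correction is applied -- each concentration is judged
#' at the raw per-test alpha. Concentrations with zero variance in both
#' samples cannot produce a p value and are treated as not significant,
#' with a warning.
#'
#' @param plate a [plate_data()] with >= 3 replicates per concentration.
#' @param baseline_concs concentrations pooled into the baseline, uM.
#' @param alpha per-test significance level (default 0.05).
#' @param var_equal `TRUE` for the Student equal-variance test; default is
#'   Welch.
#' @return An object of class `csat_result` with fields `c_sat` (uM, or
#'   `NA` for none detected), `detected`, `p_values` (named by tested
#'   concentration), `baseline_concs`, `alpha`, `test`.
#' @export
determine_csat <- function(plate, baseline_concs = c(0, 4, 8, 12),
                           alpha = 0.05, var_equal = FALSE) {
  d <- as.data.frame(plate)
  reps <- table(d$concentration_uM)
  if (any(reps < 3L))
    stop("every concentration needs >= 3 replicates for Csat determination")
  if (!all(baseline_concs %in% d$concentration_uM))
    stop("missing baseline concentration(s): ",
         paste(setdiff(baseline_concs, d$concentration_uM), collapse = ", "))
  baseline <- d$absorbance[d$concentration_uM %in% baseline_concs]
  tested <- sort(unique(d$concentration_uM[
    !d$concentration_uM %in% baseline_concs]))
  if (length(tested) == 0L) stop("no concentrations above the baseline set")
  pvals <- setNames(rep(NA_real_, length(tested)), tested)
  degenerate <- FALSE
  for (i in seq_along(tested)) {
    grp <- d$absorbance[d$concentration_uM == tested[i]]
    if (sd(baseline) == 0 && sd(grp) == 0) {
      degenerate <- TRUE
      pvals[i] <- 1  # zero variance: no evidence either way
      next
    }
    pvals[i] <- tryCatch(
      t.test(grp, baseline, var.equal = var_equal)$p.value,
      error = function(e) 1)
  }
  if (degenerate)
    warning("degenerate (zero-variance) absorbances at some concentration;",
            " treated as not significant")
  sig <- which(pvals < alpha)
  c_sat <- if (length(sig)) tested[min(sig)] else NA_real_
  structure(list(c_sat = c_sat, detected = length(sig) > 0,
                 p_values = pvals, baseline_concs = baseline_concs,
                 alpha = alpha,
                 test = if (var_equal) "two-sided Student t (pooled baseline)"
                        else "two-sided Welch t (pooled baseline)"),
            class = "csat_result")
}

#' @export
print.csat_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<csat_result> Csat = %g uM (%s, alpha = %g)\n",
                x$c_sat, x$test, x$alpha))
  else
    cat(sprintf("<csat_result> none detected up to %s uM (%s)\n",
                names(x$p_values)[length(x$p_values)], x$test))
  invisible(x)
}
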