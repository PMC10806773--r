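# Step-field drift-tube ion mobility. The arrival time at drift voltage
# difference dV is tA = t0 + L^2 / (K dV): regressing tA on 1/dV separates
# the drift mobility (slope) from the time spent outside the drift region
# (intercept t0). The reduced mobility K0 then gives the collision cross
# section via the Mason-Schamp relation.

#' Physical constants used by the Mason-Schamp conversion (CODATA 2018)
#'
#' `e` elementary charge (C), `kB` Boltzmann constant (J/K), `N0`
#' Loschmidt number density at 273.15 K and 760 Torr (m^-3), `da_kg`
#' dalton-to-kilogram factor, `torr_pa` Torr-to-pascal factor.
#'
#' @export
ims_constants <- list(
  e = 1.602176634e-19,
  kB = 1.380649e-23,
  torr_pa = 101325 / 760,
  da_kg = 1.66053906660e-27,
  N0 = 101325 / (1.380649e-23 * 273.15)
)

#' Intensity-weighted peak center of an arrival-time distribution
#'
#' Default method: centroid over the FWHM window around the maximum bin
#' (robust to asymmetric tails); `"max"` takes the maximum bin.
#'
#' @param arrival_times tA grid, ms.
#' @param counts intensities per bin.
#' @param method `"centroid"` or `"max"`.
#' @return Peak center, ms.
#' @export
atd_peak_center <- function(arrival_times, counts,
                            method = c("centroid", "max")) {
  method <- match.arg(method)
  imax <- which.max(counts)
  if (method == "max") return(arrival_times[imax])
  half <- counts[imax] / 2
  win <- counts >= half
  # restrict to the contiguous run containing the maximum
  runs <- rle(win)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  k <- which(starts <= imax & ends >= imax)
  sel <- starts[k]:ends[k]
  sum(arrival_times[sel] * counts[sel]) / sum(counts[sel])
}

#' Step-field regression: reduced mobility and t0 from tA vs 1/dV
#'
#' Ordinary least squares of the peak-center arrival time on the inverse
#' drift voltage. The slope equals `L^2 / K` (here in ms V, with L in cm
#' and K in cm^2 V^-1 s^-1) and the intercept is t0, the time spent
#' outside the drift region. The raw mobility is reduced to standard
#' conditions: `K0 = K (p / 760) (273.15 / T)`.
#'
#' @param peak_centers data frame with columns `delta_v` (V) and `t_a_ms`.
#' @param instrument an [ims_instrument()].
#' @return A list with `k0`, `t0_ms`, `k_raw`, and `regression` (slope,
#'   intercept, r_squared, n).
#' @export
fit_stepfield <- function(peak_centers, instrument) {
  pc <- as.data.frame(peak_centers)
  if (length(unique(pc$delta_v)) < 2L)
    stop("need at least 2 distinct drift voltages")
  if (nrow(pc) < 5L)
    warning("fewer than 5 voltages: below the step-field protocol")
  x <- 1 / pc$delta_v
  fit <- lm(pc$t_a_ms ~ x)
  slope <- coef(fit)[[2]]; t0 <- coef(fit)[[1]]
  if (slope <= 0) stop("negative step-field slope: unphysical mobility")
  r2 <- if (nrow(pc) > 2L)
    suppressWarnings(summary(fit))$r.squared else 1  # exact fits are expected on synthetic data
  L <- instrument$drift_length_cm
  k_raw <- 1000 * L^2 / slope   # ms V -> cm^2 V^-1 s^-1
  k0 <- k_raw * (instrument$pressure_Torr / 760) *
    (273.15 / instrument$temperature_K)
  list(k0 = k0, t0_ms = t0, k_raw = k_raw,
       regression = list(slope = slope, intercept = t0, r_squared = r2,
                         n = nrow(pc)))
}

#' Mason-Schamp collision cross section from a reduced mobility
#'
#' `CCS = 3 z e / (16 N0) * sqrt(2 pi / (mu kB T)) / K0`, with `mu` the
#' reduced ion/buffer-gas mass and `N0` the standard gas number density
#' (273.15 K, 760 Torr). Constants from [ims_constants].
#'
#' @param k0 reduced mobility, cm^2 V^-1 s^-1 (> 0).
#' @param instrument an [ims_instrument()] with charge and masses set.
#' @return CCS in Angstrom^2.
#' @export
mobility_to_ccs <- function(k0, instrument) {
  stopifnot(k0 > 0)
  if (!is.finite(instrument$ion_mass_da) ||
      !is.finite(instrument$buffer_gas_mass_da))
    stop("ion and buffer-gas masses must be set on the instrument")
  mu <- instrument$ion_mass_da * instrument$buffer_gas_mass_da /
    (instrument$ion_mass_da + instrument$buffer_gas_mass_da) *
    ims_constants$da_kg
  k0_si <- k0 * 1e-4  # cm^2/V/s -> m^2/V/s
  ccs_m2 <- 3 * instrument$charge * ims_constants$e /
    (16 * ims_constants$N0) *
    sqrt(2 * pi / (mu * ims_constants$kB * instrument$temperature_K)) / k0_si
  ccs_m2 * 1e20
}

#' First-order relative CCS uncertainty from instrument uncertainties
#'
#' Propagates the stated uncertainties on drift length, temperature and
#' pressure through `CCS proportional to slope p / (L^2 T) * T^(-1/2)`
#' (slope treated as exact here) and floors the result at the 2.0%
#' combined standard uncertainty typical of drift-tube CCS including
#' calibration terms.
#'
#' @param instrument an [ims_instrument()].
#' @param dL_cm,dT_K,dp_torr standard uncertainties (defaults 0.2 cm, 1 K,
#'   0.01 Torr).
#' @param floor_rel lower bound on the reported relative uncertainty.
#' @return Relative uncertainty (dimensionless).
#' @export
ccs_uncertainty_rel <- function(instrument, dL_cm = 0.2, dT_K = 1,
                                dp_torr = 0.01, floor_rel = 0.02) {
  relL <- 2 * dL_cm / instrument$drift_length_cm
  relp <- dp_torr / instrument$pressure_Torr
  # CCS ~ sqrt(T) / (p L^2): the 1/K0 factor carries T/(p L^2), the
  # Mason-Schamp prefactor carries T^(-1/2)
  relT <- dT_K / instrument$temperature_K / 2
  max(sqrt(relL^2 + relp^2 + relT^2), floor_rel)
}

#' Reconstruct the CCS distribution from the lowest-voltage ATD
#'
#' Linear map `CCS(tA) = a (tA - t0)` anchored so the ATD peak center maps
#' exactly onto the CCS obtained from the step-field regression:
#' `a = ccs_peak / (tA_peak - t0)`. Intensities carry over bin-for-bin.
#'
#' @param arrival_times tA grid, ms.
#' @param counts intensities.
#' @param t0_ms intercept from [fit_stepfield()].
#' @param ccs_peak CCS of the peak center, Angstrom^2.
#' @param peak_method peak-center method (see [atd_peak_center()]).
#' @return A data frame with columns `ccs` (Angstrom^2) and `intensity`.
#' @export
reconstruct_ccs_distribution <- function(arrival_times, counts, t0_ms,
                                         ccs_peak,
                                         peak_method = "centroid") {
  ta_peak <- atd_peak_center(arrival_times, counts, peak_method)
  if (ta_peak <= t0_ms)
    stop("ATD peak center precedes t0: cannot anchor the CCS axis")
  a <- ccs_peak / (ta_peak - t0_ms)
  data.frame(ccs = a * (arrival_times - t0_ms), intensity = counts)
}

#' Full step-field CCS pipeline on one dataset
#'
#' Peak centers per voltage, tA vs 1/dV regression, Mason-Schamp
#' conversion, and CCS-distribution reconstruction at the lowest voltage.
#'
#' @param stepdata a [step_field_data()].
#' @param peak_method peak-center method (see [atd_peak_center()]).
#' @return An object of class `ccs_result` with fields `k0`, `t0_ms`,
#'   `ccs`, `ccs_uncertainty_rel`, `scale_factor_a`, `regression`,
#'   `distribution`.
#' @export
ccs_pipeline <- function(stepdata, peak_method = "centroid") {
  recs <- stepdata$records
  pc <- data.frame(
    delta_v = vapply(recs, `[[`, numeric(1), "delta_v"),
    t_a_ms = vapply(recs, function(r)
      atd_peak_center(r$arrival_times, r$counts, peak_method), numeric(1)))
  sf <- fit_stepfield(pc, stepdata$instrument)
  ccs <- mobility_to_ccs(sf$k0, stepdata$instrument)
  lowest <- recs[[which.min(pc$delta_v)]]
  dist <- reconstruct_ccs_distribution(lowest$arrival_times, lowest$counts,
                                       sf$t0_ms, ccs, peak_method)
  ta_peak <- atd_peak_center(lowest$arrival_times, lowest$counts, peak_method)
  structure(list(k0 = sf$k0, t0_ms = sf$t0_ms, ccs = ccs,
                 ccs_nm2 = ccs / 100,
                 ccs_uncertainty_rel =
                   ccs_uncertainty_rel(stepdata$instrument),
                 scale_factor_a = ccs / (ta_peak - sf$t0_ms),
                 regression = sf$regression, distribution = dist,
                 peak_method = peak_method),
            class = "ccs_result")
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf("<ccs_result> K0 = %.4g cm2/V/s, t0 = %.3g ms, CCS = %.4g A^2 (+/- %.1f%%)\n",
              x$k0, x$t0_ms, x$ccs, 100 * x$ccs_uncertainty_rel))
  invisible(x)
}
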