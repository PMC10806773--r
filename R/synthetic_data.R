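# Synthetic-data generators. Each one is a pure function of its parameters
# and seed, and records the generating truth in an attribute so parameter
# recovery can be asserted downstream.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

truth_of <- function(x) attr(x, "truth")

#' Gaussian-chain (Debye) scattering profile with optional noise
#'
#' Generates `I(q) = I0 * D(x)` with the Debye function
#' `D(x) = 2 (exp(-x) + x - 1) / x^2`, `x = (q Rg)^2`, `D(0) = 1` --
#' the exact form factor of an ideal (theta-solvent) polymer chain.
#' Relative Gaussian noise is added when `noise_rel > 0`, and the sigma
#' column is set to the applied noise standard deviation.
#'
#' @param rg_nm true radius of gyration, nm (> 0).
#' @param i0 forward intensity.
#' @param q_grid q values, nm^-1.
#' @param noise_rel relative noise level (sd = `noise_rel * intensity`).
#' @param seed random seed (ignored at `noise_rel = 0`).
#' @return A [saxs_profile()] carrying a `truth` attribute.
#' @export
debye_profile <- function(rg_nm, i0 = 1, q_grid, noise_rel = 0, seed = NULL) {
  if (rg_nm <= 0) stop("rg_nm must be positive")
  if (noise_rel < 0) stop("noise_rel must be non-negative")
  x <- (q_grid * rg_nm)^2
  d <- ifelse(x < 1e-12, 1, 2 * (expm1(-x) + x) / x^2)
  intensity <- i0 * d
  sigma <- NULL
  if (noise_rel > 0) {
    sigma <- noise_rel * intensity
    intensity <- with_seed(seed, intensity + rnorm(length(intensity), 0, sigma))
  }
  p <- saxs_profile(q_grid, intensity, sigma = sigma, label = "debye_synthetic")
  attr(p, "truth") <- list(rg_nm = rg_nm, i0 = i0, nu = 0.5,
                           noise_rel = noise_rel, seed = seed)
  p
}

#' Self-avoiding-walk ensemble on the cubic lattice (pivot algorithm)
#'
#' Samples chains by the pivot algorithm: a random internal site and a
#' random non-identity octahedral symmetry are drawn, the shorter arm is
#' transformed, and the move is accepted iff the walk remains
#' self-avoiding. The chain equilibrates over `burn_in` accepted pivots
#' before the first sample and decorrelates over `gap` accepted pivots
#' between samples (defaults: 10 N and N).
#'
#' @param n_beads chain length N (>= 10).
#' @param n_walks number of sampled conformations (>= 1).
#' @param seed integer seed (C++ Mersenne Twister, independent of R's RNG).
#' @param burn_in accepted pivots before the first sample.
#' @param gap accepted pivots between samples.
#' @return An object of class `chain_ensemble`: list of `n_beads x 3`
#'   integer coordinate matrices plus metadata.
#' @export
saw_ensemble <- function(n_beads, n_walks, seed,
                         burn_in = 10L * n_beads, gap = n_beads) {
  if (n_beads < 10L) stop("n_beads must be >= 10")
  if (n_walks < 1L) stop("n_walks must be >= 1")
  walks <- .saw_pivot_cpp(as.integer(n_beads), as.integer(n_walks),
                          as.integer(burn_in), as.integer(gap),
                          as.integer(seed))
  structure(list(walks = walks, n_beads = as.integer(n_beads),
                 seed = as.integer(seed)),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  cat(sprintf("<chain_ensemble> %d self-avoiding walks of %d beads\n",
              length(x$walks), x$n_beads))
  invisible(x)
}

#' Per-walk squared radius of gyration of a chain ensemble
#'
#' @param ensemble a [saw_ensemble()] result.
#' @return Numeric vector of Rg^2 in lattice units squared.
#' @export
ensemble_rg2 <- function(ensemble) {
  vapply(ensemble$walks, function(m) {
    ctr <- colMeans(m)
    mean(rowSums((sweep(m, 2, ctr))^2))
  }, numeric(1))
}

#' Orientation-averaged scattering of a chain ensemble (Debye sum)
#'
#' `I(q) = < N^-2 sum_ij sin(q r_ij)/(q r_ij) >` over walks, with the
#' diagonal term equal to 1, so `I(0) = 1` exactly.
#'
#' @param ensemble a [saw_ensemble()] result.
#' @param q_grid q values, nm^-1.
#' @param bead_spacing_nm lattice-unit length, nm (default 0.38, the
#'   Calpha-Calpha distance).
#' @return A [saxs_profile()] (unit forward intensity).
#' @export
scattering_from_ensemble <- function(ensemble, q_grid,
                                     bead_spacing_nm = 0.38) {
  if (length(ensemble$walks) == 0L) stop("empty ensemble")
  iq <- .debye_sum_cpp(ensemble$walks, as.numeric(q_grid), bead_spacing_nm)
  rg2 <- mean(ensemble_rg2(ensemble)) * bead_spacing_nm^2
  p <- saxs_profile(q_grid, iq, label = "saw_ensemble_scattering")
  attr(p, "truth") <- list(rg_nm = sqrt(rg2), n_beads = ensemble$n_beads)
  p
}

#' Gaussian elution concentration profile with a detection floor
#'
#' Builds the `conc_profile` input of [sec_saxs_series()]: a Gaussian
#' elution peak whose dilute tails are clipped to exactly zero below
#' `floor_frac` of the peak -- emulating a baseline-separated SEC peak
#' whose shoulders fall below the concentration detection floor -- so the
#' pre-peak frames are true buffer frames.
#'
#' @param times frame times, s.
#' @param peak_conc peak concentration, g/cm^3.
#' @param center,width peak center and Gaussian sd, s.
#' @param floor_frac clip level as a fraction of the peak (default 0.02).
#' @return A data frame with columns `time` and `conc`.
#' @export
elution_profile <- function(times, peak_conc, center, width,
                            floor_frac = 0.02) {
  conc <- peak_conc * exp(-(times - center)^2 / (2 * width^2))
  conc[conc < floor_frac * peak_conc] <- 0
  data.frame(time = times, conc = conc)
}

#' Synthetic SEC-SAXS elution with a known second virial coefficient
#'
#' Frame forward intensities follow the single-contact virial relation
#' `K c / I(0, c) = 1/Mw + 2 A2 c`; the profile shape is a Debye curve of
#' the given Rg riding on a flat buffer background, and the UV trace is
#' `A280 = epsilon * c_molar * path`.
#'
#' @param mw_da molecular weight, Da.
#' @param a2 second virial coefficient, cm^3 mol g^-2.
#' @param conc_profile data frame with columns `time` (s) and `conc`
#'   (g/cm^3) forming an elution peak preceded by at least 10
#'   zero-concentration buffer frames.
#' @param q_grid q values, nm^-1.
#' @param rg_nm chain radius of gyration, nm.
#' @param noise_rel relative Gaussian noise on intensities.
#' @param seed random seed.
#' @param k_const lumped instrument constant K (recorded in truth).
#' @param background flat buffer scattering level.
#' @param epsilon molar extinction coefficient, M^-1 cm^-1.
#' @param path_cm UV path length, cm.
#' @return A [frame_series()] with UV trace and a `truth` attribute.
#' @export
sec_saxs_series <- function(mw_da, a2, conc_profile, q_grid, rg_nm,
                            noise_rel = 0, seed = NULL, k_const = 1e6,
                            background = 0.05, epsilon = 2800,
                            path_cm = 1) {
  conc_profile <- as.data.frame(conc_profile)
  names(conc_profile)[1:2] <- c("time", "conc")
  cvec <- conc_profile$conc
  if (all(cvec == 0)) stop("concentration profile is identically zero")
  if (sum(cumprod(cvec == 0)) < 10L)
    stop("elution must be preceded by >= 10 buffer (zero-concentration) frames")
  x <- (q_grid * rg_nm)^2
  shape <- ifelse(x < 1e-12, 1, 2 * (expm1(-x) + x) / x^2)
  frames <- with_seed(seed, lapply(seq_along(cvec), function(i) {
    c_i <- cvec[i]
    i0 <- if (c_i > 0) k_const * c_i / (1 / mw_da + 2 * a2 * c_i) else 0
    inten <- background + i0 * shape
    sigma <- NULL
    if (noise_rel > 0) {
      sigma <- pmax(noise_rel * inten, noise_rel * background)
      inten <- inten + rnorm(length(inten), 0, sigma)
    }
    saxs_profile(q_grid, inten, sigma = sigma, label = sprintf("frame%03d", i))
  }))
  c_molar <- cvec * 1000 / mw_da        # g/cm^3 -> mol/L
  uv <- data.frame(time = conc_profile$time,
                   a280 = epsilon * c_molar * path_cm)
  fs <- frame_series(frames, times = conc_profile$time, uv = uv)
  attr(fs, "truth") <- list(mw_da = mw_da, a2 = a2, rg_nm = rg_nm,
                            k_const = k_const, background = background,
                            noise_rel = noise_rel, epsilon = epsilon,
                            path_cm = path_cm, seed = seed)
  fs
}

#' Sigmoidal ThT aggregation traces with replicate noise
#'
#' `s(t) = F / (1 + exp(-k (t - t_half)))` plus iid Gaussian noise,
#' generated independently per replicate.
#'
#' @param f final fluorescence plateau (> 0).
#' @param k_per_h growth rate, h^-1 (> 0).
#' @param t_half_h aggregation halftime, h, inside the time window.
#' @param t_grid time points, h.
#' @param noise_sd additive Gaussian noise sd.
#' @param n_replicates number of replicate wells.
#' @param seed random seed.
#' @param condition condition label.
#' @return A list of [kinetic_trace()] objects with a `truth` attribute.
#' @export
tht_traces <- function(f = 1, k_per_h = 0.2, t_half_h = 40,
                       t_grid = seq(0, 110, length.out = 100),
                       noise_sd = 0.05, n_replicates = 3, seed = NULL,
                       condition = "synthetic") {
  stopifnot(f > 0, k_per_h > 0)
  if (t_half_h < min(t_grid) || t_half_h > max(t_grid))
    stop("t_half_h must lie within the time grid")
  clean <- f / (1 + exp(-k_per_h * (t_grid - t_half_h)))
  traces <- with_seed(seed, lapply(seq_len(n_replicates), function(r)
    kinetic_trace(t_grid, clean + rnorm(length(t_grid), 0, noise_sd),
                  condition = condition, replicate = r)))
  attr(traces, "truth") <- list(f = f, k_per_h = k_per_h,
                                t_half_h = t_half_h, noise_sd = noise_sd,
                                seed = seed)
  traces
}

#' Synthetic endpoint turbidity plate with a known LLPS onset
#'
#' Absorbance = baseline + jump * 1[c >= c_sat] + Gaussian noise, with
#' independent replicates.
#'
#' @param c_sat_um onset (saturation) concentration, uM; must be a member
#'   of `conc_list`.
#' @param conc_list tested concentrations, uM (must include the 0, 4, 8,
#'   12 uM baseline set).
#' @param baseline_au baseline absorbance.
#' @param jump_au absorbance jump above the onset (0 = no LLPS).
#' @param noise_sd Gaussian noise sd.
#' @param n_replicates replicate wells per concentration (>= 3).
#' @param seed random seed.
#' @return A [plate_data()] with a `truth` attribute.
#' @export
llps_plate <- function(c_sat_um = 24, conc_list = seq(0, 40, by = 4),
                       baseline_au = 0.05, jump_au = 0.3, noise_sd = 0.01,
                       n_replicates = 3, seed = NULL) {
  if (!all(c(0, 4, 8, 12) %in% conc_list))
    stop("conc_list must include the 0, 4, 8, 12 uM baseline set")
  if (jump_au > 0 && !(c_sat_um %in% conc_list))
    stop("c_sat_um must be one of the tested concentrations")
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration_uM = conc_list)
  mu <- baseline_au + jump_au * (grid$concentration_uM >= c_sat_um)
  ab <- with_seed(seed, mu + rnorm(nrow(grid), 0, noise_sd))
  p <- plate_data(grid$concentration_uM, grid$replicate, ab)
  attr(p, "truth") <- list(c_sat_um = if (jump_au > 0) c_sat_um else NA_real_,
                           baseline_au = baseline_au, jump_au = jump_au,
                           noise_sd = noise_sd, seed = seed)
  p
}

#' Synthetic step-field arrival-time distributions
#'
#' Peak centers obey `tA = t0 + L^2 / (K dV)` with the raw mobility `K`
#' corresponding to the reduced mobility `k0` at the instrument pressure
#' and temperature (`K = k0 (760/p) (T/273.15)`). Each arrival-time
#' distribution is a Gaussian of the given relative width about its
#' center; optional multiplicative count noise.
#'
#' @param k0_cm2_vs reduced mobility, cm^2 V^-1 s^-1 (> 0).
#' @param t0_ms time outside the drift region, ms (> 0).
#' @param voltages drift voltage differences, V (>= 5 per the step-field
#'   protocol).
#' @param peak_rel_width ATD sd as a fraction of the peak center.
#' @param instrument an [ims_instrument()].
#' @param noise_rel relative noise on counts.
#' @param seed random seed.
#' @param n_points tA bins per voltage.
#' @return A [step_field_data()] with a `truth` attribute.
#' @export
ims_arrival <- function(k0_cm2_vs, t0_ms, voltages, peak_rel_width = 0.02,
                        instrument = ims_instrument(), noise_rel = 0,
                        seed = NULL, n_points = 201L) {
  stopifnot(k0_cm2_vs > 0, t0_ms > 0)
  if (length(voltages) < 5L)
    stop("the step-field protocol uses at least 5 drift voltages")
  K <- k0_cm2_vs * (760 / instrument$pressure_Torr) *
    (instrument$temperature_K / 273.15)
  L <- instrument$drift_length_cm
  records <- with_seed(seed, lapply(voltages, function(dv) {
    center <- t0_ms + 1000 * L^2 / (K * dv)
    w <- peak_rel_width * center
    ta <- seq(center - 4 * w, center + 4 * w, length.out = n_points)
    counts <- exp(-(ta - center)^2 / (2 * w^2))
    if (noise_rel > 0)
      counts <- pmax(0, counts + rnorm(length(counts), 0, noise_rel))
    list(delta_v = dv, arrival_times = ta, counts = counts)
  }))
  sf <- step_field_data(records, instrument, min_voltages = 5L)
  attr(sf, "truth") <- list(k0_cm2_vs = k0_cm2_vs, t0_ms = t0_ms,
                            K_raw = K, peak_rel_width = peak_rel_width,
                            noise_rel = noise_rel, seed = seed)
  sf
}

#' Write a truth sidecar next to a generated dataset
#'
#' @param x any generator output carrying a `truth` attribute.
#' @param path JSON path for the sidecar.
#' @return Invisibly, the path.
#' @export
write_truth <- function(x, path) {
  tr <- truth_of(x)
  if (is.null(tr)) stop("object carries no truth record")
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}
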