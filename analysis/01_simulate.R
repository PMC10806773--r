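#!/usr/bin/env Rscript
# Generate the synthetic study: six "mutant" conditions whose chain
# dimensions, aggregation halftimes and phase behaviour are linked the
# way the analysis chain expects to detect -- more expanded chains
# aggregate faster and phase-separate at lower concentration. Every
# dataset is written in the package's on-disk formats with a truth.json
# sidecar so later stages can be scored against the generating values.

suppressPackageStartupMessages(library(idplink))
seed <- 20570L
study <- "results/synthetic_study"
dir.create(file.path(study, "batch"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(study, "secsaxs"), showWarnings = FALSE)
dir.create(file.path(study, "ims"), showWarnings = FALSE)

# condition table: Rg (nm) spans the range seen across tau187 mutants;
# halftime decreases and Csat decreases as Rg grows; the non-aggregating
# reference condition gets no halftime at all
conditions <- data.frame(
  condition = c("ref", "mut_a", "mut_b", "mut_c", "mut_d", "mut_e"),
  rg_nm = c(4.12, 4.20, 4.28, 4.38, 4.47, 4.55),
  t_half_h = c(NA, 58, 50, 40, 30, 22),
  aggregates = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))

q <- seq(0.01, 1.5, length.out = 200)
for (i in seq_len(nrow(conditions))) {
  p <- debye_profile(conditions$rg_nm[i], i0 = 100, q_grid = q,
                     noise_rel = 0.01, seed = seed + i)
  f <- file.path(study, "batch", paste0(conditions$condition[i], ".dat"))
  write.table(cbind(p$q, p$intensity, p$sigma), f,
              row.names = FALSE, col.names = FALSE)
  write_truth(p, sub("\\.dat$", "_truth.json", f))
}

# SEC-SAXS elution for one condition (A2 analysis)
cp <- elution_profile(0:79, 4.114e-4, center = 45, width = 8)
fs <- sec_saxs_series(20570, a2 = 5e-4, cp, seq(0.01, 0.3, length.out = 60),
                      rg_nm = 4.3, noise_rel = 0.01, seed = seed + 10L)
wide <- data.frame(q = fs$frames[[1]]$q)
for (j in seq_along(fs$frames))
  wide[[sprintf("frame%03d", j)]] <- fs$frames[[j]]$intensity
write.csv(wide, file.path(study, "secsaxs", "frames.csv"), row.names = FALSE)
write.csv(fs$uv, file.path(study, "secsaxs", "uv.csv"), row.names = FALSE)
write_truth(fs, file.path(study, "secsaxs", "truth.json"))

# ThT kinetics: 3 replicates per aggregating condition, 110 h window
rows <- list()
for (i in which(conditions$aggregates)) {
  tr <- tht_traces(f = 1, k_per_h = 0.2, t_half_h = conditions$t_half_h[i],
                   t_grid = seq(0, 110, length.out = 100), noise_sd = 0.05,
                   n_replicates = 3, seed = seed + 20L + i,
                   condition = conditions$condition[i])
  rows <- c(rows, lapply(tr, function(x)
    data.frame(condition = x$condition, replicate = x$replicate,
               time_h = x$time, signal = x$signal)))
}
# the reference condition: flat baseline (no aggregation on this timescale)
set.seed(seed + 40L)
for (r in 1:3)
  rows[[length(rows) + 1L]] <- data.frame(
    condition = "ref", replicate = r,
    time_h = seq(0, 110, length.out = 100),
    signal = rnorm(100, 0.02, 0.01))
write.csv(do.call(rbind, rows), file.path(study, "tht.csv"),
          row.names = FALSE)

# endpoint turbidity plate (Csat) for one condition
pl <- llps_plate(c_sat_um = 24, conc_list = seq(0, 40, 4),
                 baseline_au = 0.05, jump_au = 0.3, noise_sd = 0.01,
                 n_replicates = 3, seed = seed + 50L)
write.csv(data.frame(concentration_uM = pl$concentration_uM,
                     replicate = pl$replicate,
                     absorbance = pl$absorbance),
          file.path(study, "plate.csv"), row.names = FALSE)
write_truth(pl, file.path(study, "plate_truth.json"))

# step-field ion mobility for the most expanded condition
inst <- ims_instrument(charge = 10, ion_mass_da = 20570)
sf <- ims_arrival(k0_cm2_vs = 1.0, t0_ms = 2.0,
                  voltages = c(400, 500, 600, 700, 800),
                  instrument = inst, noise_rel = 0.01, seed = seed + 60L)
d <- do.call(rbind, lapply(sf$records, function(r)
  data.frame(delta_v = r$delta_v, t_a_ms = r$arrival_times,
             intensity = r$counts)))
write.csv(d, file.path(study, "ims", "mut_e.csv"), row.names = FALSE)
write_truth(sf, file.path(study, "ims", "mut_e_truth.json"))

write.csv(conditions, file.path(study, "conditions_truth.csv"),
          row.names = FALSE)
cat("synthetic study written to", study, "\n")
cat(sprintf("  %d batch profiles, %d SEC-SAXS frames, %d kinetic traces, 1 plate, 1 step-field set\n",
            nrow(conditions), length(fs$frames), sum(conditions$aggregates) * 3 + 3))
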