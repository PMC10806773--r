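#!/usr/bin/env Rscript
# Aggregation kinetics (sigmoid halftimes per replicate, per condition)
# and the LLPS saturation concentration from the turbidity plate.

suppressPackageStartupMessages(library(idplink))
study <- "results/synthetic_study"
stopifnot(dir.exists(study))

traces <- read_kinetic_csv(file.path(study, "tht.csv"))
# the non-aggregating reference trace is flat: normalize it against the
# plateau of an aggregating condition so the fit can (correctly) fail
ref_max <- max(vapply(traces, function(tr)
  if (tr$condition != "ref") max(tr$signal) else -Inf, numeric(1)))
fits <- lapply(traces, function(tr) {
  n <- tryCatch(normalize_trace(tr),
                error = function(e) normalize_trace(tr, reference_max = ref_max))
  fit_sigmoid(n)
})
stats <- halftime_stats(fits)
truth <- read.csv(file.path(study, "conditions_truth.csv"))
stats <- merge(stats, truth[c("condition", "t_half_h")], all.x = TRUE)
names(stats)[names(stats) == "t_half_h"] <- "t_half_true"
write.csv(stats, "results/halftimes.csv", row.names = FALSE)

cat("halftime recovery per condition:\n")
print(stats[c("condition", "t_half_true", "t_half_mean", "t_half_sd",
              "n_converged", "note")], digits = 4, row.names = FALSE)

plate <- read_plate_csv(file.path(study, "plate.csv"))
cs <- determine_csat(plate)
tr_cs <- jsonlite::read_json(file.path(study, "plate_truth.json"))
cat(sprintf("\nCsat: %s uM (truth %s uM, %s)\n",
            if (cs$detected) cs$c_sat else "none",
            tr_cs$c_sat_um, cs$test))
write_result(cs, "results/csat.json")
cat("wrote results/halftimes.csv, results/csat.json\n")
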