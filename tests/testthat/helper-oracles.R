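# Independent oracles used across the suite. Each reimplements a quantity
# by a different route than the package code so agreement is evidence,
# not tautology.

# Uniform self-avoiding walks by naive rejection: propose a simple random
# walk, accept iff self-avoiding. Exactly uniform over N-bead SAWs, so its
# mean Rg^2 is an unbiased reference for the pivot sampler. Only viable at
# small N (acceptance decays exponentially).
rejection_saw_rg2 <- function(n_beads, n_walks, seed) {
  set.seed(seed)
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- numeric(n_walks)
  got <- 0L
  while (got < n_walks) {
    dirs <- sample.int(6L, n_beads - 1L, replace = TRUE)
    xyz <- apply(steps[dirs, , drop = FALSE], 2L, cumsum)
    xyz <- rbind(c(0, 0, 0), xyz)
    if (anyDuplicated(xyz) == 0L) {
      got <- got + 1L
      ctr <- colMeans(xyz)
      out[got] <- mean(rowSums(sweep(xyz, 2L, ctr)^2))
    }
  }
  out
}

# Exact enumeration references for cubic-lattice SAWs rooted at the
# origin, computed once by exhaustive depth-first search (walk counts
# match the published series: c_9 = 1,853,886):
#   N = 10 beads (9 steps): mean Rg^2 = 2.4280150883075513
saw_exact_mean_rg2_n10 <- 2.4280150883075513

# Independent Mason-Schamp evaluation: works with the raw mobility K and
# the gas number density at the actual drift conditions (ideal-gas law),
# rather than with K0 and the standard density N0. Algebraically
# equivalent (K N = K0 N0), numerically a different path.
oracle_ccs_A2 <- function(k0_cm2_vs, charge, ion_mass_da, gas_mass_da,
                          temperature_K, pressure_Torr) {
  e <- 1.602176634e-19; kB <- 1.380649e-23
  da <- 1.66053906660e-27
  p_pa <- pressure_Torr * 101325 / 760
  n_gas <- p_pa / (kB * temperature_K)                   # m^-3 at drift conditions
  k_raw <- k0_cm2_vs * (760 / pressure_Torr) *
    (temperature_K / 273.15) * 1e-4                      # m^2 V^-1 s^-1
  mu <- ion_mass_da * gas_mass_da / (ion_mass_da + gas_mass_da) * da
  ccs_m2 <- 3 * charge * e / (16 * n_gas) *
    sqrt(2 * pi / (mu * kB * temperature_K)) / k_raw
  ccs_m2 * 1e20
}

# Frozen regression value for the Mason-Schamp conversion (z = 10,
# m_ion = 20570 Da, helium, T = 297 K, K0 = 1 cm^2 V^-1 s^-1), computed
# independently and agreed between two implementations to < 1e-6 relative.
ccs_frozen_reference <- 5369.0334006155

# Brute-force minimal WCSS over every possible assignment of points to at
# most k clusters (oracle for the k-means optimum at tiny n).
brute_force_wcss <- function(points, k) {
  m <- as.matrix(points)
  n <- nrow(m)
  stopifnot(n <= 10)
  best <- Inf
  assign_next <- function(labels, i, used) {
    if (i > n) {
      w <- 0
      for (g in seq_len(used)) {
        rows <- m[labels == g, , drop = FALSE]
        ctr <- colMeans(rows)
        w <- w + sum(sweep(rows, 2L, ctr)^2)
      }
      best <<- min(best, w)
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, k))) {
      labels[i] <- g
      assign_next(labels, i + 1L, max(used, g))
    }
  }
  assign_next(integer(n), 1L, 0L)
  best
}

# Small Gaussian point cloud helper
cloud2d <- function(n, cx, cy, s = 0.5) cbind(rnorm(n, cx, s), rnorm(n, cy, s))

# Long-format CSV writers matching the io_core readers
write_kinetic_csv <- function(traces, path) {
  d <- do.call(rbind, lapply(traces, function(tr)
    data.frame(condition = tr$condition, replicate = tr$replicate,
               time_h = tr$time, signal = tr$signal)))
  write.csv(d, path, row.names = FALSE)
}

write_plate_csv <- function(plate, path) {
  d <- as.data.frame(unclass(plate))
  write.csv(d[c("concentration_uM", "replicate", "absorbance")], path,
            row.names = FALSE)
}

write_stepfield_csv <- function(stepdata, path) {
  d <- do.call(rbind, lapply(stepdata$records, function(r)
    data.frame(delta_v = r$delta_v, t_a_ms = r$arrival_times,
               intensity = r$counts)))
  write.csv(d, path, row.names = FALSE)
}

write_frame_series_csv <- function(series, frames_path, uv_path = NULL) {
  wide <- data.frame(q = series$frames[[1]]$q)
  for (i in seq_along(series$frames))
    wide[[sprintf("frame%03d", i)]] <- series$frames[[i]]$intensity
  write.csv(wide, frames_path, row.names = FALSE)
  if (!is.null(uv_path)) write.csv(series$uv, uv_path, row.names = FALSE)
}
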