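inst10 <- ims_instrument(charge = 10, ion_mass_da = 20570)

test_that("noiseless step-field data round-trips (k0, t0) exactly", {
  sf <- ims_arrival(1.0, 2.0, c(400, 500, 600, 700, 800),
                    instrument = inst10)
  res <- ccs_pipeline(sf)
  expect_equal(res$k0, 1.0, tolerance = 1e-9)
  expect_equal(res$t0_ms, 2.0, tolerance = 1e-9)
  expect_equal(res$regression$r_squared, 1, tolerance = 1e-12)
  # full round trip: recovered CCS equals the direct conversion of k0
  expect_equal(res$ccs, mobility_to_ccs(1.0, inst10), tolerance = 1e-9)
})

test_that("regression handles two points, rejects one, ignores order", {
  pc <- data.frame(delta_v = c(400, 800), t_a_ms = c(20, 11))
  expect_warning(fit2 <- fit_stepfield(pc, inst10), "fewer than 5")
  expect_equal(fit2$regression$r_squared, 1)
  expect_error(fit_stepfield(pc[1, , drop = FALSE], inst10), "2 distinct")

  pc5 <- data.frame(delta_v = c(400, 500, 600, 700, 800),
                    t_a_ms = c(20, 17, 15, 13.5, 12.2))
  f1 <- fit_stepfield(pc5, inst10)
  f2 <- fit_stepfield(pc5[c(3, 1, 5, 2, 4), ], inst10)
  expect_equal(f1$k0, f2$k0, tolerance = 1e-14)

  bad <- data.frame(delta_v = c(400, 800), t_a_ms = c(11, 20))
  expect_error(suppressWarnings(fit_stepfield(bad, inst10)), "unphysical")
})

test_that("Mason-Schamp conversion matches the independent implementation", {
  # frozen dual-implementation reference: z = 10, 20570 Da, helium, 297 K
  ccs <- mobility_to_ccs(1.0, inst10)
  expect_equal(ccs, ccs_frozen_reference, tolerance = 1e-6)
  orc <- oracle_ccs_A2(1.0, 10, 20570, inst10$buffer_gas_mass_da,
                       inst10$temperature_K, inst10$pressure_Torr)
  expect_equal(ccs, orc, tolerance = 1e-9)

  # linear in charge at fixed K0
  inst20 <- ims_instrument(charge = 20, ion_mass_da = 20570)
  expect_equal(mobility_to_ccs(1.0, inst20) / ccs, 2, tolerance = 1e-12)

  # infinite-mass limit: mu -> m_gas
  inst_heavy <- ims_instrument(charge = 10, ion_mass_da = 1e12)
  mu_fin <- 20570 * 4.002602 / (20570 + 4.002602)
  expect_equal(mobility_to_ccs(1.0, inst_heavy) / ccs,
               sqrt(mu_fin / 4.002602), tolerance = 1e-6)

  expect_error(mobility_to_ccs(1.0, ims_instrument(charge = 10)),
               "masses must be set")
})

test_that("pinned physical constants match CODATA 2018", {
  expect_identical(ims_constants$e, 1.602176634e-19)
  expect_identical(ims_constants$kB, 1.380649e-23)
  expect_identical(ims_constants$da_kg, 1.66053906660e-27)
  expect_equal(ims_constants$N0, 2.686780111798444e25, tolerance = 1e-12)
})

test_that("CCS distribution reconstruction is anchored, symmetric, linear", {
  ta <- seq(10, 14, length.out = 201)
  counts <- exp(-(ta - 12)^2 / (2 * 0.25^2))
  d <- reconstruct_ccs_distribution(ta, counts, t0_ms = 2, ccs_peak = 5000)
  ipk <- which.max(d$intensity)
  expect_equal(d$ccs[ipk], 5000, tolerance = 1e-9)    # anchor point
  # symmetric ATD -> symmetric CCS distribution about the peak
  expect_equal(d$ccs[ipk] - d$ccs[1], d$ccs[nrow(d)] - d$ccs[ipk],
               tolerance = 1e-9)
  # the map is strictly linear in (tA - t0): ccs = a (tA - t0) with the
  # anchor-determined a, so doubling the drift offsets at fixed a (i.e.
  # with the peak CCS doubled too) doubles every CCS value
  a <- 5000 / (12 - 2)
  expect_equal(d$ccs, a * (ta - 2), tolerance = 1e-12)
  d2 <- reconstruct_ccs_distribution(2 + 2 * (ta - 2), counts, 2, 10000)
  expect_equal(d2$ccs, 2 * d$ccs, tolerance = 1e-9)
  expect_error(reconstruct_ccs_distribution(ta, counts, t0_ms = 20,
                                            ccs_peak = 5000), "precedes t0")
})

test_that("centroid vs maximum peak centers agree within the CCS uncertainty", {
  sf <- ims_arrival(1.0, 2.0, c(400, 500, 600, 700, 800),
                    instrument = inst10, noise_rel = 0.01, seed = 4)
  c1 <- ccs_pipeline(sf, peak_method = "centroid")
  c2 <- ccs_pipeline(sf, peak_method = "max")
  expect_lt(abs(c1$ccs - c2$ccs) / c1$ccs, c1$ccs_uncertainty_rel)
})

test_that("relative CCS uncertainty propagates and floors at 2%", {
  u <- ccs_uncertainty_rel(inst10)
  expect_equal(u, 0.02)                         # instrument terms < floor
  u2 <- ccs_uncertainty_rel(inst10, dL_cm = 4, dT_K = 1, dp_torr = 0.01)
  expect_gt(u2, 0.1)                            # large dL dominates: 2 dL/L
})

test_that("step-field CSV round-trips through the reader", {
  d <- withr::local_tempdir()
  sf <- ims_arrival(1.1, 1.8, c(400, 500, 600, 700, 800),
                    instrument = inst10)
  path <- file.path(d, "sf.csv")
  write_stepfield_csv(sf, path)
  back <- read_stepfield_csv(path, inst10)
  res <- ccs_pipeline(back)
  expect_equal(res$k0, 1.1, tolerance = 1e-9)
  expect_equal(res$t0_ms, 1.8, tolerance = 1e-9)
})
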