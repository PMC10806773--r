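test_that("Debye profile matches the closed form and is deterministic", {
  rg <- 3
  # x = (q rg)^2 = 1 at q = 1/rg: D = 2/e
  p <- debye_profile(rg, i0 = 1, q_grid = c(0, 1 / rg))
  expect_equal(p$intensity[1], 1)                     # D(0) = 1
  expect_equal(p$intensity[2], 2 * exp(-1), tolerance = 1e-12)
  expect_error(debye_profile(-1, 1, c(0.1)), "positive")

  a <- debye_profile(4, 2, seq(0.01, 1, length.out = 20), 0, seed = 1)
  b <- debye_profile(4, 2, seq(0.01, 1, length.out = 20), 0, seed = 99)
  expect_identical(a$intensity, b$intensity)          # noiseless: seed moot

  n1 <- debye_profile(4, 2, seq(0.01, 1, length.out = 20), 0.05, seed = 7)
  n2 <- debye_profile(4, 2, seq(0.01, 1, length.out = 20), 0.05, seed = 7)
  expect_identical(n1$intensity, n2$intensity)        # seeded noise reproducible
  expect_equal(n1$sigma, 0.05 * debye_profile(4, 2,
    seq(0.01, 1, length.out = 20))$intensity)
})

test_that("pivot SAW ensembles are self-avoiding and reproducible", {
  e <- saw_ensemble(10, 5, seed = 3)
  expect_length(e$walks, 5L)
  for (w in e$walks) {
    expect_equal(nrow(w), 10L)
    expect_equal(anyDuplicated(w), 0L)                # self-avoidance
    # successive beads are lattice neighbours
    expect_true(all(rowSums(abs(diff(w))) == 1L))
  }
  e2 <- saw_ensemble(10, 5, seed = 3)
  expect_identical(e$walks, e2$walks)
  expect_error(saw_ensemble(5, 5, seed = 1), ">= 10")
})

test_that("pivot sampler mean Rg^2 agrees with exact enumeration and a rejection sampler", {
  e <- saw_ensemble(10, 3000, seed = 21)
  rg2 <- ensemble_rg2(e)
  se <- sd(rg2) / sqrt(length(rg2))
  # exact enumeration of all 1,853,886 nine-step SAWs gives the reference
  expect_lt(abs(mean(rg2) - saw_exact_mean_rg2_n10), 4 * se)

  # independent uniform sampler (naive rejection) as a second oracle
  orc <- rejection_saw_rg2(10, 1500, seed = 5)
  se2 <- sqrt(se^2 + var(orc) / length(orc))
  expect_lt(abs(mean(rg2) - mean(orc)), 4 * se2)
})

test_that("ensemble scattering obeys the two-bead closed form and I(0)=1", {
  # hand-built 2-bead "ensemble": I(q) = (1/2)(1 + sin(qd)/(qd))
  d_nm <- 0.38
  ens <- structure(list(walks = list(matrix(c(0L, 1L, 0L, 0L, 0L, 0L), 2)),
                        n_beads = 2L, seed = 0L), class = "chain_ensemble")
  q <- c(0, 1, 2.5, 7)
  p <- scattering_from_ensemble(ens, q, bead_spacing_nm = d_nm)
  expected <- ifelse(q == 0, 1, 0.5 * (1 + sin(q * d_nm) / (q * d_nm)))
  expect_equal(p$intensity, expected, tolerance = 1e-12)

  e <- saw_ensemble(20, 10, seed = 2)
  p2 <- scattering_from_ensemble(e, c(0, 0.5, 1))
  expect_equal(p2$intensity[1], 1)                    # exact normalization
  expect_true(all(diff(p2$intensity) < 0))
})

test_that("Debye profile and ideal-chain limit of the form factor agree", {
  # mff at nu = 1/2 equals the Debye function (checked in test-mff); here
  # the generator pair: debye_profile vs an ideal-chain-like SAW at matched
  # Rg would need a non-self-avoiding walker, so instead assert the
  # generator's recorded truth is consistent with a Guinier fit
  p <- debye_profile(4, 1, seq(0.005, 0.2, length.out = 80))
  g <- guinier_fit(p, 1, 40)
  expect_equal(g$rg, 4, tolerance = 0.01)
  expect_equal(g$i0, 1, tolerance = 0.005)
})

test_that("SEC-SAXS generator obeys the virial relation", {
  cp <- elution_profile(0:59, 4e-4, 35, 6)
  q <- seq(0.02, 0.25, length.out = 40)
  # a2 = 0: I(0, c)/c constant; doubling c doubles I(0, c)
  fs0 <- sec_saxs_series(20570, 0, cp, q, 4)
  tr <- attr(fs0, "truth")
  nz <- which(cp$conc > 0)
  i0 <- vapply(nz, function(i)
    fs0$frames[[i]]$intensity[1] - tr$background, numeric(1))
  shape1 <- i0 / (tr$k_const * cp$conc[nz])          # = Mw * D(q1 rg)
  expect_equal(max(shape1) / min(shape1), 1, tolerance = 1e-12)

  # a2 > 0: c / I(0, c) strictly increasing in c
  fs1 <- sec_saxs_series(20570, 5e-4, cp, q, 4)
  i01 <- vapply(nz, function(i)
    fs1$frames[[i]]$intensity[1] - tr$background, numeric(1))
  ord <- order(cp$conc[nz])
  ratio <- (cp$conc[nz] / i01)[ord]
  expect_true(all(diff(ratio[!duplicated(cp$conc[nz][ord])]) > 0))

  expect_error(sec_saxs_series(20570, 0, data.frame(time = 1:20,
    conc = rep(0, 20)), q, 4), "identically zero")
  # UV trace mirrors concentration through Beer-Lambert
  expect_equal(fs0$uv$a280,
               2800 * (cp$conc * 1000 / 20570) * 1, tolerance = 1e-12)
})

test_that("ThT trace generator hits the sigmoid midpoint and plateau", {
  tg <- seq(0, 110, length.out = 111)
  tr <- tht_traces(f = 2, k_per_h = 0.3, t_half_h = 40, t_grid = tg,
                   noise_sd = 0, n_replicates = 2, seed = 1)
  s <- tr[[1]]$signal
  expect_equal(s[tg == 40], 1)                        # f/2 at t_half
  expect_equal(s[length(s)], 2, tolerance = 1e-9)     # -> f at late t
  expect_identical(tr[[1]]$signal, tr[[2]]$signal)    # noiseless replicates equal
  r1 <- tht_traces(seed = 8); r2 <- tht_traces(seed = 8)
  expect_identical(r1[[3]]$signal, r2[[3]]$signal)
  expect_error(tht_traces(t_half_h = 200, t_grid = tg), "within the time grid")
})

test_that("LLPS plate generator is reproducible and respects its contract", {
  p1 <- llps_plate(24, seed = 4); p2 <- llps_plate(24, seed = 4)
  expect_identical(p1$absorbance, p2$absorbance)
  expect_error(llps_plate(24, conc_list = c(0, 8, 16, 24)), "baseline set")
  expect_error(llps_plate(25, seed = 1), "tested concentrations")
  flat <- llps_plate(jump_au = 0, seed = 2)
  expect_true(is.na(attr(flat, "truth")$c_sat_um))
})

test_that("step-field generator centers regress exactly at zero noise", {
  inst <- ims_instrument(charge = 5, ion_mass_da = 20570)
  sf <- ims_arrival(1.2, 1.5, c(400, 500, 600, 700, 800), instrument = inst)
  truth <- attr(sf, "truth")
  centers <- vapply(sf$records, function(r)
    atd_peak_center(r$arrival_times, r$counts), numeric(1))
  dv <- vapply(sf$records, `[[`, numeric(1), "delta_v")
  fit <- lm(centers ~ I(1 / dv))
  expect_equal(coef(fit)[[1]], 1.5, tolerance = 1e-9)
  expect_equal(coef(fit)[[2]], 1000 * inst$drift_length_cm^2 / truth$K_raw,
               tolerance = 1e-6)
  expect_error(ims_arrival(1, 1, c(400, 500)), "5 drift voltages")
  a <- ims_arrival(1, 1, c(400, 500, 600, 700, 800), noise_rel = 0.02,
                   seed = 3)
  b <- ims_arrival(1, 1, c(400, 500, 600, 700, 800), noise_rel = 0.02,
                   seed = 3)
  expect_identical(a$records[[1]]$counts, b$records[[1]]$counts)
})

test_that("truth sidecars are written for generated data", {
  d <- withr::local_tempdir()
  p <- debye_profile(4, 1, seq(0.01, 0.5, length.out = 10))
  path <- file.path(d, "truth.json")
  write_truth(p, path)
  tr <- jsonlite::read_json(path)
  expect_equal(tr$rg_nm, 4)
  expect_equal(tr$nu, 0.5)
  expect_error(write_truth(list(), file.path(d, "x.json")), "no truth")
})
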