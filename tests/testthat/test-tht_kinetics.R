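test_that("min-max normalization and the reference-max variant behave", {
  tr <- kinetic_trace(1:4, c(2, 6, 10, 10))
  n <- normalize_trace(tr)
  expect_equal(n$signal, c(0, 0.5, 1, 1))

  flat <- kinetic_trace(1:4, rep(3, 4))
  expect_error(normalize_trace(flat), "flat trace")
  nf <- normalize_trace(flat, reference_max = 103)
  expect_true(all(nf$signal == 0))              # non-aggregating control
})

test_that("sigmoid fit recovers noiseless parameters and the midpoint identity", {
  tg <- seq(0, 110, length.out = 100)
  tr <- tht_traces(f = 1, k_per_h = 0.5, t_half_h = 40, t_grid = tg,
                   noise_sd = 0, n_replicates = 1)[[1]]
  fit <- fit_sigmoid(tr)
  expect_true(fit$converged)
  expect_equal(fit$f, 1, tolerance = 1e-6)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_equal(fit$t_half, 40, tolerance = 1e-6)
  # midpoint identity: the fitted curve at t_half equals F/2 exactly
  s_at_half <- fit$f / (1 + exp(-fit$k * (fit$t_half - fit$t_half)))
  expect_identical(s_at_half, fit$f / 2)

  down <- kinetic_trace(tg, rev(tr$signal))
  expect_false(fit_sigmoid(down)$converged)
})

test_that("fit is equivariant under time shifts and signal scaling", {
  tg <- seq(0, 110, length.out = 100)
  tr <- tht_traces(f = 1, k_per_h = 0.3, t_half_h = 50, t_grid = tg,
                   noise_sd = 0.03, n_replicates = 1, seed = 5)[[1]]
  base <- fit_sigmoid(tr)

  shifted <- kinetic_trace(tr$time + 7, tr$signal)
  fs <- fit_sigmoid(shifted)
  expect_equal(fs$t_half, base$t_half + 7, tolerance = 1e-4)
  expect_equal(fs$k, base$k, tolerance = 1e-5)
  expect_equal(fs$f, base$f, tolerance = 1e-6)

  scaled <- kinetic_trace(tr$time, tr$signal * 37 + 100)
  fn <- fit_sigmoid(normalize_trace(scaled))
  fn0 <- fit_sigmoid(normalize_trace(kinetic_trace(tr$time, tr$signal)))
  expect_equal(fn$t_half, fn0$t_half, tolerance = 1e-8)
  expect_equal(fn$k, fn0$k, tolerance = 1e-8)
  expect_equal(fn$f, fn0$f, tolerance = 1e-8)
})

test_that("replicate halftime statistics aggregate converged fits only", {
  mk <- function(th, cond, rep, conv = TRUE)
    structure(list(f = 1, k = 0.3, t_half = th, f_stderr = NA,
                   k_stderr = NA, t_half_stderr = NA, converged = conv,
                   condition = cond, replicate = rep),
              class = "sigmoid_fit")
  st <- halftime_stats(list(mk(40, "a", 1), mk(42, "a", 2), mk(44, "a", 3),
                            mk(NA, "b", 1, conv = FALSE),
                            mk(30, "c", 1)))
  a <- st[st$condition == "a", ]
  expect_equal(a$t_half_mean, 42)
  expect_equal(a$t_half_sd, 2)
  expect_equal(a$n_converged, 3L)

  b <- st[st$condition == "b", ]
  expect_equal(b$note, "no aggregation observed")
  expect_true(is.na(b$t_half_mean))

  cc <- st[st$condition == "c", ]
  expect_equal(cc$t_half_sd, 0)
  expect_equal(cc$note, "single replicate")
})

test_that("halftime is recovered within 2% at plate-reader noise", {
  errs <- vapply(1:50, function(s) {
    tr <- tht_traces(f = 1, k_per_h = 0.2, t_half_h = 40,
                     t_grid = seq(0, 110, length.out = 100),
                     noise_sd = 0.05, n_replicates = 3, seed = s)
    st <- halftime_stats(lapply(tr, fit_sigmoid))
    abs(st$t_half_mean - 40) / 40
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})
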