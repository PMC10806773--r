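sec_fixture <- function(a2, noise_rel = 0, seed = NULL) {
  cp <- elution_profile(0:79, 4.114e-4, center = 45, width = 8)
  fs <- sec_saxs_series(20570, a2, cp, seq(0.01, 0.3, length.out = 60), 4,
                        noise_rel = noise_rel, seed = seed)
  sel <- select_sec_frames(fs, "auto", threshold_frac = 0.1)
  list(fs = fs, sel = sel)
}

test_that("zero-noise A2 is recovered to 1e-9 relative for either sign", {
  for (a2_true in c(5e-4, -5e-4)) {
    fx <- sec_fixture(a2_true)
    pts <- extract_i0_series(fx$fs, fx$sel$sample_idx, fx$sel$buffer_idx)
    vf <- fit_virial(pts, 20570)
    expect_equal(vf$a2, a2_true, tolerance = 1e-9)
    expect_equal(vf$k_const * 5e-4 / 5e-4, vf$k_const)  # finite, sane
  }
})

test_that("a2 = 0 gives a flat c/I0 line and A2 within its stderr of zero", {
  fx <- sec_fixture(0, noise_rel = 0.02, seed = 11)
  pts <- suppressWarnings(
    extract_i0_series(fx$fs, fx$sel$sample_idx, fx$sel$buffer_idx))
  vf <- fit_virial(pts, 20570)
  expect_lt(abs(vf$a2), 2.5 * vf$a2_err)
})

test_that("A2 is invariant under intensity rescaling and frame relabeling", {
  fx <- sec_fixture(5e-4)
  pts <- extract_i0_series(fx$fs, fx$sel$sample_idx, fx$sel$buffer_idx)
  vf <- fit_virial(pts, 20570)

  pts2 <- pts; pts2$i0 <- pts2$i0 * 2          # instrument rescaling
  vf2 <- fit_virial(pts2, 20570)
  expect_equal(vf2$a2, vf$a2, tolerance = 1e-12)
  expect_equal(vf2$k_const, 2 * vf$k_const, tolerance = 1e-9)

  pts3 <- pts[sample.int(nrow(pts)), ]         # order must not matter
  expect_equal(fit_virial(pts3, 20570)$a2, vf$a2, tolerance = 1e-12)
})

test_that("inadequate concentration series are refused", {
  pts <- data.frame(c_gcm3 = c(1e-4, 1.2e-4, 1.3e-4),
                    i0 = c(1, 1.1, 1.2), i0_err = NA_real_)
  expect_error(fit_virial(pts, 20570), "span too small")
  expect_error(fit_virial(pts[1:2, ], 20570), "3 distinct")
})

test_that("zero-concentration frames are dropped from the i0 series", {
  fx <- sec_fixture(5e-4)
  # force a buffer frame into the sample list: it must be dropped
  expect_warning(
    pts <- extract_i0_series(fx$fs, c(2L, fx$sel$sample_idx),
                             fx$sel$buffer_idx),
    "dropped")
  expect_true(all(pts$c_gcm3 > 0))
})

test_that("UV lag compensation restores the no-lag pairing", {
  cp <- elution_profile(0:79, 4.114e-4, center = 45, width = 8)
  fs <- sec_saxs_series(20570, 5e-4, cp, seq(0.01, 0.3, length.out = 60), 4)
  sel <- select_sec_frames(fs, "auto", threshold_frac = 0.1)
  pts0 <- extract_i0_series(fs, sel$sample_idx, sel$buffer_idx)
  # shift the UV trace by +2 s, then undo it with the lag flag
  fs_lag <- fs
  fs_lag$uv$time <- fs_lag$uv$time + 2
  pts_lag <- extract_i0_series(fs_lag, sel$sample_idx, sel$buffer_idx,
                               lag_s = -2)
  expect_equal(pts_lag$c_gcm3, pts0$c_gcm3, tolerance = 1e-12)
  expect_equal(pts_lag$i0, pts0$i0, tolerance = 1e-12)
})
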