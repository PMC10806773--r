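make_frames <- function(n, q = seq(0.01, 0.5, length.out = 30),
                        base = NULL, sigma = NULL) {
  if (is.null(base)) base <- 100 * exp(-(q * 4)^2 / 3)
  lapply(seq_len(n), function(i) saxs_profile(q, base, sigma = sigma))
}

test_that("outlier rejection keeps identical frames and nails a spiked one", {
  frames <- make_frames(10)
  rep0 <- reject_outlier_frames(frames)
  expect_length(rep0$kept, 10L)                 # sd = 0 degenerate: keep all
  expect_length(rep0$rejected, 0L)

  spiked <- frames[[1]]
  spiked$intensity[15] <- spiked$intensity[15] * 2
  rep1 <- reject_outlier_frames(c(frames, list(spiked)))
  expect_identical(rep1$rejected, 11L)
  expect_error(reject_outlier_frames(frames[1:2]), "at least 3")
})

test_that("rejection threshold is monotone and order-equivariant", {
  q <- seq(0.01, 0.5, length.out = 25)
  set.seed(42)
  frames <- lapply(1:12, function(i)
    saxs_profile(q, 100 * exp(-(q * 4)^2 / 3) + rnorm(25, 0, i / 4)))
  k2 <- reject_outlier_frames(frames, threshold_sigmas = 2)$kept
  k3 <- reject_outlier_frames(frames, threshold_sigmas = 3)$kept
  expect_true(all(k2 %in% k3))                  # kept(2) subset of kept(3)

  perm <- c(5, 1, 12, 3, 8, 2, 11, 6, 10, 4, 7, 9)
  rp <- reject_outlier_frames(frames[perm])
  expect_setequal(perm[rp$rejected],
                  reject_outlier_frames(frames)$rejected)
})

test_that("frame averaging is exact and its sigma scales like 1/sqrt(n)", {
  q <- seq(0.01, 0.5, length.out = 20)
  f1 <- saxs_profile(q, rep(2, 20)); f3 <- saxs_profile(q, rep(6, 20))
  avg <- average_frames(list(f1, f3))
  expect_equal(avg$intensity, rep(4, 20))       # (I + 3I)/2 = 2I

  frames <- make_frames(5)
  expect_equal(average_frames(frames, 1:5)$intensity, frames[[1]]$intensity)

  # Monte-Carlo: n iid noisy frames with sd s average to sigma ~ s / sqrt(n)
  set.seed(7)
  s <- 0.5; n <- 100
  noisy <- lapply(seq_len(n), function(i)
    saxs_profile(q, 10 + rnorm(20, 0, s)))
  av <- average_frames(noisy)
  expect_equal(mean(av$sigma), s / sqrt(n), tolerance = 0.2)
  expect_error(average_frames(list(), integer(0)), "no frames")
})

test_that("buffer subtraction is exact, propagates sigma, and inverts", {
  q <- seq(0.01, 0.4, length.out = 15)
  s <- saxs_profile(q, 10 * exp(-q), sigma = rep(1, 15))
  b <- saxs_profile(q, rep(2, 15), sigma = rep(1, 15))
  sub <- subtract_buffer(s, b)
  expect_equal(sub$intensity, 10 * exp(-q) - 2)
  expect_equal(sub$sigma, rep(sqrt(2), 15))

  zero <- subtract_buffer(s, s)
  expect_true(all(zero$intensity == 0))

  # subtract then add back: bit-level identity for exact doubles
  back <- sub$intensity + b$intensity
  expect_identical(back, s$intensity)

  b2 <- saxs_profile(q[-1], rep(2, 14))
  expect_error(subtract_buffer(s, b2), "grids differ")
})

test_that("SEC frame selection finds the UV peak and places buffer before it", {
  cp <- elution_profile(0:59, 4e-4, 35, 6)
  fs <- sec_saxs_series(20570, 0, cp, seq(0.02, 0.3, length.out = 30), 4)
  sel <- select_sec_frames(fs, "auto")
  peak_frame <- which.max(fs$uv$a280)
  expect_true(min(sel$sample_idx) < peak_frame &&
              max(sel$sample_idx) > peak_frame)
  expect_true(max(sel$buffer_idx) < min(sel$sample_idx))
  expect_true(all(cp$conc[sel$buffer_idx] == 0))

  man <- select_sec_frames(fs, "manual", sample_idx = 30:40,
                           buffer_idx = 5:14)
  expect_identical(man$sample_idx, 30:40)
  expect_identical(man$buffer_idx, 5:14)

  flat <- frame_series(make_frames(12), uv = data.frame(time = 0:11,
                                                        a280 = rep(0.1, 12)))
  expect_error(select_sec_frames(flat, "auto"), "no UV peak")
})

test_that("UV absorbance converts to molar and mass concentration", {
  # A = 0.056 at eps = 2800, path 1 cm -> 20 uM
  expect_equal(uv_to_concentration(0.056, 2800, 1), 20e-6)
  expect_equal(uv_to_concentration(0, 2800, 1), 0)
  expect_warning(c_neg <- uv_to_concentration(-0.01, 2800, 1), "clamped")
  expect_equal(c_neg, 0)
  # 20 uM at Mw 20570 Da -> 4.114e-4 g/cm^3
  expect_equal(molar_to_gcm3(20e-6, 20570), 4.114e-4)
})

test_that("noiseless batch reduction reproduces the generator profile exactly", {
  q <- seq(0.01, 0.6, length.out = 40)
  p <- debye_profile(4.2, 10, q)
  frames <- lapply(1:8, function(i) p)
  rep0 <- reject_outlier_frames(frames)
  avg <- average_frames(frames, rep0$kept)
  expect_equal(avg$intensity, p$intensity, tolerance = 1e-15)
})
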