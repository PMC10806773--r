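test_that("the t-test ladder finds a constructed onset, checked by hand", {
  plate <- llps_plate(c_sat_um = 24, baseline_au = 0.05, jump_au = 0.3,
                      noise_sd = 0.001, n_replicates = 3, seed = 2)
  res <- determine_csat(plate)
  expect_true(res$detected)
  expect_equal(res$c_sat, 24)

  # hand-computed Welch t tests on the same plate confirm every rung
  d <- as.data.frame(plate)
  base <- d$absorbance[d$concentration_uM %in% c(0, 4, 8, 12)]
  for (cc in c(16, 20, 24, 28)) {
    grp <- d$absorbance[d$concentration_uM == cc]
    m1 <- mean(grp); m2 <- mean(base)
    v1 <- var(grp) / length(grp); v2 <- var(base) / length(base)
    tstat <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(grp) - 1) + v2^2 / (length(base) - 1))
    p_manual <- 2 * pt(-abs(tstat), df)
    expect_equal(unname(res$p_values[as.character(cc)]), p_manual,
                 tolerance = 1e-12)
  }
  expect_true(all(res$p_values[c("16", "20")] >= 0.05))
  expect_lt(res$p_values[["24"]], 0.05)
})

test_that("a flat plate yields no detection and degenerate plates warn", {
  # fixed seed: any single null plate false-detects with the probability
  # of the uncorrected ladder (~0.3); the type-I behaviour over many
  # plates is asserted in the acceptance suite
  flat <- llps_plate(jump_au = 0, noise_sd = 0.001, seed = 1)
  res <- determine_csat(flat)
  expect_false(res$detected)
  expect_true(is.na(res$c_sat))

  # all absorbances identical: zero variance everywhere
  exact <- plate_data(rep(seq(0, 40, 4), each = 3), rep(1:3, 11),
                      rep(0.05, 33))
  expect_warning(res0 <- determine_csat(exact), "degenerate")
  expect_false(res0$detected)
})

test_that("plate preconditions are enforced", {
  p <- llps_plate(24, n_replicates = 3, seed = 1)
  d <- as.data.frame(p)
  two_reps <- d[d$replicate <= 2, ]
  expect_error(determine_csat(plate_data(two_reps$concentration_uM,
                                         two_reps$replicate,
                                         two_reps$absorbance)),
               ">= 3 replicates")
  no_base <- d[d$concentration_uM != 8, ]
  expect_error(determine_csat(plate_data(no_base$concentration_uM,
                                         no_base$replicate,
                                         no_base$absorbance)),
               "baseline")
})

test_that("larger jumps never raise the detected onset", {
  for (seed in 1:10) {
    csats <- vapply(c(0.05, 0.15, 0.45), function(j) {
      pl <- llps_plate(c_sat_um = 24, jump_au = j, noise_sd = 0.02,
                       seed = seed)
      r <- determine_csat(pl)
      if (r$detected) r$c_sat else Inf
    }, numeric(1))
    expect_true(all(diff(csats) <= 0))
  }
})

test_that("the ladder is deterministic given the plate", {
  pl <- llps_plate(28, seed = 9)
  r1 <- determine_csat(pl); r2 <- determine_csat(pl)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$c_sat, r2$c_sat)
})
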