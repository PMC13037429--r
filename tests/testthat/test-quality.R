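# minimal recording wrapper around an intensity matrix
mk_rec <- function(I, fs = 10) {
  hm <- .fix$model()
  structure(list(fs = fs, t = seq(0, by = 1 / fs,
                                  length.out = ncol(I)),
                 intensity = I, channels = hm$montage$channels, I0 = 1),
            class = "dot_recording")
}

test_that("range and SNR pruning follow the stated bounds", {
  n <- 600
  I <- matrix(1, 128, n)                       # constant: kept
  I[2, ] <- 1e-5                               # below dRange
  set.seed(1)
  I[3, ] <- 2 + rnorm(n, sd = 4)               # SNR ~ 0.5
  m <- prune_channels(mk_rec(I))
  expect_true(m$good[1])
  expect_false(m$good[2]); expect_equal(m$reason[2], "range")
  expect_false(m$good[3]); expect_equal(m$reason[3], "snr")
  # a pair is usable only when both wavelengths pass
  expect_false(m$pair_good[2])
  expect_false(m$pair_good[64 + 2 - 64])       # same pair index
  expect_error(prune_channels(mk_rec(I[, 1:100])), "30 s")
})

test_that("PSD flags respond to in-band peaks only", {
  n <- 3000
  tt <- seq(0, by = 0.1, length.out = n)
  base <- matrix(1, 128, n)
  m0 <- psd_flags(mk_rec(base))
  expect_true(all(m0$good))
  # amplitude calibrated through the estimator: a 2.5%-of-baseline tone
  # at 3.5 Hz exceeds the 0.01 power/Hz threshold in the 3-4 Hz band
  I <- base
  I[5, ] <- 1 + 0.025 * sin(2 * pi * 3.5 * tt)
  I[6, ] <- 1 + 0.025 * sin(2 * pi * 4.5 * tt)  # outside both bands
  m <- psd_flags(mk_rec(I))
  expect_false(m$good[5])
  expect_equal(m$reason[5], "psd_high_band")
  expect_true(m$good[6])
  # flags invariant under constant offset (estimator demeans)
  I2 <- I + 0.5
  m2 <- psd_flags(mk_rec(I2))
  expect_equal(m2$good, m$good)
  # low-band reason code
  I3 <- base
  I3[7, ] <- 1 + 0.1 * sin(2 * pi * 0.5 * tt)
  m3 <- psd_flags(mk_rec(I3))
  expect_equal(m3$reason[7], "psd_low_band")
})

test_that("welch estimator recovers the density of a known sinusoid", {
  tt <- seq(0, by = 0.1, length.out = 3000)
  x <- 0.05 * sin(2 * pi * 1 * tt)
  p <- welch_psd(x, fs = 10)
  # peak at 1 Hz, integrated power ~ A^2/2
  expect_equal(p$freq[which.max(p$psd)], 1, tolerance = 0.02)
  df <- diff(p$freq[1:2])
  expect_equal(sum(p$psd) * df, 0.05^2 / 2, tolerance = 0.1)
  # matrix and vector paths agree
  pm <- glucodot:::.welch_psd_mat(rbind(x, x), 10)
  expect_equal(pm$psd[1, ], p$psd)
})

test_that("coverage threshold implements both formula readings", {
  expect_equal(coverage_threshold(coverage_params(pthresh = 0, vhat = 125)),
               0)
  # independent hand evaluation: ln(1.01) / ((10/125) * 0.001)
  p <- coverage_params(pthresh = 1, actvol = 10, vhat = 125, dmua = 0.001)
  expect_equal(coverage_threshold(p), log(1.01) / ((10 / 125) * 0.001),
               tolerance = 1e-12)
  p2 <- coverage_params(actvol = 20, vhat = 125)
  expect_equal(coverage_threshold(p2), coverage_threshold(p) / 2)
  pm <- coverage_params(vhat = 125, reading = "multiply")
  expect_equal(coverage_threshold(pm), log(1.01) * (10 / 125) * 0.001)
  expect_error(coverage_params(actvol = -1), "positive")
})

test_that("sensitivity map equals brute-force summation over good pairs", {
  hm <- .fix$model()
  ch <- glucodot:::.channel_table(hm$jac)
  all_bad <- channel_mask(rep(FALSE, 128), channels = ch)
  expect_warning(m0 <- sensitivity_map(hm$jac, all_bad), "all channels bad")
  expect_equal(m0$sensitivity, rep(0, nrow(hm$head$vol)))
  one <- channel_mask(c(rep(TRUE, 1), rep(FALSE, 63)) [c(1:64, 1:64)],
                      channels = ch)
  m1 <- sensitivity_map(hm$jac, one)
  expect_equal(m1$sensitivity, abs(hm$jac$J[["850"]][1, ]))
  set.seed(3)
  for (i in 1:5) {
    good_pairs <- runif(64) < 0.5
    mk <- channel_mask(rep(good_pairs, 2), channels = ch)
    ms <- suppressWarnings(sensitivity_map(hm$jac, mk))
    brute <- colSums(abs(hm$jac$J[["850"]])[good_pairs, , drop = FALSE])
    expect_equal(ms$sensitivity, brute)
  }
})

test_that("ROI mean sensitivity equals brute-force sphere means", {
  hm <- .fix$model()
  nvol <- nrow(hm$head$vol)
  uni <- structure(list(sensitivity = rep(3.5, nvol), n_channels = 64),
                   class = "sensitivity_map")
  expect_equal(unname(roi_mean_sensitivity(uni, hm$head)), rep(3.5, 9))
  zero <- structure(list(sensitivity = rep(0, nvol), n_channels = 64),
                    class = "sensitivity_map")
  expect_equal(unname(roi_mean_sensitivity(zero, hm$head)), rep(0, 9))
  set.seed(4)
  v <- runif(nvol)
  rm <- structure(list(sensitivity = v, n_channels = 64),
                  class = "sensitivity_map")
  got <- roi_mean_sensitivity(rm, hm$head)
  for (j in 1:9) {
    d <- sqrt(colSums((t(hm$head$vol) - hm$head$landmarks[j, ])^2))
    expect_equal(unname(got[j]), mean(v[d <= 15]))
  }
})

test_that("window selection breaks ties to the earliest start", {
  hm <- .fix$model()
  spec0 <- connectivity_spec(hbo_amp = 0, hbr_ratio = 0)
  rec <- gen_dot_recording(hm$head, hm$jac, spec0, duration_s = 600,
                           seed = 1, noise_cv = 0)
  cov <- coverage_params(vhat = hm$head$node_volume_mm3,
                         reading = "multiply")
  wc <- select_best_window(rec, c(0, 10), hm$jac, hm$head, cov = cov)
  expect_equal(wc$start_min, 0)
  expect_true(wc$feasible)
  expect_equal(wc$n_covered, 9)
  expect_error(select_best_window(rec, c(0, 4), hm$jac, hm$head, cov = cov),
               "span")
})

test_that("infeasible coverage falls back with the flag lowered", {
  hm <- .fix$model()
  spec0 <- connectivity_spec(hbo_amp = 0, hbr_ratio = 0)
  rec <- gen_dot_recording(hm$head, hm$jac, spec0, duration_s = 600,
                           seed = 2, noise_cv = 0)
  # the faithful "divide" reading is unattainable on this model
  cov <- coverage_params(vhat = hm$head$node_volume_mm3)
  wc <- select_best_window(rec, c(0, 10), hm$jac, hm$head, cov = cov)
  expect_false(wc$feasible)
  expect_equal(wc$start_min, 0)
  expect_lt(wc$n_covered, 9)
})

test_that("adding a good channel never lowers sensitivity anywhere", {
  hm <- .fix$model()
  ch <- glucodot:::.channel_table(hm$jac)
  set.seed(5)
  for (i in 1:5) {
    pairs <- runif(64) < 0.4
    more <- pairs; more[sample(which(!pairs), 1)] <- TRUE
    m1 <- suppressWarnings(sensitivity_map(hm$jac,
      channel_mask(rep(pairs, 2), channels = ch)))
    m2 <- sensitivity_map(hm$jac, channel_mask(rep(more, 2), channels = ch))
    expect_true(all(m2$sensitivity >= m1$sensitivity))
    if (any(pairs)) {
      r1 <- roi_mean_sensitivity(m1, hm$head)
      r2 <- roi_mean_sensitivity(m2, hm$head)
      expect_true(all(r2 >= r1 - 1e-12))
    }
  }
})
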