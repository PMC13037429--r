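test_that("ROI labels are unique with lateral precedence", {
  hm <- .fix$model()
  head <- hm$head
  nsurf <- nrow(head$surface)
  rois <- build_rois(head, rep(1, nsurf), cthresh = 0.5)
  # uniform sensitivity above threshold: all included
  expect_true(all(vapply(rois$rois, `[[`, logical(1), "included")))
  # no node carries two labels
  all_members <- unlist(lapply(rois$rois, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)
  # nodes in both a central and a lateral sphere go lateral
  d2 <- glucodot:::.pairwise_dist2(head$surface, head$landmarks)
  overlap <- which(d2[, "FZ"] <= 225 & d2[, "F4"] <= 225)
  if (length(overlap) > 0)
    expect_true(all(overlap %in% rois$rois[["F4"]]$members))
  expect_false(any(overlap %in% rois$rois[["FZ"]]$members))
})

test_that("sensitivity gates ROI inclusion via the one-third rule", {
  hm <- .fix$model()
  head <- hm$head
  nsurf <- nrow(head$surface)
  expect_equal(unname(roi_mean_sensitivity(
    structure(list(sensitivity = rep(0, nrow(head$vol)), n_channels = 0),
              class = "sensitivity_map"), head))[1], 0)
  # zero sensitivity inside P3's sphere only: P3 excluded, others stay
  sens <- rep(1, nsurf)
  d2 <- glucodot:::.pairwise_dist2(head$surface, head$landmarks)
  sens[d2[, "P3"] <= 225] <- 0
  rois <- build_rois(head, sens, cthresh = 0.5)
  inc <- vapply(rois$rois, `[[`, logical(1), "included")
  expect_false(inc[["P3"]])
  expect_true(all(inc[setdiff(names(inc), "P3")]))
})

test_that("ROI time courses average covered nodes and propagate NA", {
  hm <- .fix$model()
  head <- hm$head
  nsurf <- nrow(head$surface)
  rois <- build_rois(head, rep(1, nsurf), cthresh = 0.5)
  s <- sin(seq(0, 4 * pi, length.out = 200))
  series <- matrix(rep(s, each = nsurf), nsurf, 200)
  tc <- roi_timecourses(series, rois)
  for (j in 1:9) expect_equal(unname(tc[j, ]), s)
  # excluded ROI rows are missing
  sens <- rep(1, nsurf); sens[rois$rois[["CZ"]]$members] <- 0
  rois2 <- build_rois(head, sens, cthresh = 0.5)
  tc2 <- roi_timecourses(series, rois2)
  expect_true(all(is.na(tc2["CZ", ])))
  # random fields equal brute-force means over covered nodes
  set.seed(31)
  rf <- matrix(rnorm(nsurf * 50), nsurf, 50)
  tc3 <- roi_timecourses(rf, rois)
  for (j in c(1, 5, 9)) {
    cov_nodes <- rois$rois[[j]]$covered
    expect_equal(unname(tc3[j, ]),
                 colMeans(rf[cov_nodes, , drop = FALSE]))
  }
})

test_that("connectivity matrices are symmetric with the clipped transform", {
  tt <- seq(0, 299.9, by = 0.1)
  courses <- matrix(NA_real_, 9, 3000,
                    dimnames = list(c("F3", "FZ", "F4", "C3", "CZ", "C4",
                                      "P3", "PZ", "P4"), NULL))
  courses["F3", ] <- sin(2 * pi * 0.05 * tt)
  courses["FZ", ] <- sin(2 * pi * 0.05 * tt)           # identical
  courses["F4", ] <- cos(2 * pi * 0.05 * tt)           # orthogonal
  courses["C3", ] <- rnorm(3000)
  m <- tffc_matrix(courses)
  expect_equal(m$R["F3", "FZ"], 1)
  expect_equal(m$Z["F3", "FZ"], atanh(1 - 1e-7))
  expect_equal(m$R["F3", "F4"], 0, tolerance = 1e-6)
  expect_equal(m$Z["F3", "F4"], 0, tolerance = 1e-6)
  expect_equal(m$R, t(m$R))
  expect_true(all(is.na(m$R["CZ", ])))                 # excluded ROI
  expect_equal(diag(m$R)[c("F3", "FZ", "F4", "C3")],
               c(F3 = 1, FZ = 1, F4 = 1, C3 = 1))
  courses["C4", ] <- 5                                  # zero variance
  expect_warning(m2 <- tffc_matrix(courses), "zero-variance")
  expect_true(all(is.na(m2$R["C4", ])))
  expect_error(tffc_matrix(courses[, 1:50]), "100 samples")
})

test_that("group t equals the closed form and the t-test oracle", {
  g <- group_t(c(0.5, 0.7, 0.9))
  expect_equal(unname(g["t"]), 0.7 / (0.2 / sqrt(3)), tolerance = 1e-10)
  expect_equal(unname(g["t"]), 6.0621778, tolerance = 1e-6)
  expect_equal(unname(group_t(c(-0.4, 0.4))["t"]), 0)
  set.seed(32)
  for (i in 1:20) {
    z <- rnorm(sample(3:15, 1), sd = 0.5)
    got <- group_t(z)
    tt <- t.test(z)
    expect_equal(unname(got["t"]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(got["p"]), tt$p.value, tolerance = 1e-10)
  }
  # missing values dropped with n adjusted
  expect_equal(unname(group_t(c(0.5, 0.7, 0.9, NA))["n"]), 3)
  expect_equal(unname(group_t(c(0.3, 0.3, 0.3))["t"]), Inf)
  expect_error(group_t(c(0, 0)), "degenerate")
})

test_that("window comparison matches an independent two-sample oracle", {
  set.seed(33)
  z <- matrix(rnorm(12 * 36, sd = 0.4), 12, 36,
              dimnames = list(NULL, paste0("p", 1:36)))
  same <- window_comparison(z, z)
  expect_equal(same$t, rep(0, 36))
  expect_equal(same$p, rep(1, 36))
  shifted <- window_comparison(z, z + 3)
  expect_true(all(shifted$p < 1e-8))
  z2 <- matrix(rnorm(12 * 36, sd = 0.4), 12, 36,
               dimnames = list(NULL, paste0("p", 1:36)))
  got <- window_comparison(z, z2)
  for (j in c(1, 17, 36)) {
    tt <- t.test(z2[, j], z[, j], var.equal = TRUE)
    expect_equal(got$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$p[j], tt$p.value, tolerance = 1e-10)
  }
  paired <- window_comparison(z, z2, variant = "paired")
  tt <- t.test(z2[, 1], z[, 1], paired = TRUE)
  expect_equal(paired$t[1], unname(tt$statistic), tolerance = 1e-10)
})

test_that("BH adjustment reproduces hand and degenerate cases", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
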