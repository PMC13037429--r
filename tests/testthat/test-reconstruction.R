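test_that("tikhonov pseudoinverse matches closed-form small systems", {
  expect_equal(tikhonov_pseudoinverse(diag(4), lambda = 0), diag(4))
  # 2x3 system by hand: J J^T = diag(1,4), smax = 4,
  # J# = J^T diag(1/(1+0.4), 1/(4+0.4))
  J <- rbind(c(1, 0, 0), c(0, 2, 0))
  got <- tikhonov_pseudoinverse(J, lambda = 0.1)
  want <- t(J) %*% diag(c(1 / 1.4, 1 / 4.4))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(tikhonov_pseudoinverse(matrix(0, 2, 3)), "zero")
})

test_that("tikhonov limit recovers the Moore-Penrose pseudoinverse", {
  set.seed(21)
  J <- matrix(rnorm(20 * 50), 20, 50)
  got <- tikhonov_pseudoinverse(J, lambda = 1e-12)
  expect_equal(got, MASS::ginv(J), tolerance = 1e-6)
})

test_that("tikhonov residual identity holds on random systems", {
  set.seed(22)
  for (i in 1:5) {
    J <- matrix(rnorm(20 * 50), 20, 50)
    lam <- 0.1
    Js <- tikhonov_pseudoinverse(J, lam)
    JJt <- J %*% t(J)
    smax <- max(eigen(JJt, symmetric = TRUE, only.values = TRUE)$values)
    lhs <- (JJt + lam * smax * diag(20)) %*% t(Js)
    expect_equal(lhs, J, tolerance = 1e-8)
  }
})

test_that("absorption reconstruction is linear and shape-checked", {
  set.seed(23)
  J <- matrix(rnorm(10 * 30), 10, 30)
  Js <- tikhonov_pseudoinverse(J, 0.1)
  expect_equal(reconstruct_mua(Js, matrix(0, 10, 5)), matrix(0, 30, 5))
  x <- matrix(rnorm(50), 10, 5); y <- matrix(rnorm(50), 10, 5)
  expect_equal(reconstruct_mua(Js, 2 * x + 3 * y),
               2 * reconstruct_mua(Js, x) + 3 * reconstruct_mua(Js, y),
               tolerance = 1e-12)
  expect_error(reconstruct_mua(Js, matrix(0, 11, 5)), "mismatch")
})

test_that("planted blobs are localized near their true position", {
  hm <- .fix$model()
  head <- hm$head
  depth <- 44 - sqrt(rowSums(head$vol^2))
  cand <- which(depth > 6 & depth < 11 & head$vol[, 3] > 22)
  Js <- tikhonov_pseudoinverse(hm$jac$J[["850"]], 0.1)
  set.seed(24)
  ok <- 0
  for (s in 1:10) {
    node <- sample(cand, 1)
    dmua <- numeric(nrow(head$vol)); dmua[node] <- 0.001
    rec <- reconstruct_mua(Js, hm$jac$J[["850"]] %*% dmua)
    peak <- which.max(abs(rec[, 1]))
    d <- sqrt(sum((head$vol[peak, ] - head$vol[node, ])^2))
    if (d <= 2 * head$grid_mm) ok <- ok + 1
    # regularized reconstruction underestimates the planted peak
    expect_lte(max(abs(rec[, 1])), 0.001)
  }
  expect_gte(ok, 9)
})

test_that("hemoglobin unmixing inverts the extinction system exactly", {
  E <- log(10) * extinction_defaults()
  hb <- unmix_hemoglobin(matrix(E[1, 1]), matrix(E[2, 1]))
  expect_equal(hb$HbO[1, 1], 1, tolerance = 1e-12)
  expect_equal(hb$HbR[1, 1], 0, tolerance = 1e-12)
  v <- E %*% c(2, -1)
  hb2 <- unmix_hemoglobin(matrix(v[1]), matrix(v[2]))
  expect_equal(c(hb2$HbO, hb2$HbR), c(2, -1), tolerance = 1e-12)
  set.seed(25)
  A <- matrix(rnorm(40), 20, 2)
  mixed <- A %*% t(E)
  hb3 <- unmix_hemoglobin(matrix(mixed[, 1]), matrix(mixed[, 2]))
  expect_equal(cbind(hb3$HbO, hb3$HbR), A, tolerance = 1e-10)
})

test_that("surface mapping averages the 3-mm neighborhoods", {
  hm <- .fix$model()
  head <- hm$head
  nvol <- nrow(head$vol)
  uni <- map_to_surface(rep(2.5, nvol), head)
  expect_equal(uni$values[, 1], rep(2.5, nrow(head$surface)))
  set.seed(26)
  v <- rnorm(nvol)
  got <- map_to_surface(v, head)
  for (i in sample(nrow(head$surface), 20)) {
    d <- sqrt(colSums((t(head$vol) - head$surface[i, ])^2))
    idx <- which(d <= 3)
    want <- if (length(idx) == 0) v[which.min(d)] else mean(v[idx])
    expect_equal(got$values[i, 1], want)
    expect_equal(got$fallback[i], length(idx) == 0)
  }
  # two-neighbor arithmetic mean on a hand-built model
  tiny <- head
  tiny$surface <- matrix(c(0, 0, 30), 1)
  tiny$vol <- rbind(c(0, 0, 31), c(0, 0, 29))
  expect_equal(map_to_surface(c(1, 3), tiny)$values[1, 1], 2)
})

test_that("the reconstruction chain is time-separable", {
  hm <- .fix$model()
  spec <- connectivity_spec(roi_corr = glucodot:::.baseline_roi_corr(hm$head))
  rec <- gen_dot_recording(hm$head, hm$jac, spec, duration_s = 30, seed = 27)
  od <- intensity_to_od(rec)
  rr <- reconstruct_window(od, hm$jac, hm$head)
  perm <- sample(ncol(od$od))
  odp <- od; odp$od <- od$od[, perm]
  rrp <- reconstruct_window(odp, hm$jac, hm$head)
  expect_equal(rrp$HbO, rr$HbO[, perm], tolerance = 1e-12)
})
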