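test_that("Welch PSD obeys Parseval, locates peaks, and rejects short input", {
  expect_error(welchPsd(rnorm(100), 100), "too short")

  w0 <- welchPsd(numeric(3000), 100)
  expect_true(all(w0$psd == 0))

  set.seed(11)
  x <- rnorm(3000)
  w <- welchPsd(x, 100)
  df <- w$freq[2] - w$freq[1]
  expect_lt(abs(sum(w$psd) * df / var(x) - 1), 0.05)

  s <- sin(2 * pi * 10 * seq_len(3000) / 100)
  ws <- welchPsd(s, 100)
  expect_equal(ws$freq[which.max(ws$psd)], 10)
})

test_that("band features integrate the canonical bands", {
  f <- seq(0, 40, by = 0.25)
  # all power inside theta (4-8 Hz)
  p <- ifelse(f > 4 & f < 8, 1, 0)
  bf <- bandFeatures(f, p)
  expect_gt(bf[["theta_power"]], 0)
  expect_equal(unname(bf[c("delta_power", "alpha_power", "beta_power",
                           "gamma_power")]), rep(0, 4))
  expect_equal(bf[["beta_theta_ratio"]], 0)

  # flat density c: rectangle integrals
  c0 <- 2.5
  bfl <- bandFeatures(f, rep(c0, length(f)))
  expect_equal(unname(bfl[paste0(c("delta", "theta", "alpha", "beta", "gamma"),
                                 "_power")]),
               c0 * c(3.5, 4, 5, 17, 5))
  expect_equal(bfl[["fast_slow_ratio"]], 22 / 7.5)
  expect_equal(unname(bfl[paste0(c("delta", "theta", "alpha", "beta", "gamma"),
                                 "_density")]), rep(c0, 5))

  bands <- attr(bfl, "bands")
  expect_equal(unname(unlist(bands)), c(0.5, 4, 4, 8, 8, 13, 13, 30, 30, 35))

  expect_error(bandFeatures(seq(0, 20, 0.25), rep(1, 81)), "0.5-35")
})

test_that("band features are positively homogeneous in the PSD", {
  set.seed(3)
  f <- seq(0, 50, by = 0.25)
  p <- abs(rnorm(length(f)))
  b1 <- bandFeatures(f, p)
  b3 <- bandFeatures(f, 3 * p)
  pow <- grepl("power|density", names(b1))
  expect_equal(unname(b3[pow]), unname(3 * b1[pow]))
  expect_equal(unname(b3[!pow]), unname(b1[!pow]), tolerance = 1e-9)
})

test_that("subject features are the mean of per-epoch features", {
  set.seed(4)
  fs <- 80
  e1 <- rnorm(30 * fs)
  rec1 <- new("EpochedRecording", X = rbind(e1, e1, e1),
              labels = factor(rep("N2", 3), levels = STAGES), fs = fs,
              epochLen = 30, subjectId = "a")
  w <- welchPsd(e1, fs)
  expect_equal(unname(subjectFeatures(rec1)),
               unname(bandFeatures(w$freq, w$psd)))

  e2 <- rnorm(30 * fs)
  rec2 <- new("EpochedRecording", X = rbind(e1, e2),
              labels = factor(c("N2", "N3"), levels = STAGES), fs = fs,
              epochLen = 30, subjectId = "b")
  w2 <- welchPsd(e2, fs)
  expect_equal(unname(subjectFeatures(rec2)),
               unname((bandFeatures(w$freq, w$psd) +
                       bandFeatures(w2$freq, w2$psd)) / 2))
})

test_that("a delta-dominant synthetic subject has delta as top band power", {
  prof <- defaultStageProfiles()$N3
  fs <- 80
  X <- t(vapply(1:6, function(i) synthEpoch(prof, fs, seed = 60 + i),
                numeric(30 * fs)))
  rec <- new("EpochedRecording", X = X,
             labels = factor(rep("N3", 6), levels = STAGES), fs = fs,
             epochLen = 30, subjectId = "n3")
  sf <- subjectFeatures(rec)
  pow <- sf[paste0(c("delta", "theta", "alpha", "beta", "gamma"), "_power")]
  expect_equal(names(which.max(pow)), "delta_power")
})

test_that("PCA eigenvalues match an independent SVD oracle", {
  set.seed(12)
  X <- matrix(rnorm(20 * 13), 20, 13) %*% diag(seq(0.2, 3, length.out = 13))
  model <- fitPca(X, U = 5)
  # oracle: singular values of the centred, scaled matrix
  Z <- scale(X)
  lam <- svd(Z)$d^2 / (nrow(X) - 1)
  expect_equal(model@eigenvalues, lam, tolerance = 1e-8)
  expect_equal(model@roi, sum(lam[1:5]) / sum(lam), tolerance = 1e-10)
})

test_that("PCA handles degenerate shapes and warns on constant columns", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fitPca(X[1, , drop = FALSE]), "at least 2")
  expect_error(fitPca(X, U = 3), "between 1 and 2")
  Xc <- cbind(X, 7)
  expect_warning(fitPca(Xc, U = 1), "constant")
})

test_that("rank-1 data is fully retained by one component", {
  t <- seq(-2, 2, length.out = 9)
  X <- outer(t, c(1, -2, 0.5, 3)) + 5
  model <- fitPca(X, U = 1)
  expect_equal(model@roi, 1, tolerance = 1e-9)
  # reconstruction of z-scored data from the single component
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  proj <- pcaTransform(model, X)
  expect_equal(proj %*% t(model@components), Z, tolerance = 1e-8)
})

test_that("transform centres the mean and decorrelates training data", {
  set.seed(13)
  X <- matrix(rnorm(30 * 13), 30, 13)
  model <- fitPca(X, U = 4)
  expect_equal(unname(pcaTransform(model, colMeans(X))), rep(0, 4))
  Y <- pcaTransform(model, X)
  offDiag <- cov(Y) - diag(diag(cov(Y)))
  expect_lt(max(abs(offDiag)), 1e-8)
  expect_identical(pcaTransform(model, X[1, ]), pcaTransform(model, X[1, ]))
  expect_error(pcaTransform(model, rnorm(5)), "does not match")
})

test_that("retained information is exact, monotone and bounded", {
  expect_equal(retainedInformation(c(4, 3, 2, 1), 3), 0.9)
  expect_equal(retainedInformation(rep(2, 10), 3), 0.3)
  expect_equal(retainedInformation(c(5, 1), 2), 1)
  set.seed(14)
  for (rep in 1:25) {
    lam <- sort(rexp(sample(3:13, 1)), decreasing = TRUE)
    rois <- vapply(seq_along(lam), function(U) retainedInformation(lam, U),
                   numeric(1))
    expect_true(all(diff(rois) >= -1e-12))
    expect_equal(rois[length(lam)], 1)
  }
  expect_error(retainedInformation(c(3, 2), 3), "between 1 and")
  expect_error(retainedInformation(c(0, 0), 1), "zero")
})
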