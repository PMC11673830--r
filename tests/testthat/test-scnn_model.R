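test_that("config validity enforces the SE divisibility and dropout bounds", {
  expect_error(scnnConfig(nFilters = 6L, seReduction = 4L), "divisible")
  expect_error(scnnConfig(dropout = 1), "dropout")
  expect_s4_class(tinyConfig(), "SCNNConfig")
})

test_that("the network emits (windows, L, 5) softmax rows, deterministically", {
  cfg <- tinyConfig()
  model <- buildScnn(cfg)
  rec <- randomRecording(P = 12L, seed = 31)
  st <- encodeSequences(rec, 10L)
  pr <- scnnForward(model, st)
  expect_equal(dim(pr), c(3L, 10L, 5L))
  expect_lt(max(abs(apply(pr, c(1, 2), sum) - 1)), 1e-6)
  expect_identical(pr, scnnForward(model, st))

  model2 <- buildScnn(cfg)
  expect_identical(model@params, model2@params)

  expect_error(buildScnn(scnnConfig(fs = 80, smallKernelW = 30 * 80 + 1)),
               "exceeds epoch length")
  badSeq <- encodeSequences(randomRecording(P = 11L, fs = 100, seed = 1), 10L)
  expect_error(scnnForward(model, badSeq), "does not match")
})

test_that("untrained output probabilities are near-uniform on noise", {
  model <- buildScnn(tinyConfig())
  rec <- randomRecording(P = 109L, seed = 32)
  pr <- scnnForward(model, encodeSequences(rec, 10L))
  meanProb <- apply(pr, 3, mean)      # over 1000 (window, position) rows
  expect_true(all(abs(meanProb - 0.2) < 0.15))
})

test_that("SE recalibration gates features channel-wise", {
  O <- 8L; hid <- 4L
  set.seed(33)
  w <- list(W1 = matrix(rnorm(hid * O, 0, 0.5), hid, O), b1 = numeric(hid),
            W2 = matrix(rnorm(O * hid, 0, 0.5), O, hid), b2 = numeric(O))
  zero <- array(0, c(2, 6, O))
  expect_equal(seRecalibrate(zero, w), zero)

  x <- array(abs(rnorm(2 * 6 * O)), c(2, 6, O))
  out <- seRecalibrate(x, w)
  expect_true(all(out <= x))          # sigmoid gates < 1 on non-negative input
  expect_true(all(out >= 0))

  wSat <- w; wSat$b2 <- rep(20, O)    # saturated gates ~ 1: identity map
  expect_equal(seRecalibrate(x, wSat), x, tolerance = 1e-6)

  expect_error(seRecalibrate(x, list(W1 = matrix(0, 2, 3),
                                     W2 = matrix(0, 3, 2), b1 = 0, b2 = 0)),
               "channels")
})

test_that("kernel height 2 couples adjacent epochs; height 1 does not", {
  rec <- randomRecording(P = 12L, seed = 34)
  st <- encodeSequences(rec, 10L)
  zeroEpochInWindow <- function(st, j) {
    st@data[1, j, ] <- 0
    st
  }
  m2 <- buildScnn(tinyConfig())
  base2 <- scnnForward(m2, st)
  pert2 <- scnnForward(m2, zeroEpochInWindow(st, 4L))
  # zeroing epoch 4 changes position 3 (which pairs epochs 3 and 4) ...
  expect_gt(max(abs(pert2[1, 3, ] - base2[1, 3, ])), 1e-8)
  # ... and position 4 itself, but not earlier positions
  expect_equal(pert2[1, 2, ], base2[1, 2, ])

  m1 <- buildScnn(tinyConfig(kernelH = 1L))
  base1 <- scnnForward(m1, st)
  pert1 <- scnnForward(m1, zeroEpochInWindow(st, 4L))
  expect_equal(pert1[1, 3, ], base1[1, 3, ])          # position 3 untouched
  expect_gt(max(abs(pert1[1, 4, ] - base1[1, 4, ])), 1e-8)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- scnnConfig(fs = 4 / 30, nFilters = 4L, seReduction = 2L,
                    smallKernelW = 2L, largeKernelW = 3L, smallStride = 1L,
                    largeStride = 1L, dropout = 0, seed = 40L)
  model <- buildScnn(cfg)
  arch <- model@arch
  params <- model@params
  set.seed(41)
  Xb <- matrix(rnorm(2 * 4 * 3), ncol = 3)     # 3 samples of 2x4 pairs
  y <- c(1L, 3L, 5L)
  lossOf <- function(p) {
    fw <- escnn:::scnnBatchForward(p, arch, Xb)
    pr <- escnn:::softmaxCols(fw$logits)
    -mean(log(pr[cbind(y, 1:3)]))
  }
  fw <- escnn:::scnnBatchForward(params, arch, Xb, keepCache = TRUE)
  pr <- escnn:::softmaxCols(fw$logits)
  Y <- matrix(0, 5, 3); Y[cbind(y, 1:3)] <- 1
  grads <- escnn:::scnnBatchBackward(params, arch, fw, (pr - Y) / 3)
  eps <- 1e-6
  for (nm in c("W1.s", "W2.l", "W3.s", "se1W.l", "se2W.s", "Wd", "bd",
               "se2b.l", "b2.s")) {
    p <- params
    i <- if (length(p[[nm]]) > 3) 3L else 1L
    p[[nm]][i] <- p[[nm]][i] + eps
    up <- lossOf(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps
    dn <- lossOf(p)
    expect_equal(grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("training reduces the loss and is reproducible", {
  coh <- tinyCohort()
  cfg <- tinyConfig(maxEpochs = 3L)
  m1 <- trainScnn(buildScnn(cfg), coh$recordings[1:2])
  expect_true(m1@trained)
  expect_lt(m1@history$trainLoss[3], m1@history$trainLoss[1])
  m2 <- trainScnn(buildScnn(cfg), coh$recordings[1:2])
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)
  expect_error(trainScnn(buildScnn(cfg), list()), "empty")
})

test_that("trained models save and reload", {
  coh <- tinyCohort()
  m <- trainScnn(buildScnn(tinyConfig(maxEpochs = 1L)), coh$recordings[1:2])
  path <- withr::local_tempfile(fileext = ".rds")
  saveScnn(m, path)
  m2 <- readScnn(path)
  expect_identical(m@params, m2@params)
  st <- encodeSequences(coh$recordings[[1]], 10L)
  expect_identical(scnnForward(m, st), scnnForward(m2, st))
})
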