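test_that("fusion weights are normalised inverse-squared distances", {
  expect_equal(fusionWeights(c(1, 2))@weights, c(0.8, 0.2))
  expect_equal(fusionWeights(c(3, 3, 3))@weights, rep(1 / 3, 3))
  expect_equal(fusionWeights(c(0, 5))@weights, c(1, 0))
  expect_equal(fusionWeights(c(0, 0, 5))@weights, c(0.5, 0.5, 0))
  expect_error(fusionWeights(c(-1, 2)), "non-negative")

  set.seed(51)
  for (i in 1:30) {
    d <- runif(sample(2:6, 1), 0.1, 10)
    w <- fusionWeights(d)@weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(fusionWeights(d * 17.3)@weights, w, tolerance = 1e-12)
    expect_true(all(diff(w[order(d)]) <= 1e-12))   # nonincreasing in distance
  }
})

test_that("ensemble prediction is a convex combination of decoded models", {
  set.seed(52)
  mkProbs <- function() {
    p <- array(runif(3 * 2 * 5), c(3, 2, 5))
    sweep(p, c(1, 2), apply(p, c(1, 2), sum), "/")
  }
  pa <- mkProbs(); pb <- mkProbs()
  st <- new("SequenceTensor", data = array(0, c(3, 2, 10)), L = 2L,
            offset = 1L)          # placeholder; probs are precomputed

  # k = 1 reduces to single-model decoding
  one <- ensemblePredict(list(pa), fusionWeights(1), st)
  expect_equal(one$consolidated@scores, decodeConsolidate(pa)@scores)

  # identical models: fusion equals either decode for any weights
  same <- ensemblePredict(list(pa, pa), fusionWeights(c(1, 3)), st)
  expect_equal(same$consolidated@scores, decodeConsolidate(pa)@scores)

  # convexity: fused scores lie between the per-model extremes
  w <- fusionWeights(c(1, 2))
  mix <- ensemblePredict(list(pa, pb), w, st)
  sa <- decodeConsolidate(pa)@scores
  sb <- decodeConsolidate(pb)@scores
  expect_true(all(mix$consolidated@scores <= pmax(sa, sb) + 1e-12))
  expect_true(all(mix$consolidated@scores >= pmin(sa, sb) - 1e-12))
  expect_equal(mix$consolidated@scores, 0.8 * sa + 0.2 * sb)

  expect_error(ensemblePredict(list(pa), fusionWeights(c(1, 2)), st),
               "1 models")
})

test_that("a hand-set one-hot disagreement goes to the heavier model", {
  # P = 2, L = 1: two epochs; models disagree on epoch 2
  onehot <- function(stageIdx) {
    p <- array(0, c(2, 1, 5))
    for (m in 1:2) p[m, 1, stageIdx[m]] <- 1
    p
  }
  pa <- onehot(c(1L, 2L))   # Wake, N1
  pb <- onehot(c(1L, 4L))   # Wake, N3
  st <- new("SequenceTensor", data = array(0, c(2, 1, 10)), L = 1L,
            offset = 1L)
  out <- ensemblePredict(list(pa, pb), fusionWeights(c(1, 2)), st)
  expect_equal(as.character(out$stages), c("Wake", "N1"))
  out2 <- ensemblePredict(list(pa, pb), fusionWeights(c(2, 1)), st)
  expect_equal(as.character(out2$stages), c("Wake", "N3"))
})

test_that("metrics match hand computations on a binary confusion", {
  # confusion [[50,10],[10,30]] realised as Wake/N1 label vectors
  truth <- stageFactor(rep(c("Wake", "N1"), c(60, 40)))
  pred <- stageFactor(c(rep("Wake", 50), rep("N1", 10),
                        rep("Wake", 10), rep("N1", 30)))
  suppressWarnings(rep <- evaluateStaging(pred, truth))
  expect_equal(rep@acc, 0.8)
  expect_equal(rep@kappa, (0.8 - 0.52) / 0.48, tolerance = 1e-10)
  expect_equal(rep@confusion["Wake", "Wake"], 50)
  expect_equal(unname(rep@perClassSens["Wake"]), 50 / 60)
  expect_equal(unname(rep@perClassSpec["Wake"]), 30 / 40)
})

test_that("perfect predictions score 1 across the board", {
  truth <- stageFactor(STAGES[rep(1:5, 8)])
  rep <- evaluateStaging(truth, truth)
  expect_equal(rep@acc, 1)
  expect_equal(rep@kappa, 1)
  expect_equal(rep@macroF1, 1)
  expect_equal(rep@macroSens, 1)
  expect_equal(rep@macroSpec, 1)
})

test_that("random predictions over balanced classes give kappa near zero", {
  set.seed(53)
  n <- 10000
  truth <- stageFactor(STAGES[sample.int(5, n, replace = TRUE)])
  pred <- stageFactor(STAGES[sample.int(5, n, replace = TRUE)])
  rep <- evaluateStaging(pred, truth)
  expect_lt(abs(rep@kappa), 0.05)
})

test_that("metrics agree with definitional oracles on random labelings", {
  set.seed(54)
  for (i in 1:30) {
    n <- sample(50:200, 1)
    truth <- stageFactor(STAGES[sample.int(5, n, replace = TRUE)])
    pred <- stageFactor(STAGES[sample.int(5, n, replace = TRUE)])
    rep <- suppressWarnings(evaluateStaging(pred, truth))
    # oracle: explicit double loop over the label vectors
    conf <- matrix(0, 5, 5)
    for (j in seq_len(n))
      conf[as.integer(truth[j]), as.integer(pred[j])] <-
        conf[as.integer(truth[j]), as.integer(pred[j])] + 1
    po <- sum(diag(conf)) / n
    pe <- sum(rowSums(conf) * colSums(conf)) / n^2
    expect_equal(rep@acc, po, tolerance = 1e-12)
    expect_equal(rep@kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    for (cidx in 1:5) {
      tp <- conf[cidx, cidx]; fn <- sum(conf[cidx, ]) - tp
      fp <- sum(conf[, cidx]) - tp; tn <- n - tp - fn - fp
      if (tp + fn + fp == 0) next
      expect_equal(unname(rep@perClassSens[cidx]), tp / (tp + fn))
      expect_equal(unname(rep@perClassSpec[cidx]), tn / (tn + fp))
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      recall <- tp / (tp + fn)
      f1 <- if (prec + recall > 0) 2 * prec * recall / (prec + recall) else 0
      expect_equal(unname(rep@perClassF1[cidx]), f1)
    }
  }
})

test_that("AUC matches pROC and absent classes are excluded with warning", {
  set.seed(55)
  n <- 120
  truth <- stageFactor(STAGES[sample.int(3, n, replace = TRUE)])  # no N3/REM
  scores <- matrix(runif(n * 5), n, 5)
  pred <- stageFactor(STAGES[max.col(scores[, 1:3])])   # N3/REM never predicted
  expect_warning(rep <- evaluateStaging(
    pred, truth,
    new("ConsolidatedProbs", scores = scores, coverage = rep(1L, n))),
    "absent")
  norm <- scores / rowSums(scores)
  for (cidx in 1:3) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = truth == STAGES[cidx], predictor = norm[, cidx],
      direction = "<", quiet = TRUE)))
    expect_equal(unname(rep@aucPerClass[cidx]), as.numeric(ref),
                 tolerance = 1e-10)
  }
  expect_true(all(is.na(rep@aucPerClass[4:5])))
  expect_true(all(is.na(rep@perClassF1[4:5])))
})

test_that("LOSO produces one fold per subject with leak-free manifests", {
  coh <- tinyCohort()
  cfg <- tinyConfig(maxEpochs = 2L)
  # the 30-epoch mini-cohort can lack a stage entirely in one subject, which
  # evaluateStaging flags; that warning is expected here
  res <- suppressWarnings(
    losoRun(coh$recordings, cfg, L = 10L, seed = 5L, pooled = TRUE))
  ids <- vapply(coh$recordings, subjectId, character(1))
  expect_equal(sort(unique(res$metrics$subject)), sort(ids))
  expect_equal(nrow(res$metrics), 2L * length(ids))
  for (id in ids) {
    man <- res$manifests[[id]]
    expect_false(id %in% man$train)
    expect_equal(sort(c(man$test, man$train)), sort(ids))
    expect_equal(sum(man$weights), 1, tolerance = 1e-9)
  }
  expect_true(all(res$metrics$acc >= 0 & res$metrics$acc <= 1))
  expect_error(losoRun(coh$recordings[1:2], cfg), "at least 3")
})

test_that("LOSO is reproducible for a fixed master seed", {
  coh <- tinyCohort()
  cfg <- tinyConfig(maxEpochs = 1L)
  r1 <- losoRun(coh$recordings, cfg, seed = 8L, folds = 1L, pooled = FALSE)
  r2 <- losoRun(coh$recordings, cfg, seed = 8L, folds = 1L, pooled = FALSE)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$manifests, r2$manifests)
})
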