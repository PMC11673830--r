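# Leave-one-subject-out evaluation of the full pipeline.

trainSubgroupModels <- function(recs, assignment, k, config, L, foldSeed) {
  lapply(seq_len(k), function(cc) {
    members <- recs[assignment == cc]
    cfg <- initialize(config, seed = childSeed(foldSeed, cc))
    trainScnn(buildScnn(cfg), members, L = L)
  })
}

#' Leave-one-subject-out evaluation of the subgroup ensemble
#'
#' For each held-out subject: subject spectral features, PCA and subgroup
#' clustering are fitted on the remaining subjects only (no leakage of the
#' test subject into the clustering); one network is trained per subgroup;
#' the test subject's subgroup distances give the fusion weights; and the
#' fused prediction is scored against the reference hypnogram. A pooled
#' ablation (one network trained on all training subjects) is evaluated on
#' the same folds when `pooled = TRUE`. If any subgroup in a fold has no
#' members the fold falls back to the pooled model, with a warning.
#'
#' @param cohort list of at least 3 [EpochedRecording-class] objects.
#' @param config an [SCNNConfig-class] shared by all models.
#' @param L sequence window length in epochs (default 10).
#' @param U number of principal components (default 3).
#' @param kRange candidate subgroup counts (default 2:5, clipped to the
#'   training-fold size).
#' @param seed master seed; every per-fold seed derives from it.
#' @param folds indices of subjects to hold out (default: all, full LOSO).
#' @param pooled also train and score the pooled single-model ablation.
#' @param distanceMode subgroup distance mode, see [clusterDistances()].
#'   The default, `"centroid"`, measures the test subject's distance to each
#'   cluster centre (the quantity the fusion weights are defined on);
#'   `"members"` uses the mean distance to the subgroup's members, which
#'   folds within-subgroup spread into every distance and so yields more
#'   diffuse weights.
#' @param verbose print per-fold progress.
#' @return list with `metrics` (data.frame: one row per fold and model
#'   flavour with accuracy, kappa, macro F1/sensitivity/specificity),
#'   `reports` (per-fold [MetricsReport-class] objects) and `manifests`
#'   (per-fold training/test composition, selected k, silhouette table,
#'   distances and weights).
#' @export
losoRun <- function(cohort, config, L = 10L, U = 3L, kRange = 2:5,
                    seed = 1L, folds = seq_along(cohort), pooled = TRUE,
                    distanceMode = c("centroid", "members"),
                    verbose = FALSE) {
  if (length(cohort) < 3L) stop("LOSO needs at least 3 subjects")
  distanceMode <- match.arg(distanceMode)
  ids <- vapply(cohort, subjectId, character(1))
  feats <- cohortFeatures(cohort)          # fold-independent, computed once

  metrics <- data.frame()
  reports <- list()
  manifests <- list()
  for (f in folds) {
    foldSeed <- childSeed(seed, f)
    trainIdx <- setdiff(seq_along(cohort), f)
    trainRecs <- cohort[trainIdx]
    S <- length(trainIdx)

    pca <- fitPca(feats[trainIdx, , drop = FALSE], U = min(U, ncol(feats)))
    pts <- pcaTransform(pca, feats[trainIdx, , drop = FALSE])
    rownames(pts) <- ids[trainIdx]
    ks <- kRange[kRange >= 2L & kRange <= S]
    if (!length(ks)) stop("no admissible k in kRange for ", S, " subjects")
    sel <- selectK(pts, ks, seed = foldSeed)
    clusters <- sel$models[[match(sel$k, sel$table$k)]]

    testSeq <- encodeSequences(cohort[[f]], L)
    truth <- stageLabels(cohort[[f]])

    ensembleOk <- all(tabulate(clusters@assignment, clusters@k) > 0L)
    poolModel <- NULL
    if (pooled || !ensembleOk) {
      cfg <- initialize(config, seed = childSeed(foldSeed, 999L))
      poolModel <- trainScnn(buildScnn(cfg), trainRecs, L = L)
    }

    if (ensembleOk) {
      models <- trainSubgroupModels(trainRecs, clusters@assignment,
                                    clusters@k, config, L, foldSeed)
      dist <- clusterDistances(clusters,
                               pcaTransform(pca, feats[f, ]),
                               mode = distanceMode)
      wts <- fusionWeights(dist)
      ens <- ensemblePredict(models, wts, testSeq)
    } else {
      warning("fold ", f, ": empty subgroup; falling back to pooled model")
      probs <- scnnForward(poolModel, testSeq)
      cp <- decodeConsolidate(probs)
      ens <- list(stages = predictStages(cp), consolidated = cp)
      dist <- numeric(0)
      wts <- NULL
    }
    rep <- evaluateStaging(ens$stages, truth, ens$consolidated)
    reports[[ids[f]]] <- list(escnn = rep)
    row <- data.frame(subject = ids[f], model = "escnn", acc = rep@acc,
                      kappa = rep@kappa, macroF1 = rep@macroF1,
                      macroSens = rep@macroSens, macroSpec = rep@macroSpec)
    if (pooled) {
      pprobs <- scnnForward(poolModel, testSeq)
      pcp <- decodeConsolidate(pprobs)
      prep <- evaluateStaging(predictStages(pcp), truth, pcp)
      reports[[ids[f]]]$pooled <- prep
      row <- rbind(row, data.frame(subject = ids[f], model = "pooled",
                                   acc = prep@acc, kappa = prep@kappa,
                                   macroF1 = prep@macroF1,
                                   macroSens = prep@macroSens,
                                   macroSpec = prep@macroSpec))
    }
    metrics <- rbind(metrics, row)
    manifests[[ids[f]]] <- list(test = ids[f], train = ids[trainIdx],
                                k = clusters@k,
                                silhouetteTable = sel$table,
                                roi = pca@roi,
                                distances = dist,
                                weights = if (!is.null(wts)) wts@weights)
    if (verbose)
      message(sprintf("fold %s: escnn acc %.3f%s", ids[f], rep@acc,
                      if (pooled) sprintf(" pooled acc %.3f",
                                          row$acc[row$model == "pooled"])
                      else ""))
  }
  rownames(metrics) <- NULL
  list(metrics = metrics, reports = reports, manifests = manifests)
}
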