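# Staging metrics: accuracy, Cohen's kappa, per-class F1 / sensitivity /
# specificity, one-vs-rest AUC.

# Rank-based one-vs-rest AUC (equivalent to the trapezoidal ROC area).
aucOneVsRest <- function(score, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate predicted stages against a reference hypnogram
#'
#' Computes overall accuracy; Cohen's kappa from the confusion-matrix
#' marginals; one-vs-rest F1, sensitivity and specificity per stage with
#' unweighted (macro) averages; and, when consolidated scores are supplied,
#' a one-vs-rest AUC per stage from the L1-normalised score rows. A stage
#' absent from both truth and prediction has undefined F1 and is excluded
#' from the macro averages, with a warning.
#'
#' @param pred factor of predicted stages (levels [STAGES]).
#' @param truth factor of reference stages, same length.
#' @param scores optional [ConsolidatedProbs-class] (or P x 5 matrix) for
#'   AUC computation.
#' @return a [MetricsReport-class].
#' @export
evaluateStaging <- function(pred, truth, scores = NULL) {
  pred <- stageFactor(pred)
  truth <- stageFactor(truth)
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ")
  conf <- table(truth = truth, pred = pred)
  conf <- unclass(conf)
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1

  C <- length(STAGES)
  f1 <- sens <- spec <- rep(NA_real_, C)
  names(f1) <- names(sens) <- names(spec) <- STAGES
  for (i in seq_len(C)) {
    tp <- conf[i, i]
    fn <- sum(conf[i, ]) - tp
    fp <- sum(conf[, i]) - tp
    tn <- n - tp - fn - fp
    if (tp + fn + fp == 0) next                    # absent everywhere
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  if (anyNA(f1))
    warning("stage(s) absent from both truth and prediction excluded from ",
            "macro averages: ", paste(STAGES[is.na(f1)], collapse = ", "))

  auc <- rep(NA_real_, C)
  names(auc) <- STAGES
  if (!is.null(scores)) {
    m <- if (is(scores, "ConsolidatedProbs")) scores@scores
         else as.matrix(scores)
    m <- m / pmax(rowSums(m), 1e-12)
    for (i in seq_len(C)) auc[i] <- aucOneVsRest(m[, i], truth == STAGES[i])
  }

  new("MetricsReport", acc = acc, kappa = kappa,
      macroF1 = mean(f1, na.rm = TRUE), macroSens = mean(sens, na.rm = TRUE),
      macroSpec = mean(spec, na.rm = TRUE), perClassF1 = f1,
      perClassSens = sens, perClassSpec = spec, aucPerClass = auc,
      confusion = conf)
}
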