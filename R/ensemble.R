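# Weighted fusion of per-subgroup model predictions.

#' Inverse-squared-distance fusion weights
#'
#' `w_i = (1 / D_i^2) / sum_j (1 / D_j^2)`: subgroups whose members are
#' spectrally closer to the test subject dominate the fused prediction. If a
#' distance is (numerically) zero, the full weight goes to the nearest
#' subgroup, split uniformly among exact ties.
#'
#' @param distances non-negative length-k subgroup distance vector.
#' @param eps zero-distance threshold (default 1e-9).
#' @return an [EnsembleWeights-class]. Weights sum to 1 and are invariant to
#'   rescaling all distances by a common factor.
#' @export
fusionWeights <- function(distances, eps = 1e-9) {
  distances <- as.numeric(distances)
  if (!length(distances)) stop("distances must be non-empty")
  if (any(distances < 0)) stop("distances must be non-negative")
  if (min(distances) < eps) {
    w <- as.numeric(distances == min(distances))
    w <- w / sum(w)
  } else {
    inv <- 1 / distances^2
    w <- inv / sum(inv)
  }
  new("EnsembleWeights", weights = w, distances = distances)
}

#' Fuse per-subgroup model predictions for one subject
#'
#' Each subgroup model's per-position probabilities are decoded with
#' [decodeConsolidate()]; the consolidated per-epoch scores are combined as
#' the weight-convex sum `sum_i w_i * scores_i` and the stage is the argmax
#' (ties toward the lower stage index).
#'
#' @param models list of k [SCNNModel-class] objects, or precomputed
#'   (windows x L x 5) probability arrays.
#' @param weights an [EnsembleWeights-class] of matching length.
#' @param seq the subject's [SequenceTensor-class].
#' @return list with `stages` (factor of length P) and `consolidated`
#'   (the fused [ConsolidatedProbs-class]).
#' @export
ensemblePredict <- function(models, weights, seq) {
  stopifnot(is(weights, "EnsembleWeights"))
  if (length(models) != length(weights@weights))
    stop("got ", length(models), " models for ", length(weights@weights),
         " weights")
  fused <- NULL
  coverage <- NULL
  for (i in seq_along(models)) {
    probs <- if (is(models[[i]], "SCNNModel"))
      scnnForward(models[[i]], seq) else models[[i]]
    cp <- decodeConsolidate(probs)
    if (is.null(fused)) {
      fused <- weights@weights[i] * cp@scores
      coverage <- cp@coverage
    } else fused <- fused + weights@weights[i] * cp@scores
  }
  cp <- new("ConsolidatedProbs", scores = fused, coverage = coverage)
  list(stages = predictStages(cp), consolidated = cp)
}
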