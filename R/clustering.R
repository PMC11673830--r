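# Subject subgroup discovery: seeded k-means, silhouette selection of k, and
# member-mean subgroup distances for ensemble weighting.

#' Partition subjects into subgroups with k-means
#'
#' Euclidean k-means with 10 seeded restarts, keeping the best inertia.
#' Deterministic given `seed`.
#'
#' @param points S x U matrix of PCA-space subject coordinates.
#' @param k number of subgroups (2 <= k <= S).
#' @param seed RNG seed.
#' @param nstart number of restarts (default 10).
#' @return a [ClusterModel-class].
#' @export
fitClusters <- function(points, k, seed = 1L, nstart = 10L) {
  points <- as.matrix(points)
  S <- nrow(points)
  if (k < 2L) stop("k must be >= 2")
  if (k > S) stop("k (", k, ") exceeds number of subjects (", S, ")")
  if (nrow(unique(points)) < k)
    stop("degenerate data: fewer than k distinct points")
  if (k == S) {
    # every subject its own subgroup; stats::kmeans refuses k == nrow
    km <- list(centers = points, cluster = seq_len(S))
  } else {
    km <- withSeed(seed, stats::kmeans(points, centers = k, nstart = nstart,
                                       iter.max = 100L))
  }
  new("ClusterModel", centers = km$centers,
      assignment = as.integer(km$cluster), k = as.integer(k),
      silhouette = silhouetteScore(points, km$cluster), points = points,
      subjectIds = rownames(points) %||% as.character(seq_len(S)))
}

#' Mean silhouette coefficient of a partition
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to the members of any other
#' cluster; its silhouette is `(b - a) / max(a, b)`, with singleton-cluster
#' points contributing 0. Returns the mean over all points.
#'
#' @param points S x U coordinate matrix.
#' @param assignment cluster index per point (at least two clusters).
#' @return mean silhouette in \[-1, 1\].
#' @export
silhouetteScore <- function(points, assignment) {
  points <- as.matrix(points)
  assignment <- as.integer(assignment)
  ks <- sort(unique(assignment))
  if (length(ks) < 2L) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(points))
  S <- nrow(points)
  sil <- numeric(S)
  sizes <- tabulate(assignment, max(ks))
  for (i in seq_len(S)) {
    own <- assignment[i]
    if (sizes[own] == 1L) { sil[i] <- 0; next }
    a <- sum(D[i, assignment == own]) / (sizes[own] - 1L)
    b <- min(vapply(ks[ks != own],
                    function(cc) mean(D[i, assignment == cc]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Select the number of subgroups by silhouette
#'
#' Fits k-means for every candidate `k` and returns the `k` with the largest
#' mean silhouette (ties broken toward the smallest `k`, favouring
#' parsimony), together with the full silhouette table and fitted models.
#'
#' @param points S x U coordinate matrix.
#' @param kRange candidate subgroup counts (default 2:5).
#' @param seed RNG seed used for every fit.
#' @return list with `k` (selected), `table` (data.frame `k`, `silhouette`)
#'   and `models` (one [ClusterModel-class] per candidate).
#' @export
selectK <- function(points, kRange = 2:5, seed = 1L) {
  if (!length(kRange)) stop("kRange must be non-empty")
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > nrow(points)))
    stop("every k must satisfy 2 <= k <= number of subjects")
  models <- lapply(kRange, function(k) fitClusters(points, k, seed = seed))
  sils <- vapply(models, function(m) m@silhouette, numeric(1))
  best <- .pickK(kRange, sils)
  list(k = best, table = data.frame(k = kRange, silhouette = sils),
       models = models)
}

# argmax silhouette with ties toward the smallest k (ks sorted ascending)
.pickK <- function(ks, sils) ks[which.max(sils)]

#' Distances from a subject to each subgroup
#'
#' By default the distance to subgroup C is the mean Euclidean distance from
#' the query point to each of C's members; `mode = "centroid"` uses the
#' distance to the subgroup centroid instead.
#'
#' @param model a [ClusterModel-class].
#' @param point length-U coordinate vector (PCA space of the model).
#' @param mode `"members"` (default) or `"centroid"`.
#' @return length-k non-negative distance vector.
#' @export
clusterDistances <- function(model, point, mode = c("members", "centroid")) {
  stopifnot(is(model, "ClusterModel"))
  mode <- match.arg(mode)
  point <- as.numeric(point)
  if (length(point) != ncol(model@points))
    stop("point dimension does not match cluster space")
  vapply(seq_len(model@k), function(cc) {
    if (mode == "centroid")
      return(sqrt(sum((point - model@centers[cc, ])^2)))
    members <- model@points[model@assignment == cc, , drop = FALSE]
    if (!nrow(members)) stop("empty subgroup ", cc)
    mean(sqrt(rowSums(sweep(members, 2L, point)^2)))
  }, numeric(1))
}
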