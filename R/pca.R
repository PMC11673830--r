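# PCA of subject spectral features, with retention of information.

#' Fit a PCA model on subject feature vectors
#'
#' Features are z-scored column-wise (so power-scale features do not dominate
#' ratio features) before eigendecomposition of their covariance. All
#' eigenvalues are stored; the retention of information is the fraction of
#' eigenvalue mass carried by the first `U` components.
#'
#' @param features S x T numeric matrix, one row per subject (S >= 2).
#' @param U number of components to retain, default 3.
#' @return a [PCAModel-class].
#' @export
fitPca <- function(features, U = 3L) {
  features <- as.matrix(features)
  S <- nrow(features); T <- ncol(features)
  if (S < 2L) stop("need at least 2 subjects to fit PCA")
  if (U < 1L || U > T) stop("U must be between 1 and ", T)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  if (any(scl < 1e-12)) {
    warning("constant feature column(s): ",
            paste(colnames(features)[scl < 1e-12], collapse = ", "),
            "; scale floored at 1e-12")
    scl <- pmax(scl, 1e-12)
  }
  Z <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  e <- eigen(stats::cov(Z), symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  comp <- e$vectors[, seq_len(U), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(U)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  rownames(comp) <- colnames(features)
  new("PCAModel", center = ctr, scale = scl, components = comp,
      eigenvalues = lambda, U = as.integer(U),
      roi = retainedInformation(lambda, U),
      featureNames = colnames(features) %||% paste0("f", seq_len(T)))
}

#' Retention of information of a principal-component truncation
#'
#' The fraction of total eigenvalue mass carried by the first `U`
#' eigenvalues: `sum(lambda[1:U]) / sum(lambda)`. Non-decreasing in `U` and
#' equal to 1 at `U = n`.
#'
#' @param eigenvalues non-negative, non-increasing eigenvalues.
#' @param U number of leading eigenvalues retained.
#' @return fraction in \[0, 1\].
#' @export
retainedInformation <- function(eigenvalues, U) {
  if (U < 1L || U > length(eigenvalues))
    stop("U must be between 1 and ", length(eigenvalues))
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be non-negative")
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be non-increasing")
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero")
  sum(eigenvalues[seq_len(U)]) / tot
}

#' Project feature vectors into PCA space
#'
#' Applies the stored centring/scaling, then the component loadings.
#'
#' @param model a [PCAModel-class].
#' @param features length-T vector or S x T matrix.
#' @return length-U vector or S x U matrix of reduced coordinates.
#' @export
pcaTransform <- function(model, features) {
  stopifnot(is(model, "PCAModel"))
  vec <- is.null(dim(features))
  x <- if (vec) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(x) != length(model@center))
    stop("feature length ", ncol(x), " does not match model (",
         length(model@center), ")")
  Z <- sweep(sweep(x, 2L, model@center), 2L, model@scale, "/")
  out <- Z %*% model@components
  if (vec) drop(out) else out
}
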