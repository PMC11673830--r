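# Sequence encoding (sliding-window stacking of adjacent epochs) and
# decoding (normalise, consolidate, argmax of overlapping predictions).

#' Encode a recording as overlapping windows of adjacent epochs
#'
#' A window of length L epochs slides over the night with a stride of one
#' epoch, producing a (P-L+1) x L x M tensor whose window i, position j is
#' epoch i+j-1 verbatim.
#'
#' @param rec an [EpochedRecording-class] with P >= L epochs.
#' @param L window length in epochs (default 10).
#' @return a [SequenceTensor-class].
#' @export
encodeSequences <- function(rec, L = 10L) {
  stopifnot(is(rec, "EpochedRecording"))
  L <- as.integer(L)
  P <- nrow(rec@X); M <- ncol(rec@X)
  if (P < L)
    stop("cannot encode: P = ", P, " epochs is less than window length L = ",
         L)
  nWin <- P - L + 1L
  data <- array(0, dim = c(nWin, L, M))
  for (j in seq_len(L)) data[, j, ] <- rec@X[j:(j + nWin - 1L), , drop = FALSE]
  new("SequenceTensor", data = data, L = L, offset = 1L)
}

#' Normalise and consolidate overlapping window predictions
#'
#' Each (window, position) probability row is L1-normalised to sum 1 (rows
#' summing to zero are replaced by a uniform distribution, with a warning);
#' rows covering the same absolute epoch m (window i, position j with
#' i+j-1 = m) are then summed, so epoch m's score row sums to its coverage
#' count.
#'
#' @param probs (P-L+1) x L x C array of non-negative class probabilities.
#' @return a [ConsolidatedProbs-class] with P x C scores and per-epoch
#'   coverage.
#' @export
decodeConsolidate <- function(probs) {
  d <- dim(probs)
  if (length(d) != 3L) stop("probs must be a (windows x L x classes) array")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("probabilities must be finite and non-negative")
  nWin <- d[1L]; L <- d[2L]; C <- d[3L]
  P <- nWin + L - 1L
  mat <- matrix(probs, nrow = nWin * L, ncol = C)   # row r = (window i, pos j)
  rs <- rowSums(mat)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " zero probability row(s) replaced by uniform")
    mat[zero, ] <- 1 / C
    rs[zero] <- 1
  }
  mat <- mat / rs
  r <- seq_len(nWin * L)
  m <- (r - 1L) %% nWin + (r - 1L) %/% nWin + 1L      # i + j - 1
  scores <- rowsum(mat, group = m)
  dimnames(scores) <- NULL
  new("ConsolidatedProbs", scores = scores,
      coverage = as.integer(tabulate(m, P)))
}

#' Per-epoch stage prediction by argmax
#'
#' Exact ties break toward the lower stage index in the order
#' Wake, N1, N2, N3, REM.
#'
#' @param scores a [ConsolidatedProbs-class] (or bare P x 5 score matrix).
#' @return factor of length P with levels [STAGES].
#' @export
predictStages <- function(scores) {
  m <- if (is(scores, "ConsolidatedProbs")) scores@scores else as.matrix(scores)
  if (ncol(m) != length(STAGES))
    stop("expected ", length(STAGES), " stage columns")
  stageFactor(STAGES[max.col(m, ties.method = "first")])
}
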