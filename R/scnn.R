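# The dual-scale sequential CNN: configuration, construction, forward pass
# and training.
#
# The network scores one window position from the pair of adjacent epochs the
# kernel-height-2 convolution sees there (position j of window i pairs epochs
# i+j-1 and i+j; the last position pairs the window's final epoch with zero
# padding). Because no layer mixes different window positions beyond that
# pairing and the classifier head is shared across positions, training
# operates directly on the distinct epoch pairs of each recording, weighted
# by how many (window, position) slots map onto each pair -- an exact,
# cheaper reformulation of the per-window loss.

#' Configure a sequential CNN
#'
#' Defaults follow the dual-scale convention: the small branch kernel spans
#' half a second of signal (high-frequency detail) with stride fs/16, the
#' large branch four seconds (slow-wave scale) with stride fs/2; both
#' convolve with height `kernelH` over the epoch axis. Each branch continues
#' with max-pooling (8 then 4) and two width-8 convolutions of `2 * nFilters`
#' channels, then squeeze-and-excitation recalibration and global average
#' pooling; the two branch features are concatenated and mapped to the five
#' stage logits by a shared linear head.
#'
#' @param fs sampling rate the model will see, Hz.
#' @param nFilters filters per branch in the first convolution (default 64).
#' @param kernelH convolution height in epochs (default 2: cross-epoch).
#' @param seReduction SE bottleneck ratio (default 16); must divide
#'   `nFilters`.
#' @param smallKernelW,largeKernelW,smallStride,largeStride kernel geometry
#'   in samples; defaults derived from `fs` as above.
#' @param dropout dropout on concatenated features during training.
#' @param lr,batchSize,maxEpochs,patience Adam learning rate, minibatch size,
#'   training-epoch cap and early-stopping patience.
#' @param validFraction fraction of training pairs held out for early
#'   stopping when no validation recordings are supplied.
#' @param classWeights weight the loss by inverse stage frequency.
#' @param restarts maximum number of seeded training restarts (default 1,
#'   i.e. a single attempt). Small networks occasionally settle in poor
#'   optima; with `restarts > 1` training is repeated from fresh seeded
#'   initialisations and the attempt with the best validation accuracy is
#'   kept.
#' @param restartFloor validation accuracy that ends the restart loop early
#'   (default 0.9).
#' @param nStages number of output classes (5).
#' @param seed RNG seed for initialisation and shuffling.
#' @return an [SCNNConfig-class].
#' @export
scnnConfig <- function(fs = 100, nFilters = 64L, kernelH = 2L,
                       seReduction = 16L,
                       smallKernelW = round(fs / 2),
                       largeKernelW = round(fs * 4),
                       smallStride = max(1, round(fs / 16)),
                       largeStride = max(1, round(fs / 2)),
                       dropout = 0.3, lr = 1e-3, batchSize = 32L,
                       maxEpochs = 30L, patience = 5L, validFraction = 0.15,
                       classWeights = FALSE, restarts = 1L,
                       restartFloor = 0.9, nStages = 5L, seed = 1L) {
  new("SCNNConfig", fs = fs, nStages = as.integer(nStages),
      smallKernelW = as.integer(smallKernelW),
      largeKernelW = as.integer(largeKernelW),
      smallStride = as.integer(smallStride),
      largeStride = as.integer(largeStride), kernelH = as.integer(kernelH),
      nFilters = as.integer(nFilters), seReduction = as.integer(seReduction),
      dropout = dropout, lr = lr, batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      validFraction = validFraction, classWeights = classWeights,
      restarts = as.integer(restarts), restartFloor = restartFloor,
      seed = as.integer(seed))
}

buildArch <- function(config) {
  M <- as.integer(30 * config@fs)
  H <- config@kernelH
  F1 <- config@nFilters
  mk <- function(kw, stride) {
    if (kw > M)
      stop("kernel width (", kw, " samples) exceeds epoch length (", M, ")")
    op1 <- makeIm2col(H, M, kw, stride)
    p1 <- min(8L, op1$Wout)
    w1p <- op1$Wout %/% p1
    op2 <- makeIm2col(F1, w1p, min(8L, w1p), 1L,
                      padL = (min(8L, w1p) - 1L) %/% 2L,
                      padR = min(8L, w1p) %/% 2L)
    p2 <- min(4L, op2$Wout)
    w2p <- op2$Wout %/% p2
    op3 <- makeIm2col(2L * F1, w2p, min(8L, w2p), 1L,
                      padL = (min(8L, w2p) - 1L) %/% 2L,
                      padR = min(8L, w2p) %/% 2L)
    list(op1 = op1, pool1 = p1, op2 = op2, pool2 = p2, op3 = op3)
  }
  list(s = mk(config@smallKernelW, config@smallStride),
       l = mk(config@largeKernelW, config@largeStride),
       M = M, H = H)
}

# First-layer filters start as Hann-windowed sinusoids at log-spaced
# frequencies (plus a little noise), so each branch opens as a crude
# filter bank over its frequency range instead of waiting for random
# filters to acquire band selectivity; later layers use He initialisation.
bandpassInit <- function(F1, H, kw, fs, fLo, fHi) {
  freqs <- exp(seq(log(fLo), log(fHi), length.out = F1))
  tt <- (seq_len(kw) - 1) / fs
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(kw) / (kw + 1))
  W <- matrix(0, F1, H * kw)
  for (i in seq_len(F1)) {
    tmpl <- win * sin(2 * pi * freqs[i] * tt + (i %% 2) * pi / 2)
    tmpl <- tmpl / sqrt(sum(tmpl^2)) * sqrt(2)
    # channel-fastest layout: rows of the height-H kernel interleave
    for (h in seq_len(H))
      W[i, h + (seq_len(kw) - 1L) * H] <- tmpl / sqrt(H)
  }
  W + matrix(stats::rnorm(length(W), 0, 0.1 / sqrt(H * kw)), F1)
}

initParams <- function(config, arch) {
  F1 <- config@nFilters
  O <- 2L * F1
  hid <- max(1L, O %/% config@seReduction)
  he <- function(nout, nin) matrix(stats::rnorm(nout * nin, 0,
                                                sqrt(2 / nin)), nout, nin)
  nyq <- config@fs / 2
  p <- list()
  for (br in c("s", "l")) {
    a <- arch[[br]]
    kw <- if (br == "s") config@smallKernelW else config@largeKernelW
    fLo <- if (br == "s") min(4, nyq / 4) else 0.5
    fHi <- if (br == "s") min(35, 0.9 * nyq) else min(16, 0.9 * nyq)
    p[[paste0("W1.", br)]] <- bandpassInit(F1, config@kernelH, kw,
                                           config@fs, fLo, fHi)
    p[[paste0("b1.", br)]] <- numeric(F1)
    p[[paste0("W2.", br)]] <- he(O, a$op2$K)
    p[[paste0("b2.", br)]] <- numeric(O)
    p[[paste0("W3.", br)]] <- he(O, a$op3$K)
    p[[paste0("b3.", br)]] <- numeric(O)
    p[[paste0("se1W.", br)]] <- he(hid, O)
    p[[paste0("se1b.", br)]] <- numeric(hid)
    p[[paste0("se2W.", br)]] <- he(O, hid)
    p[[paste0("se2b.", br)]] <- numeric(O)
  }
  # small classifier head: untrained predictions start near the uniform
  # prior while leaving enough gradient signal for the trunk early on
  p$Wd <- matrix(stats::rnorm(config@nStages * 2L * O, 0, 0.05),
                 config@nStages, 2L * O)
  p$bd <- numeric(config@nStages)
  p
}

#' Build an (untrained) sequential CNN
#'
#' Constructs the layer geometry for the configured sampling rate and draws
#' seeded initial parameters (He initialisation for the convolutional and SE
#' layers); the same seed always yields bit-identical parameters.
#'
#' @param config an [SCNNConfig-class].
#' @return an untrained [SCNNModel-class].
#' @export
buildScnn <- function(config) {
  stopifnot(is(config, "SCNNConfig"))
  arch <- buildArch(config)
  params <- withSeed(config@seed, initParams(config, arch))
  new("SCNNModel", params = params, attempts = list(), config = config,
      arch = arch, history = data.frame(), trained = FALSE)
}

#' Squeeze-and-excitation feature recalibration
#'
#' Global average pooling over the width axis, a bottleneck FC pair
#' (O -> O/r -> O) with ReLU, a sigmoid gate per channel, and multiplication
#' of the gates back onto the features. Gates lie strictly in (0, 1).
#'
#' @param features numeric array of shape (batch, width, channels).
#' @param weights list with elements `W1` (hidden x O), `b1`, `W2`
#'   (O x hidden), `b2`.
#' @return array of the same shape with recalibrated features.
#' @export
seRecalibrate <- function(features, weights) {
  d <- dim(features)
  if (length(d) != 3L) stop("features must be a (batch, width, channels) array")
  O <- d[3L]
  if (nrow(weights$W2) != O || ncol(weights$W1) != O)
    stop("SE weight shapes do not match ", O, " channels")
  A <- matrix(aperm(features, c(3L, 2L, 1L)), nrow = O)  # O x (width*batch)
  out <- seForward(A, d[2L], weights$W1, weights$b1, weights$W2,
                   weights$b2)$act
  aperm(array(out, dim = c(O, d[2L], d[1L])), c(3L, 2L, 1L))
}

# Flatten epoch pairs into network input columns (channel-fastest layout).
# top, bottom: n x M matrices (bottom ignored when H = 1).
pairColumns <- function(top, bottom, H) {
  if (H == 1L) return(t(top))
  n <- nrow(top); M <- ncol(top)
  T3 <- array(0, dim = c(2L, M, n))
  T3[1L, , ] <- t(top)
  T3[2L, , ] <- t(bottom)
  matrix(T3, nrow = 2L * M)
}

#' Per-position stage probabilities for encoded sequences
#'
#' Runs the network over every (window, position) slot of a sequence tensor
#' and applies a softmax, so each probability row sums to 1. For a model
#' trained with restarts, the probabilities of the near-best attempts are
#' averaged. Deterministic: no dropout is applied at evaluation.
#'
#' @param model an [SCNNModel-class].
#' @param seq a [SequenceTensor-class] whose sample count matches the model's
#'   configured sampling rate.
#' @param chunk evaluation batch size (default 256).
#' @return array of shape (windows, L, 5) of stage probabilities.
#' @export
scnnForward <- function(model, seq, chunk = 256L) {
  stopifnot(is(model, "SCNNModel"), is(seq, "SequenceTensor"))
  d <- dim(seq@data)
  if (d[3L] != model@arch$M)
    stop("sequence sample count (", d[3L], ") does not match model (",
         model@arch$M, ")")
  nWin <- d[1L]; L <- d[2L]; H <- model@arch$H
  C <- model@config@nStages
  paramSets <- if (length(model@attempts)) model@attempts
               else list(model@params)
  probs <- array(0, dim = c(nWin, L, C))
  for (j in seq_len(L)) {
    top <- matrix(seq@data[, j, ], nrow = nWin)
    bottom <- if (j < L) matrix(seq@data[, j + 1L, ], nrow = nWin)
              else matrix(0, nWin, d[3L])
    Xb <- pairColumns(top, bottom, H)
    for (s in seq(1L, nWin, by = chunk)) {
      idx <- s:min(nWin, s + chunk - 1L)
      acc <- 0
      for (ps in paramSets) {
        fw <- scnnBatchForward(ps, model@arch, Xb[, idx, drop = FALSE])
        acc <- acc + t(softmaxCols(fw$logits))
      }
      probs[idx, j, ] <- acc / length(paramSets)
    }
  }
  probs
}

# Build the weighted epoch-pair training set for a list of recordings.
# Returns X ((H*M) x N), y (stage index), w (slot multiplicities).
buildPairData <- function(recordings, L, arch) {
  H <- arch$H; M <- arch$M
  Xs <- list(); ys <- list(); ws <- list()
  for (rec in recordings) {
    P <- nrow(rec@X)
    if (P < L)
      stop("recording ", rec@subjectId, " has P = ", P, " < L = ", L)
    y <- as.integer(rec@labels)
    if (H == 1L) {
      m <- seq_len(P)
      w <- pmin(m, L, P - L + 1L, P - m + 1L)
      Xs[[length(Xs) + 1L]] <- t(rec@X)
      ys[[length(ys) + 1L]] <- y
      ws[[length(ws) + 1L]] <- w
    } else {
      m <- seq_len(P - 1L)      # real adjacent pairs (epoch m, epoch m+1)
      wReal <- pmin(L - 1L, m) - pmax(1L, m - P + L) + 1L
      Xreal <- pairColumns(rec@X[m, , drop = FALSE],
                           rec@X[m + 1L, , drop = FALSE], H)
      mPad <- L:P                # each window's last position: zero bottom
      Xpad <- pairColumns(rec@X[mPad, , drop = FALSE],
                          matrix(0, length(mPad), M), H)
      Xs[[length(Xs) + 1L]] <- cbind(Xreal, Xpad)
      ys[[length(ys) + 1L]] <- c(y[m], y[mPad])
      ws[[length(ws) + 1L]] <- c(wReal, rep(1L, length(mPad)))
    }
  }
  list(X = do.call(cbind, Xs), y = unlist(ys), w = as.numeric(unlist(ws)))
}

weightedAccuracy <- function(params, arch, X, y, w, nStages, chunk = 512L) {
  N <- ncol(X)
  correct <- 0
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(N, s + chunk - 1L)
    fw <- scnnBatchForward(params, arch, X[, idx, drop = FALSE])
    pred <- max.col(t(fw$logits), ties.method = "first")
    correct <- correct + sum(w[idx] * (pred == y[idx]))
  }
  correct / sum(w)
}

#' Train a sequential CNN on labelled recordings
#'
#' Minimises the multiplicity-weighted cross-entropy over all (window,
#' position) slots of every length-L window of the training recordings,
#' using Adam with seeded shuffling, dropout on the concatenated features,
#' and early stopping on validation accuracy (best parameters are kept).
#' When `valid` is empty, a seeded fraction of the training pairs
#' (`config@validFraction`) is held out instead.
#'
#' @param model an [SCNNModel-class] from [buildScnn()].
#' @param train non-empty list of [EpochedRecording-class] objects.
#' @param valid optional list of validation recordings.
#' @param L window length in epochs (default 10).
#' @param verbose print per-epoch progress.
#' @return the trained [SCNNModel-class] with its training history.
#' @export
trainScnn <- function(model, train, valid = list(), L = 10L,
                      verbose = FALSE) {
  stopifnot(is(model, "SCNNModel"))
  if (!length(train)) stop("training set is empty")
  config <- model@config
  arch <- model@arch
  C <- config@nStages
  if (length(valid)) {
    vdata <- buildPairData(valid, L, arch)
    data <- buildPairData(train, L, arch)
  } else {
    # hold out the trailing block of each recording's epochs, so validation
    # pairs share no epochs with training pairs (a random pair split would
    # leak through the epoch overlap of adjacent pairs)
    sliceRec <- function(rec, from, to)
      initialize(rec, X = rec@X[from:to, , drop = FALSE],
                 labels = rec@labels[from:to])
    trainPart <- list(); validPart <- list()
    for (rec in train) {
      P <- nrow(rec@X)
      cut <- max(L, P - max(L, ceiling(config@validFraction * P)))
      if (P - cut < L) {    # too short to split: use the whole recording
        trainPart[[length(trainPart) + 1L]] <- rec
        next
      }
      trainPart[[length(trainPart) + 1L]] <- sliceRec(rec, 1L, cut)
      validPart[[length(validPart) + 1L]] <- sliceRec(rec, cut + 1L, P)
    }
    if (!length(validPart))
      stop("recordings too short to carve a validation block; pass `valid`")
    data <- buildPairData(trainPart, L, arch)
    vdata <- buildPairData(validPart, L, arch)
  }

  w <- data$w
  if (config@classWeights) {
    freq <- tabulate(data$y, C)
    cw <- sum(freq) / (C * pmax(freq, 1))
    w <- w * cw[data$y]
  }

  N <- ncol(data$X)
  bs <- config@batchSize

  trainOnce <- function(params, attemptSeed) {
    state <- list(t = 0L, m = lapply(params, function(x) x * 0),
                  v = lapply(params, function(x) x * 0))
    best <- list(acc = -Inf, params = params)
    waited <- 0L
    hist <- data.frame()
    for (ep in seq_len(config@maxEpochs)) {
      ord <- withSeed(childSeed(attemptSeed, 100L + ep), sample.int(N))
      epLoss <- 0; epW <- 0; epCorrect <- 0
      dropRng <- childSeed(attemptSeed, 200L + ep)
      nb <- 0L
      for (s in seq(1L, N, by = bs)) {
        idx <- ord[s:min(N, s + bs - 1L)]
        Xb <- data$X[, idx, drop = FALSE]
        yb <- data$y[idx]
        wb <- w[idx]
        nb <- nb + 1L
        dropMask <- NULL
        if (config@dropout > 0) {
          nFeat <- ncol(params$Wd)
          dropMask <- withSeed(childSeed(dropRng, nb),
            matrix(stats::runif(nFeat * length(idx)) >= config@dropout,
                   nFeat, length(idx))) / (1 - config@dropout)
        }
        fw <- scnnBatchForward(params, arch, Xb, keepCache = TRUE,
                               dropMask = dropMask)
        pr <- softmaxCols(fw$logits)
        sw <- sum(wb)
        epLoss <- epLoss +
          sum(wb * -log(pmax(pr[cbind(yb, seq_along(idx))], 1e-12)))
        epCorrect <- epCorrect +
          sum(wb * (max.col(t(fw$logits), ties.method = "first") == yb))
        epW <- epW + sw
        Y <- matrix(0, C, length(idx))
        Y[cbind(yb, seq_along(idx))] <- 1
        dLogits <- sweep(pr - Y, 2L, wb / sw, "*")
        grads <- scnnBatchBackward(params, arch, fw, dLogits,
                                   dropMask = dropMask)
        upd <- adamStep(params, grads, state, config@lr)
        params <- upd$params
        state <- upd$state
      }
      vAcc <- weightedAccuracy(params, arch, vdata$X, vdata$y, vdata$w, C)
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss / epW,
                                     trainAcc = epCorrect / epW,
                                     validAcc = vAcc))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f train acc %.3f valid acc %.3f",
                        ep, epLoss / epW, epCorrect / epW, vAcc))
      if (vAcc > best$acc + 1e-6) {
        best <- list(acc = vAcc, params = params)
        waited <- 0L
      } else {
        waited <- waited + 1L
        if (waited >= config@patience) break
      }
    }
    list(best = best, hist = hist)
  }

  # Small networks occasionally converge to poor optima; retry from fresh
  # seeded initialisations. The best-validation attempt becomes the model's
  # parameters; attempts within 0.01 validation accuracy of it (near-ties)
  # form a prediction ensemble whose probabilities are averaged at
  # inference. The band is deliberately narrow: averaging clearly weaker
  # attempts softens the probability margins, which matters when fused
  # scores compete against another subgroup's confident model.
  runs <- list()
  for (a in seq_len(max(1L, config@restarts))) {
    attemptSeed <- if (a == 1L) config@seed
                   else childSeed(config@seed, 5000L + a)
    params0 <- if (a == 1L) model@params
               else withSeed(attemptSeed, initParams(config, arch))
    runs[[a]] <- trainOnce(params0, attemptSeed)
    if (verbose && config@restarts > 1L)
      message(sprintf("attempt %d: best validation accuracy %.3f", a,
                      runs[[a]]$best$acc))
    if (runs[[a]]$best$acc >= config@restartFloor) break
  }
  accs <- vapply(runs, function(r) r$best$acc, numeric(1))
  champion <- runs[[which.max(accs)]]
  keep <- which(accs >= max(accs) - 0.01)
  initialize(model, params = champion$best$params,
             attempts = lapply(runs[keep], function(r) r$best$params),
             history = champion$hist, trained = TRUE)
}

#' Save / load a trained model
#'
#' The parameter store and configuration are serialised together with RDS.
#'
#' @param model an [SCNNModel-class].
#' @param path file path.
#' @return `saveScnn()` returns `path` invisibly; `readScnn()` the model.
#' @export
saveScnn <- function(model, path) {
  stopifnot(is(model, "SCNNModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveScnn
#' @export
readScnn <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "SCNNModel"))
  m
}
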