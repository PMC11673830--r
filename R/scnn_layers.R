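# Internal neural-network primitives for the sequential CNN.
#
# Activations are stored as dense (channels x width*batch) matrices whose
# columns are grouped per sample; convolutions are im2col products against
# precomputed sparse patch-extraction operators, so forward and backward
# passes reduce to BLAS matrix multiplies.

# Sparse patch extractor: maps a flattened (inC x inW) input (channel
# fastest) to stacked im2col columns of a kernel of width kw and stride,
# with asymmetric zero padding. Out-of-range taps are simply absent rows,
# which is equivalent to zero padding.
makeIm2col <- function(inC, inW, kw, stride, padL = 0L, padR = 0L) {
  Wout <- (inW + padL + padR - kw) %/% stride + 1L
  K <- inC * kw
  r <- seq_len(K * Wout)
  k <- (r - 1L) %% K
  t <- (r - 1L) %/% K
  ch <- k %% inC
  off <- k %/% inC
  pos <- t * stride - padL + off          # 0-based input position
  ok <- pos >= 0L & pos < inW
  # Forward patch extraction is plain row indexing into the input augmented
  # with one zero row; out-of-range (padding) taps point at that row.
  idx <- rep(inC * inW + 1L, K * Wout)
  idx[ok] <- (ch + pos * inC + 1L)[ok]
  # Backward scatter uses the transposed sparse operator.
  St <- Matrix::sparseMatrix(i = (ch + pos * inC + 1L)[ok], j = r[ok], x = 1,
                             dims = c(inC * inW, K * Wout))
  list(idx = idx, St = St, K = K, Wout = Wout, inC = inC, inW = inW)
}

convForward <- function(op, Xflat, W, b) {
  cols <- matrix(rbind(Xflat, 0)[op$idx, , drop = FALSE], nrow = op$K)
  Z <- W %*% cols + b
  list(act = Z * (Z > 0), cols = cols)
}

convBackward <- function(op, cache, W, dAct, needInput = TRUE) {
  dZ <- dAct * (cache$act > 0)
  out <- list(dW = tcrossprod(dZ, cache$cols), db = rowSums(dZ))
  if (needInput) {
    dCols <- crossprod(W, dZ)                        # K x (Wout*B)
    dFlat <- op$St %*% matrix(dCols, nrow = op$K * op$Wout)
    out$dX <- matrix(as.matrix(dFlat), nrow = op$inC) # inC x (inW*B)
  }
  out
}

maxPool <- function(A, W, p) {
  B <- ncol(A) %/% W
  p <- min(p, W)
  Wp <- W %/% p
  base <- as.vector(outer((seq_len(Wp) - 1L) * p, (seq_len(B) - 1L) * W, "+"))
  out <- A[, base + 1L, drop = FALSE]
  amax <- matrix(1L, nrow(A), length(base))
  if (p > 1L) for (q in 2L:p) {
    cand <- A[, base + q, drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    amax[upd] <- q
  }
  list(act = out, amax = amax, base = base, W = W, Wp = Wp, p = p, B = B)
}

maxPoolBackward <- function(cache, dOut) {
  dA <- matrix(0, nrow(dOut), cache$W * cache$B)
  for (q in seq_len(cache$p)) {
    blk <- matrix(0, nrow(dOut), length(cache$base))
    sel <- cache$amax == q
    blk[sel] <- dOut[sel]
    dA[, cache$base + q] <- blk
  }
  dA
}

sigmoid <- function(x) 1 / (1 + exp(-x))

seForward <- function(A, W, Ws1, bs1, Ws2, bs2) {
  B <- ncol(A) %/% W
  grp <- rep(seq_len(B), each = W)
  s <- t(rowsum(t(A), group = grp)) / W              # O x B squeeze
  z1 <- Ws1 %*% s + bs1
  z1 <- z1 * (z1 > 0)
  g <- sigmoid(Ws2 %*% z1 + bs2)                     # O x B gates in (0,1)
  list(act = A * g[, grp, drop = FALSE], s = s, z1 = z1, g = g, grp = grp,
       W = W)
}

seBackward <- function(cache, A, Ws1, Ws2, dOut) {
  g <- cache$g; grp <- cache$grp
  dA <- dOut * g[, grp, drop = FALSE]
  dG <- t(rowsum(t(dOut * A), group = grp))          # O x B
  dgp <- dG * g * (1 - g)
  dz1 <- crossprod(Ws2, dgp) * (cache$z1 > 0)
  ds <- crossprod(Ws1, dz1)
  list(dA = dA + ds[, grp, drop = FALSE] / cache$W,
       dWs2 = dgp %*% t(cache$z1), dbs2 = rowSums(dgp),
       dWs1 = dz1 %*% t(cache$s), dbs1 = rowSums(dz1))
}

gap <- function(A, W) {
  B <- ncol(A) %/% W
  grp <- rep(seq_len(B), each = W)
  t(rowsum(t(A), group = grp)) / W
}

gapBackward <- function(dOut, W) {
  B <- ncol(dOut)
  dOut[, rep(seq_len(B), each = W), drop = FALSE] / W
}

softmaxCols <- function(Z) {
  mx <- Z[1L, ]
  for (i in seq_len(nrow(Z))[-1L]) mx <- pmax(mx, Z[i, ])
  E <- exp(sweep(Z, 2L, mx))
  sweep(E, 2L, colSums(E), "/")
}

# One full forward pass over a batch of flattened epoch pairs.
# Xb: (kernelH * M) x B matrix. Returns logits and (optionally) caches.
scnnBatchForward <- function(params, arch, Xb, keepCache = FALSE,
                             dropMask = NULL) {
  feats <- list(); caches <- list()
  for (br in c("s", "l")) {
    a <- arch[[br]]
    c1 <- convForward(a$op1, Xb, params[[paste0("W1.", br)]],
                      params[[paste0("b1.", br)]])
    p1 <- maxPool(c1$act, a$op1$Wout, a$pool1)
    c2 <- convForward(a$op2, matrix(p1$act, nrow = a$op2$inC * a$op2$inW),
                      params[[paste0("W2.", br)]],
                      params[[paste0("b2.", br)]])
    p2 <- maxPool(c2$act, a$op2$Wout, a$pool2)
    c3 <- convForward(a$op3, matrix(p2$act, nrow = a$op3$inC * a$op3$inW),
                      params[[paste0("W3.", br)]],
                      params[[paste0("b3.", br)]])
    se <- seForward(c3$act, a$op3$Wout,
                    params[[paste0("se1W.", br)]],
                    params[[paste0("se1b.", br)]],
                    params[[paste0("se2W.", br)]],
                    params[[paste0("se2b.", br)]])
    feats[[br]] <- gap(se$act, a$op3$Wout)
    if (keepCache)
      caches[[br]] <- list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3,
                           se = se)
  }
  feat <- rbind(feats$s, feats$l)
  if (!is.null(dropMask)) feat <- feat * dropMask
  logits <- params$Wd %*% feat + params$bd
  list(logits = logits, feat = feat, caches = caches)
}

scnnBatchBackward <- function(params, arch, fwd, dLogits, dropMask = NULL) {
  g <- list(Wd = dLogits %*% t(fwd$feat), bd = rowSums(dLogits))
  dFeat <- crossprod(params$Wd, dLogits)
  if (!is.null(dropMask)) dFeat <- dFeat * dropMask
  O <- nrow(fwd$feat) / 2L
  for (br in c("s", "l")) {
    a <- arch[[br]]
    cc <- fwd$caches[[br]]
    dGap <- if (br == "s") dFeat[seq_len(O), , drop = FALSE]
            else dFeat[O + seq_len(O), , drop = FALSE]
    dSe <- gapBackward(dGap, a$op3$Wout)
    seb <- seBackward(cc$se, cc$c3$act, params[[paste0("se1W.", br)]],
                      params[[paste0("se2W.", br)]], dSe)
    g[[paste0("se1W.", br)]] <- seb$dWs1
    g[[paste0("se1b.", br)]] <- seb$dbs1
    g[[paste0("se2W.", br)]] <- seb$dWs2
    g[[paste0("se2b.", br)]] <- seb$dbs2
    b3 <- convBackward(a$op3, cc$c3, params[[paste0("W3.", br)]], seb$dA)
    g[[paste0("W3.", br)]] <- b3$dW
    g[[paste0("b3.", br)]] <- b3$db
    dP2 <- matrix(b3$dX, nrow = nrow(cc$c2$act))
    dA2 <- maxPoolBackward(cc$p2, dP2)
    b2 <- convBackward(a$op2, cc$c2, params[[paste0("W2.", br)]], dA2)
    g[[paste0("W2.", br)]] <- b2$dW
    g[[paste0("b2.", br)]] <- b2$db
    dP1 <- matrix(b2$dX, nrow = nrow(cc$c1$act))
    dA1 <- maxPoolBackward(cc$p1, dP1)
    b1 <- convBackward(a$op1, cc$c1, params[[paste0("W1.", br)]], dA1,
                       needInput = FALSE)
    g[[paste0("W1.", br)]] <- b1$dW
    g[[paste0("b1.", br)]] <- b1$db
  }
  g
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
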