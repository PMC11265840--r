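## Vectorized convnet primitives (im2col + BLAS) with hand-written
## backprop.  Layout everywhere: arrays (H, W, C, B); im2col matrices
## (H*W*B) x (9*C) with kernel-row order (ki, kj, c), ki fastest.

.idxCache <- new.env(parent = emptyenv())

.im2colIndex <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  nPix <- H * W
  base <- matrix(0L, nPix, 9L * C)
  k <- 1L
  for (c0 in seq_len(C)) for (kj in 0:2) for (ki in 0:2) {
    base[, k] <- (oi + ki) + (oj + kj - 1L) * Hp + (c0 - 1L) * Hp * Wp
    k <- k + 1L
  }
  idx <- if (B > 1L) {
    len <- Hp * Wp * C
    base[rep(seq_len(nPix), times = B), , drop = FALSE] +
      rep((seq_len(B) - 1L) * len, each = nPix)
  } else base
  .idxCache[[key]] <- idx
  idx
}

.pad1 <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  Xp[1L + seq_len(d[1]), 1L + seq_len(d[2]), , ] <- X
  Xp
}

## 3x3 same-size convolution, no bias.
.convFwd <- function(X, Wmat) {
  d <- dim(X)
  idx <- .im2colIndex(d[1], d[2], d[3], d[4])
  M <- matrix(.pad1(X)[idx], nrow = nrow(idx))
  Y <- M %*% Wmat
  dim(Y) <- c(d[1], d[2], d[4], ncol(Wmat))
  list(Y = aperm(Y, c(1, 2, 4, 3)), M = M)
}

.convBwd <- function(dY, M, Wmat, dimsX) {
  d <- dimsX
  Cout <- dim(dY)[3]
  dYm <- aperm(dY, c(1, 2, 4, 3))
  dim(dYm) <- c(d[1] * d[2] * d[4], Cout)
  dW <- crossprod(M, dYm)
  dM <- tcrossprod(dYm, Wmat)
  idx <- .im2colIndex(d[1], d[2], d[3], d[4])
  Hp <- d[1] + 2L; Wp <- d[2] + 2L
  acc <- numeric(Hp * Wp * d[3] * d[4])
  for (k in seq_len(ncol(dM))) {   # each column's targets are distinct
    ik <- idx[, k]
    acc[ik] <- acc[ik] + dM[, k]
  }
  dim(acc) <- c(Hp, Wp, d[3], d[4])
  list(dW = dW,
       dX = acc[1L + seq_len(d[1]), 1L + seq_len(d[2]), , , drop = FALSE])
}

.toChanMat <- function(X) {          # (H,W,C,B) -> (H*W*B) x C
  d <- dim(X)
  m <- aperm(X, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

.fromChanMat <- function(m, d) {     # inverse of .toChanMat
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

.bnEps <- 1e-5

.bnFwdTrain <- function(V, gamma, beta) {
  n <- nrow(V)
  mu <- colMeans(V)
  xc <- V - rep(mu, each = n)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + .bnEps)
  xhat <- xc * rep(istd, each = n)
  list(Y = xhat * rep(gamma, each = n) + rep(beta, each = n),
       xhat = xhat, istd = istd, mu = mu, va = va)
}

.bnFwdEval <- function(V, gamma, beta, mu, va) {
  n <- nrow(V)
  istd <- 1 / sqrt(va + .bnEps)
  xhat <- (V - rep(mu, each = n)) * rep(istd, each = n)
  xhat * rep(gamma, each = n) + rep(beta, each = n)
}

.bnBwd <- function(dYm, xhat, istd, gamma) {
  n <- nrow(dYm)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxh <- dYm * rep(gamma, each = n)
  s1 <- colSums(dxh) / n
  s2 <- colSums(dxh * xhat) / n
  dV <- (dxh - rep(s1, each = n) - xhat * rep(s2, each = n)) *
    rep(istd, each = n)
  list(dV = dV, dgamma = dgamma, dbeta = dbeta)
}

.pool2Fwd <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  (X[i1, j1, , , drop = FALSE] + X[i1 + 1L, j1, , , drop = FALSE] +
     X[i1, j1 + 1L, , , drop = FALSE] +
     X[i1 + 1L, j1 + 1L, , , drop = FALSE]) / 4
}

.pool2Bwd <- function(dY, dimsX) {
  dX <- array(0, dimsX)
  i1 <- seq(1L, dimsX[1], 2L); j1 <- seq(1L, dimsX[2], 2L)
  q <- dY / 4
  dX[i1, j1, , ] <- q
  dX[i1 + 1L, j1, , ] <- q
  dX[i1, j1 + 1L, , ] <- q
  dX[i1 + 1L, j1 + 1L, , ] <- q
  dX
}

.gapFwd <- function(X) {             # -> B x C feature matrix
  d <- dim(X)
  m <- X
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(m), d[3], d[4]))
}

.gapBwd <- function(dFeats, dimsX) {
  hw <- dimsX[1] * dimsX[2]
  v <- rep(as.vector(t(dFeats)) / hw, each = hw)
  dim(v) <- dimsX
  v
}

.softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---- ConvNetModel forward / backward ------------------------------------
##
## The encoder (4 conv-BN-ReLU-pool blocks) is shared across the stacked
## RGB triplets: the (ps, ps, 3*nP, B) input is viewed as nP*B three-
## channel patches, encoded, GAP-ed to per-patch embeddings, and
## summarized across patches by mean and maximum before the linear head.

.convnetForward <- function(model, X, train = FALSE) {
  p <- model@params
  run <- model@running
  nb <- length(model@arch$channels)
  nP <- model@arch$nPatch
  d0 <- dim(X)
  B <- d0[4]
  dim(X) <- c(d0[1], d0[2], 3L, nP * B)     # patch-shared encoder view
  cache <- if (train) list(blocks = vector("list", nb)) else NULL
  for (b in seq_len(nb)) {
    dimsIn <- dim(X)
    cf <- .convFwd(X, p[[paste0("W", b)]])
    V <- .toChanMat(cf$Y)
    g <- p[[paste0("g", b)]]; be <- p[[paste0("be", b)]]
    if (train) {
      bn <- .bnFwdTrain(V, g, be)
      mom <- 0.1
      run[[paste0("mu", b)]] <- (1 - mom) * run[[paste0("mu", b)]] + mom * bn$mu
      run[[paste0("va", b)]] <- (1 - mom) * run[[paste0("va", b)]] + mom * bn$va
      Ybn <- bn$Y
    } else {
      Ybn <- .bnFwdEval(V, g, be, run[[paste0("mu", b)]],
                        run[[paste0("va", b)]])
    }
    mask <- Ybn > 0
    R <- .fromChanMat(Ybn * mask, dim(cf$Y))
    Xn <- .pool2Fwd(R)
    if (train)
      cache$blocks[[b]] <- list(dimsIn = dimsIn, M = cf$M, xhat = bn$xhat,
                                istd = bn$istd, mask = mask,
                                dimsPre = dim(cf$Y))
    X <- Xn
  }
  feats <- .gapFwd(X)                       # (nP*B) x C, rows patch-major
  C <- ncol(feats)
  F3 <- feats
  dim(F3) <- c(nP, B, C)
  meanF <- colMeans(F3)                     # B x C
  if (nP > 1L) {
    maxF <- apply(F3, c(2, 3), max)
    amax <- apply(F3, c(2, 3), which.max)
  } else {
    maxF <- meanF
    amax <- matrix(1L, B, C)
  }
  if (is.null(dim(meanF))) {                # B == 1 edge case
    meanF <- matrix(meanF, 1L, C)
    maxF <- matrix(maxF, 1L, C)
    amax <- matrix(amax, 1L, C)
  }
  Hfeat <- cbind(meanF, maxF)               # B x 2C
  logits <- Hfeat %*% p$fcW +
    matrix(p$fcb, nrow(Hfeat), length(p$fcb), byrow = TRUE)
  probs <- .softmaxRows(logits)
  if (train) {
    cache$Hfeat <- Hfeat
    cache$amax <- amax
    cache$nP <- nP; cache$B <- B; cache$C <- C
    cache$dimsLast <- dim(X)
  }
  model@running <- run
  list(probs = probs, cache = cache, model = model)
}

.convnetBackward <- function(model, cache, dZ) {
  p <- model@params
  grads <- list(fcW = crossprod(cache$Hfeat, dZ), fcb = colSums(dZ))
  dH <- tcrossprod(dZ, p$fcW)               # B x 2C
  nP <- cache$nP; B <- cache$B; C <- cache$C
  dMean <- dH[, seq_len(C), drop = FALSE]
  dMax <- dH[, C + seq_len(C), drop = FALSE]
  dF3 <- array(rep(as.vector(dMean) / nP, each = nP), c(nP, B, C))
  idx <- cbind(as.vector(cache$amax), rep(seq_len(B), C),
               rep(seq_len(C), each = B))
  dF3[idx] <- dF3[idx] + as.vector(dMax)
  dFeats <- dF3
  dim(dFeats) <- c(nP * B, C)
  dX <- .gapBwd(dFeats, cache$dimsLast)
  nb <- length(model@arch$channels)
  for (b in rev(seq_len(nb))) {
    cb <- cache$blocks[[b]]
    dR <- .pool2Bwd(dX, cb$dimsPre)
    dYm <- .toChanMat(dR) * cb$mask
    bn <- .bnBwd(dYm, cb$xhat, cb$istd, p[[paste0("g", b)]])
    grads[[paste0("g", b)]] <- bn$dgamma
    grads[[paste0("be", b)]] <- bn$dbeta
    dConv <- .fromChanMat(bn$dV, cb$dimsPre)
    cv <- .convBwd(dConv, cb$M, p[[paste0("W", b)]], cb$dimsIn)
    grads[[paste0("W", b)]] <- cv$dW
    dX <- cv$dX
  }
  grads
}

## ---- GapLinearModel forward / backward ----------------------------------

.gapLinForward <- function(model, X, train = FALSE) {
  feats <- .gapFwd(X)
  logits <- feats %*% model@params$W +
    matrix(model@params$b, nrow(feats), 4L, byrow = TRUE)
  list(probs = .softmaxRows(logits),
       cache = if (train) list(feats = feats) else NULL,
       model = model)
}

.gapLinBackward <- function(model, cache, dZ) {
  list(W = crossprod(cache$feats, dZ), b = colSums(dZ))
}

## ---- dispatch helpers ----------------------------------------------------

.bbForward <- function(model, X, train = FALSE) {
  if (is(model, "ConvNetModel")) .convnetForward(model, X, train)
  else .gapLinForward(model, X, train)
}

.bbBackward <- function(model, cache, dZ) {
  if (is(model, "ConvNetModel")) .convnetBackward(model, cache, dZ)
  else .gapLinBackward(model, cache, dZ)
}

## AdamW with decoupled weight decay; no decay on batch-norm / bias terms.
.adamwInit <- function(params)
  list(t = 0,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))

.adamwStep <- function(params, grads, state, lr, weightDecay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    wd <- if (grepl("^(g|be|fcb|b)[0-9]*$", nm)) 0 else weightDecay
    params[[nm]] <- params[[nm]] -
      lr * ((state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps) +
              wd * params[[nm]])
  }
  list(params = params, state = state)
}
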