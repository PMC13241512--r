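## Minimal neural-network layer library (forward + hand-written backward)
## used by the modality encoders. Dense, ReLU, 1D/2D convolution (im2col on
## top of BLAS matrix products), layer norm, single-head self-attention and
## an Adam optimizer. Parameters live in nested named lists of numeric
## arrays; gradients mirror that structure exactly.

## ---- nested parameter-list helpers --------------------------------------

paramMap <- function(f, p) {
  if (is.list(p)) lapply(p, function(x) paramMap(f, x)) else f(p)
}

paramZip <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- paramZip(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

paramZero <- function(p) paramMap(function(x) x * 0, p)

paramCount <- function(p) {
  tot <- 0
  paramMap(function(x) { tot <<- tot + length(x); x }, p)
  tot
}

## flatten/unflatten for gradient checking
paramFlatten <- function(p) {
  out <- numeric(0)
  paramMap(function(x) { out <<- c(out, as.numeric(x)); x }, p)
  out
}

paramUnflatten <- function(p, v) {
  i <- 0
  paramMap(function(x) {
    n <- length(x)
    y <- array(v[(i + 1):(i + n)], dim = if (is.null(dim(x))) n else dim(x))
    if (is.null(dim(x))) y <- as.numeric(y)
    i <<- i + n
    y
  }, p)
}

## He-style initialization
initMat <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

## ---- dense / relu -------------------------------------------------------

denseInit <- function(nin, nout) list(W = initMat(nin, nout),
                                      b = numeric(nout))

denseFwd <- function(p, X) {
  Y <- X %*% p$W
  Y <- sweep(Y, 2, p$b, "+")
  list(Y = Y, cache = X)
}

denseBwd <- function(p, cache, dY) {
  list(grads = list(W = crossprod(cache, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))
}

reluFwd <- function(X) list(Y = pmax(X, 0), cache = X > 0)
reluBwd <- function(cache, dY) dY * cache

## ---- 1D convolution -----------------------------------------------------

## X: array (n, L, Cin); weight W: (K*Cin, Cout); zero padding `pad` on both
## ends of the length axis
padAxis1d <- function(X, pad) {
  if (pad == 0) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  Xp[, (pad + 1):(pad + d[2]), ] <- X
  Xp
}

conv1dInit <- function(K, Cin, Cout) {
  list(W = initMat(K * Cin, Cout), b = numeric(Cout))
}

conv1dFwd <- function(p, X, stride = 1, pad = 0) {
  X <- padAxis1d(X, pad)
  d <- dim(X); n <- d[1]; L <- d[2]; Cin <- d[3]
  Cout <- ncol(p$W); K <- nrow(p$W) / Cin
  Lout <- (L - K) %/% stride + 1
  starts <- (seq_len(Lout) - 1) * stride + 1
  if (stride == K && Cin == 1 && L == Lout * K) {
    # non-overlapping windows: im2col is a plain reshape
    Xcol <- matrix(aperm(array(X, c(n, K, Lout)), c(1, 3, 2)), n * Lout, K)
  } else {
  Xcol <- matrix(0, n * Lout, K * Cin)
  for (k in seq_len(K))
    Xcol[, ((k - 1) * Cin + 1):(k * Cin)] <-
      matrix(X[, starts + k - 1, , drop = FALSE], n * Lout, Cin)
  }
  Y <- sweep(Xcol %*% p$W, 2, p$b, "+")
  list(Y = array(Y, c(n, Lout, Cout)),
       cache = list(Xcol = Xcol, dimX = d, stride = stride, pad = pad,
                    K = K, starts = starts))
}

conv1dBwd <- function(p, cache, dY) {
  d <- cache$dimX; n <- d[1]; Cin <- d[3]
  Cout <- ncol(p$W); Lout <- dim(dY)[2]
  dYm <- matrix(dY, n * Lout, Cout)
  grads <- list(W = crossprod(cache$Xcol, dYm), b = colSums(dYm))
  dXcol <- tcrossprod(dYm, p$W)
  if (cache$stride == cache$K && Cin == 1 && cache$pad == 0 &&
      d[2] == Lout * cache$K) {
    # non-overlapping windows: the scatter is a plain inverse reshape
    dX <- array(aperm(array(dXcol, c(n, Lout, cache$K)), c(1, 3, 2)), d)
    return(list(grads = grads, dX = dX))
  }
  dX <- array(0, d)
  for (k in seq_len(cache$K)) {
    idx <- cache$starts + k - 1
    dX[, idx, ] <- dX[, idx, , drop = FALSE] +
      array(dXcol[, ((k - 1) * Cin + 1):(k * Cin)], c(n, Lout, Cin))
  }
  if (cache$pad > 0)
    dX <- dX[, (cache$pad + 1):(d[2] - cache$pad), , drop = FALSE]
  list(grads = grads, dX = dX)
}

## ---- 2D convolution -----------------------------------------------------

## X: array (n, H, W, Cin); weight: (K*K*Cin, Cout)
padAxis2d <- function(X, pad) {
  if (pad == 0) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  Xp[, (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3]), ] <- X
  Xp
}

conv2dInit <- function(K, Cin, Cout) {
  list(W = initMat(K * K * Cin, Cout), b = numeric(Cout))
}

conv2dFwd <- function(p, X, stride = 1, pad = 0, K) {
  X <- padAxis2d(X, pad)
  d <- dim(X); n <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- ncol(p$W)
  Ho <- (H - K) %/% stride + 1; Wo <- (Wd - K) %/% stride + 1
  si <- (seq_len(Ho) - 1) * stride + 1
  sj <- (seq_len(Wo) - 1) * stride + 1
  Xcol <- matrix(0, n * Ho * Wo, K * K * Cin)
  col <- 0
  for (kj in seq_len(K)) for (ki in seq_len(K)) {
    sl <- X[, si + ki - 1, sj + kj - 1, , drop = FALSE]
    Xcol[, (col * Cin + 1):((col + 1) * Cin)] <-
      matrix(sl, n * Ho * Wo, Cin)
    col <- col + 1
  }
  Y <- sweep(Xcol %*% p$W, 2, p$b, "+")
  list(Y = array(Y, c(n, Ho, Wo, Cout)),
       cache = list(Xcol = Xcol, dimX = d, stride = stride, pad = pad,
                    K = K, si = si, sj = sj))
}

conv2dBwd <- function(p, cache, dY) {
  d <- cache$dimX; n <- d[1]; Cin <- d[4]
  Ho <- dim(dY)[2]; Wo <- dim(dY)[3]; Cout <- dim(dY)[4]
  dYm <- matrix(dY, n * Ho * Wo, Cout)
  grads <- list(W = crossprod(cache$Xcol, dYm), b = colSums(dYm))
  dXcol <- tcrossprod(dYm, p$W)
  dX <- array(0, d)
  col <- 0
  for (kj in seq_len(cache$K)) for (ki in seq_len(cache$K)) {
    ii <- cache$si + ki - 1; jj <- cache$sj + kj - 1
    dX[, ii, jj, ] <- dX[, ii, jj, , drop = FALSE] +
      array(dXcol[, (col * Cin + 1):((col + 1) * Cin)], c(n, Ho, Wo, Cin))
    col <- col + 1
  }
  if (cache$pad > 0) {
    p2 <- cache$pad
    dX <- dX[, (p2 + 1):(d[2] - p2), (p2 + 1):(d[3] - p2), , drop = FALSE]
  }
  list(grads = grads, dX = dX)
}

## non-overlapping average pooling on a (n, H, W, C) array
avgPool2dFwd <- function(X, p) {
  d <- dim(X); n <- d[1]; H <- d[2] %/% p; Wd <- d[3] %/% p; C <- d[4]
  Y <- array(0, c(n, H, Wd, C))
  for (i in seq_len(p)) for (j in seq_len(p))
    Y <- Y + X[, seq(i, by = p, length.out = H),
               seq(j, by = p, length.out = Wd), , drop = FALSE]
  list(Y = Y / p^2, cache = list(dimX = d, p = p))
}

avgPool2dBwd <- function(cache, dY) {
  d <- cache$dimX; p <- cache$p
  H <- dim(dY)[2]; Wd <- dim(dY)[3]
  dX <- array(0, d)
  for (i in seq_len(p)) for (j in seq_len(p))
    dX[, seq(i, by = p, length.out = H),
       seq(j, by = p, length.out = Wd), ] <- dY / p^2
  dX
}

## ---- layer norm (over the last/feature axis of n x L x D) ---------------

lnInit <- function(D) list(g = rep(1, D), b = numeric(D))

lnFwd <- function(p, X, eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(X, d[1] * d[2], d[3])
  mu <- rowMeans(Xm)
  xc <- Xm - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  list(Y = array(Y, d), cache = list(xhat = xhat, inv = inv, d = d))
}

lnBwd <- function(p, cache, dY) {
  d <- cache$d
  dYm <- matrix(dY, d[1] * d[2], d[3])
  xhat <- cache$xhat; inv <- cache$inv; D <- d[3]
  dg <- colSums(dYm * xhat); db <- colSums(dYm)
  dxhat <- sweep(dYm, 2, p$g, "*")
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(grads = list(g = dg, b = db), dX = array(dX, d))
}

## ---- single-head self-attention -----------------------------------------

## X: (n, L, D). Optional `mask`: n x L logical, TRUE = real position.
## Masked (padding) positions are excluded as keys; their own outputs are
## garbage by construction and must be ignored downstream (pooling masks
## them out).
attnInit <- function(D) {
  list(Wq = initMat(D, D), Wk = initMat(D, D),
       Wv = initMat(D, D), Wo = initMat(D, D))
}

attnFwd <- function(p, X, mask = NULL) {
  d <- dim(X); n <- d[1]; L <- d[2]; D <- d[3]
  Y <- array(0, d)
  caches <- vector("list", n)
  sc <- 1 / sqrt(D)
  for (s in seq_len(n)) {
    Xi <- matrix(X[s, , ], L, D)
    Q <- Xi %*% p$Wq; K <- Xi %*% p$Wk; V <- Xi %*% p$Wv
    S <- tcrossprod(Q, K) * sc
    if (!is.null(mask)) S[, !mask[s, ]] <- -1e30
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    H <- A %*% V
    Y[s, , ] <- H %*% p$Wo
    caches[[s]] <- list(Xi = Xi, Q = Q, K = K, V = V, A = A, H = H)
  }
  list(Y = Y, cache = list(per = caches, d = d, sc = sc, mask = mask))
}

attnBwd <- function(p, cache, dY) {
  d <- cache$d; n <- d[1]; L <- d[2]; D <- d[3]
  g <- list(Wq = p$Wq * 0, Wk = p$Wk * 0, Wv = p$Wv * 0, Wo = p$Wo * 0)
  dX <- array(0, d)
  sc <- cache$sc
  for (s in seq_len(n)) {
    cc <- cache$per[[s]]
    dYi <- matrix(dY[s, , ], L, D)
    g$Wo <- g$Wo + crossprod(cc$H, dYi)
    dH <- tcrossprod(dYi, p$Wo)
    dA <- tcrossprod(dH, cc$V)
    dV <- crossprod(cc$A, dH)
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQ <- dS %*% cc$K * sc
    dK <- crossprod(dS, cc$Q) * sc
    g$Wq <- g$Wq + crossprod(cc$Xi, dQ)
    g$Wk <- g$Wk + crossprod(cc$Xi, dK)
    g$Wv <- g$Wv + crossprod(cc$Xi, dV)
    dX[s, , ] <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
                 tcrossprod(dV, p$Wv)
  }
  list(grads = g, dX = dX)
}

## ---- L2 normalization row-wise ------------------------------------------

l2normFwd <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  list(Y = X / nrm, cache = list(Y = X / nrm, nrm = nrm))
}

l2normBwd <- function(cache, dY) {
  Y <- cache$Y
  (dY - Y * rowSums(dY * Y)) / cache$nrm
}

## ---- Adam ---------------------------------------------------------------

adamInit <- function(params) {
  list(m = paramZero(params), v = paramZero(params), t = 0)
}

adamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- paramZip(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- paramZip(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- paramZip(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  params <- paramZip(`-`, params, upd)
  list(params = params, state = state)
}
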