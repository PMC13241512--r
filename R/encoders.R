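## Modality encoders. Architecture follows the package-wide design: a
## multi-layer perceptron for the binary 13C vector, residual convolutional
## networks with a self-attention block for 1H and HSQC, a plain CNN for IR,
## and a small token-level transformer over SMILES for the molecule side.
## Every encoder ends in a linear projection head to the shared dimension d
## followed by L2 normalization, so dot products in the shared space are
## exactly cosine similarities.

#' Encoder configuration
#'
#' @param d shared embedding dimension (default 64).
#' @param c13Hidden hidden sizes of the 13C MLP.
#' @param convChannels channel progression of the 1H conv stack.
#' @param fcHidden width of the fully connected layer before projection.
#' @param molDim,molLayers,molFF transformer width, depth and feed-forward
#'   width of the molecule encoder.
#' @param hsqcPool average-pooling factor applied to the HSQC grid before
#'   convolution.
#' @param maxTokens maximum SMILES length in tokens.
#' @param codec a [codecConfig] fixing the input vector lengths.
#' @param seed integer seed for weight initialization.
#' @return list of class `encoderConfig`.
#' @export
encoderConfig <- function(d = 64L, c13Hidden = c(256L, 128L),
                          convChannels = c(8L, 16L, 32L), fcHidden = 128L,
                          molDim = 64L, molLayers = 2L, molFF = 128L,
                          hsqcPool = 8L, maxTokens = 128L,
                          codec = codecConfig(), seed = 1L) {
  structure(list(d = as.integer(d), c13Hidden = as.integer(c13Hidden),
                 convChannels = as.integer(convChannels),
                 fcHidden = as.integer(fcHidden), molDim = as.integer(molDim),
                 molLayers = as.integer(molLayers), molFF = as.integer(molFF),
                 hsqcPool = as.integer(hsqcPool),
                 maxTokens = as.integer(maxTokens), codec = codec,
                 seed = as.integer(seed)),
            class = "encoderConfig")
}

## ---- SMILES tokenizer ---------------------------------------------------

SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]|Cl|Br|%[0-9]{2}|",
  "[BCNOPSFIbcnops]|[0-9]|[=#$/\\\\().+@<>*~-]")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' as single tokens, two-letter halogens, ring-bond digits and all
#' single-character symbols. The tokenization is reversible:
#' `paste(tokens, collapse = "")` restores the input.
#'
#' @param smiles a SMILES string.
#' @return character vector of tokens.
#' @export
tokenizeSmiles <- function(smiles) {
  m <- gregexpr(SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  tok <- regmatches(smiles, list(m))[[1]]
  if (sum(nchar(tok)) != nchar(smiles))
    stop("SMILES contains untokenizable characters: ", smiles)
  tok
}

#' @rdname tokenizeSmiles
#' @param tokens character vector of tokens.
#' @export
detokenizeSmiles <- function(tokens) paste(tokens, collapse = "")

buildVocab <- function(smilesVec) {
  toks <- sort(unique(unlist(lapply(smilesVec, tokenizeSmiles))))
  c("<pad>", "<unk>", toks)
}

tokensToIds <- function(tokens, vocab) {
  i <- match(tokens, vocab)
  i[is.na(i)] <- 2L   # <unk>
  i
}

## ---- encoder initialization ---------------------------------------------

conv1dOutLen <- function(L, K, s, pad = 0) (L + 2 * pad - K) %/% s + 1

initEncoders <- function(config, vocab) {
  cd <- config$codec; d <- config$d
  withSeed(config$seed, {
    params <- list()
    # 13C MLP
    sizes <- c(cd$c13Len, config$c13Hidden)
    params$c13 <- list(
      fc = lapply(seq_len(length(sizes) - 1),
                  function(i) denseInit(sizes[i], sizes[i + 1])),
      proj = denseInit(sizes[length(sizes)], d))
    # 1H residual CNN + attention
    ch <- config$convChannels
    L1 <- conv1dOutLen(cd$h1Len, 10, 10)
    L2 <- conv1dOutLen(L1, 9, 5)
    L3 <- conv1dOutLen(L2, 7, 4)
    params$h1 <- list(
      conv1 = conv1dInit(10, 1, ch[1]), conv2 = conv1dInit(9, ch[1], ch[2]),
      conv3 = conv1dInit(7, ch[2], ch[3]),
      res = conv1dInit(3, ch[3], ch[3]),
      attn = attnInit(ch[3]),
      fc = denseInit(L3 * ch[3], config$fcHidden),
      proj = denseInit(config$fcHidden, d))
    attr(params$h1, "dims") <- list(L3 = L3, C = ch[3])
    # IR CNN
    M1 <- conv1dOutLen(cd$irLen, 8, 8)
    M2 <- conv1dOutLen(M1, 9, 4)
    params$ir <- list(
      conv1 = conv1dInit(8, 1, ch[1]), conv2 = conv1dInit(9, ch[1], ch[2]),
      fc = denseInit(M2 * ch[2], config$fcHidden),
      proj = denseInit(config$fcHidden, d))
    attr(params$ir, "dims") <- list(M2 = M2, C = ch[2])
    # HSQC residual CNN + attention
    G0 <- cd$hsqcDim %/% config$hsqcPool
    G1 <- conv1dOutLen(G0, 3, 2)
    G2 <- conv1dOutLen(G1, 3, 2)
    params$hsqc <- list(
      conv1 = conv2dInit(3, 1, ch[1]), conv2 = conv2dInit(3, ch[1], ch[2]),
      res = conv2dInit(3, ch[2], ch[2]),
      attn = attnInit(ch[2]),
      fc = denseInit(G2 * G2 * ch[2], config$fcHidden),
      proj = denseInit(config$fcHidden, d))
    attr(params$hsqc, "dims") <- list(G2 = G2, C = ch[2])
    # molecule transformer
    D <- config$molDim
    params$molecule <- list(
      emb = initMat(length(vocab), D) * 0.5,
      pos = initMat(config$maxTokens, D) * 0.1,
      layers = lapply(seq_len(config$molLayers), function(i) list(
        ln1 = lnInit(D), attn = attnInit(D), ln2 = lnInit(D),
        ff1 = denseInit(D, config$molFF), ff2 = denseInit(config$molFF, D))),
      proj = denseInit(D, d))
    params
  })
}

## ---- per-modality forward / backward ------------------------------------

c13Fwd <- function(p, X) {
  caches <- list()
  H <- X
  for (i in seq_along(p$fc)) {
    f <- denseFwd(p$fc[[i]], H); r <- reluFwd(f$Y)
    caches[[i]] <- list(f = f$cache, r = r$cache)
    H <- r$Y
  }
  pr <- denseFwd(p$proj, H)
  nn <- l2normFwd(pr$Y)
  list(E = nn$Y, cache = list(fc = caches, proj = pr$cache, norm = nn$cache))
}

c13Bwd <- function(p, cache, dE) {
  dH <- l2normBwd(cache$norm, dE)
  pr <- denseBwd(p$proj, cache$proj, dH)
  g <- list(fc = vector("list", length(p$fc)), proj = pr$grads)
  dH <- pr$dX
  for (i in rev(seq_along(p$fc))) {
    dH <- reluBwd(cache$fc[[i]]$r, dH)
    bw <- denseBwd(p$fc[[i]], cache$fc[[i]]$f, dH)
    g$fc[[i]] <- bw$grads
    dH <- bw$dX
  }
  g
}

h1Fwd <- function(p, X) {
  dm <- list(C = ncol(p$conv3$W), L3 = nrow(p$fc$W) / ncol(p$conv3$W))
  n <- nrow(X)
  A0 <- array(X, c(n, ncol(X), 1))
  c1 <- conv1dFwd(p$conv1, A0, stride = 10); r1 <- reluFwd(c1$Y)
  c2 <- conv1dFwd(p$conv2, r1$Y, stride = 5); r2 <- reluFwd(c2$Y)
  c3 <- conv1dFwd(p$conv3, r2$Y, stride = 4); r3 <- reluFwd(c3$Y)
  cr <- conv1dFwd(p$res, r3$Y, stride = 1, pad = 1); rr <- reluFwd(cr$Y)
  R <- rr$Y + r3$Y                       # residual conv block
  at <- attnFwd(p$attn, R)
  Z <- at$Y + R                          # residual attention block
  Zm <- matrix(Z, n, dm$L3 * dm$C)
  f <- denseFwd(p$fc, Zm); rf <- reluFwd(f$Y)
  pr <- denseFwd(p$proj, rf$Y)
  nn <- l2normFwd(pr$Y)
  list(E = nn$Y,
       cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                    r2 = r2$cache, c3 = c3$cache, r3 = r3$cache,
                    cr = cr$cache, rr = rr$cache, at = at$cache,
                    f = f$cache, rf = rf$cache, pr = pr$cache,
                    norm = nn$cache, n = n, dm = dm))
}

h1Bwd <- function(p, cache, dE) {
  dm <- cache$dm; n <- cache$n
  dH <- l2normBwd(cache$norm, dE)
  pr <- denseBwd(p$proj, cache$pr, dH)
  dH <- reluBwd(cache$rf, pr$dX)
  f <- denseBwd(p$fc, cache$f, dH)
  dZ <- array(f$dX, c(n, dm$L3, dm$C))
  at <- attnBwd(p$attn, cache$at, dZ)
  dR <- at$dX + dZ
  dRr <- reluBwd(cache$rr, dR)
  cr <- conv1dBwd(p$res, cache$cr, dRr)
  dR3 <- cr$dX + dR
  dR3 <- reluBwd(cache$r3, dR3)
  c3 <- conv1dBwd(p$conv3, cache$c3, dR3)
  dR2 <- reluBwd(cache$r2, c3$dX)
  c2 <- conv1dBwd(p$conv2, cache$c2, dR2)
  dR1 <- reluBwd(cache$r1, c2$dX)
  c1 <- conv1dBwd(p$conv1, cache$c1, dR1)
  list(conv1 = c1$grads, conv2 = c2$grads, conv3 = c3$grads,
       res = cr$grads, attn = at$grads, fc = f$grads, proj = pr$grads)
}

irFwd <- function(p, X) {
  dm <- list(C = ncol(p$conv2$W), M2 = nrow(p$fc$W) / ncol(p$conv2$W))
  n <- nrow(X)
  A0 <- array(X, c(n, ncol(X), 1))
  c1 <- conv1dFwd(p$conv1, A0, stride = 8); r1 <- reluFwd(c1$Y)
  c2 <- conv1dFwd(p$conv2, r1$Y, stride = 4); r2 <- reluFwd(c2$Y)
  Zm <- matrix(r2$Y, n, dm$M2 * dm$C)
  f <- denseFwd(p$fc, Zm); rf <- reluFwd(f$Y)
  pr <- denseFwd(p$proj, rf$Y)
  nn <- l2normFwd(pr$Y)
  list(E = nn$Y, cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                              r2 = r2$cache, f = f$cache, rf = rf$cache,
                              pr = pr$cache, norm = nn$cache, n = n,
                              dm = dm))
}

irBwd <- function(p, cache, dE) {
  dm <- cache$dm; n <- cache$n
  dH <- l2normBwd(cache$norm, dE)
  pr <- denseBwd(p$proj, cache$pr, dH)
  dH <- reluBwd(cache$rf, pr$dX)
  f <- denseBwd(p$fc, cache$f, dH)
  dZ <- array(f$dX, c(n, dm$M2, dm$C))
  dZ <- reluBwd(cache$r2, dZ)
  c2 <- conv1dBwd(p$conv2, cache$c2, dZ)
  dZ <- reluBwd(cache$r1, c2$dX)
  c1 <- conv1dBwd(p$conv1, cache$c1, dZ)
  list(conv1 = c1$grads, conv2 = c2$grads, fc = f$grads, proj = pr$grads)
}

hsqcFwd <- function(p, X, pool) {
  C <- ncol(p$conv2$W)
  dm <- list(C = C, G2 = as.integer(round(sqrt(nrow(p$fc$W) / C))))
  n <- dim(X)[1]
  A0 <- array(X, c(dim(X), 1))
  pl <- avgPool2dFwd(A0, pool)
  c1 <- conv2dFwd(p$conv1, pl$Y, stride = 2, K = 3); r1 <- reluFwd(c1$Y)
  c2 <- conv2dFwd(p$conv2, r1$Y, stride = 2, K = 3); r2 <- reluFwd(c2$Y)
  cr <- conv2dFwd(p$res, r2$Y, stride = 1, pad = 1, K = 3)
  rr <- reluFwd(cr$Y)
  R <- rr$Y + r2$Y
  Rs <- array(R, c(n, dm$G2 * dm$G2, dm$C))
  at <- attnFwd(p$attn, Rs)
  Z <- at$Y + Rs
  Zm <- matrix(Z, n, dm$G2 * dm$G2 * dm$C)
  f <- denseFwd(p$fc, Zm); rf <- reluFwd(f$Y)
  pr <- denseFwd(p$proj, rf$Y)
  nn <- l2normFwd(pr$Y)
  list(E = nn$Y,
       cache = list(pl = pl$cache, c1 = c1$cache, r1 = r1$cache,
                    c2 = c2$cache, r2 = r2$cache, cr = cr$cache,
                    rr = rr$cache, at = at$cache, f = f$cache,
                    rf = rf$cache, pr = pr$cache, norm = nn$cache,
                    n = n, dm = dm))
}

hsqcBwd <- function(p, cache, dE) {
  dm <- cache$dm; n <- cache$n
  dH <- l2normBwd(cache$norm, dE)
  pr <- denseBwd(p$proj, cache$pr, dH)
  dH <- reluBwd(cache$rf, pr$dX)
  f <- denseBwd(p$fc, cache$f, dH)
  dZ <- array(f$dX, c(n, dm$G2 * dm$G2, dm$C))
  at <- attnBwd(p$attn, cache$at, dZ)
  dR <- array(at$dX + dZ, c(n, dm$G2, dm$G2, dm$C))
  dRr <- reluBwd(cache$rr, dR)
  cr <- conv2dBwd(p$res, cache$cr, dRr)
  dR2 <- reluBwd(cache$r2, cr$dX + dR)
  c2 <- conv2dBwd(p$conv2, cache$c2, dR2)
  dR1 <- reluBwd(cache$r1, c2$dX)
  c1 <- conv2dBwd(p$conv1, cache$c1, dR1)
  avgPool2dBwd(cache$pl, c1$dX)   # input gradient unused; kept for checks
  list(conv1 = c1$grads, conv2 = c2$grads, res = cr$grads,
       attn = at$grads, fc = f$grads, proj = pr$grads)
}

## molecule transformer: ids is an n x L integer matrix (0 = padding)
molFwd <- function(p, ids, nLayers) {
  n <- nrow(ids); L <- ncol(ids); D <- ncol(p$emb)
  mask <- ids > 0
  idsSafe <- pmax(ids, 1)
  H <- array(0, c(n, L, D))
  for (s in seq_len(n))
    H[s, , ] <- p$emb[idsSafe[s, ], , drop = FALSE] +
                p$pos[seq_len(L), , drop = FALSE]
  caches <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    lp <- p$layers[[l]]
    n1 <- lnFwd(lp$ln1, H)
    at <- attnFwd(lp$attn, n1$Y, mask = mask)
    H1 <- H + at$Y
    n2 <- lnFwd(lp$ln2, H1)
    d <- dim(n2$Y)
    Zm <- matrix(n2$Y, d[1] * d[2], d[3])
    f1 <- denseFwd(lp$ff1, Zm); r1 <- reluFwd(f1$Y)
    f2 <- denseFwd(lp$ff2, r1$Y)
    H2 <- H1 + array(f2$Y, d)
    caches[[l]] <- list(n1 = n1$cache, at = at$cache, n2 = n2$cache,
                        f1 = f1$cache, r1 = r1$cache, f2 = f2$cache, d = d)
    H <- H2
  }
  # masked mean pooling
  cnt <- rowSums(mask)
  P <- matrix(0, n, D)
  for (s in seq_len(n))
    P[s, ] <- colSums(matrix(H[s, mask[s, ], ], sum(mask[s, ]), D)) / cnt[s]
  pr <- denseFwd(p$proj, P)
  nn <- l2normFwd(pr$Y)
  list(E = nn$Y, cache = list(layers = caches, mask = mask, cnt = cnt,
                              ids = idsSafe, pr = pr$cache, norm = nn$cache,
                              n = n, L = L, D = D))
}

molBwd <- function(p, cache, dE, nLayers) {
  n <- cache$n; L <- cache$L; D <- cache$D
  mask <- cache$mask
  dH <- l2normBwd(cache$norm, dE)
  pr <- denseBwd(p$proj, cache$pr, dH)
  dP <- pr$dX
  dHarr <- array(0, c(n, L, D))
  for (s in seq_len(n))
    dHarr[s, mask[s, ], ] <- matrix(dP[s, ] / cache$cnt[s],
                                    sum(mask[s, ]), D, byrow = TRUE)
  g <- list(emb = p$emb * 0, pos = p$pos * 0,
            layers = vector("list", nLayers), proj = pr$grads)
  for (l in rev(seq_len(nLayers))) {
    lp <- p$layers[[l]]; cc <- cache$layers[[l]]
    # FFN branch
    dH2 <- dHarr
    dZm <- matrix(dH2, cc$d[1] * cc$d[2], cc$d[3])
    f2 <- denseBwd(lp$ff2, cc$f2, dZm)
    dR <- reluBwd(cc$r1, f2$dX)
    f1 <- denseBwd(lp$ff1, cc$f1, dR)
    n2 <- lnBwd(lp$ln2, cc$n2, array(f1$dX, cc$d))
    dH1 <- dH2 + n2$dX
    # attention branch
    at <- attnBwd(lp$attn, cc$at, dH1)
    n1 <- lnBwd(lp$ln1, cc$n1, at$dX)
    dHarr <- dH1 + n1$dX
    g$layers[[l]] <- list(ln1 = n1$grads, attn = at$grads, ln2 = n2$grads,
                          ff1 = f1$grads, ff2 = f2$grads)
  }
  for (s in seq_len(n)) {
    idx <- cache$ids[s, ]
    for (t in seq_len(L)) {
      g$emb[idx[t], ] <- g$emb[idx[t], ] + dHarr[s, t, ]
      g$pos[t, ] <- g$pos[t, ] + dHarr[s, t, ]
    }
  }
  g
}

## ---- model object and public encode API ---------------------------------

#' Build an untrained alignment model
#'
#' Initializes all modality encoders and the molecule transformer with the
#' configured seed. The SMILES vocabulary is built from the supplied corpus.
#'
#' @param config an [encoderConfig].
#' @param smiles character vector of training SMILES (vocabulary source).
#' @return list of class `specmolModel` with elements `config`, `vocab`,
#'   `params`, `version`.
#' @export
buildModel <- function(config = encoderConfig(), smiles) {
  vocab <- buildVocab(smiles)
  structure(list(config = config, vocab = vocab,
                 params = initEncoders(config, vocab),
                 version = "SpectraMol-0.1"),
            class = "specmolModel")
}

smilesToIds <- function(smilesVec, vocab, maxTokens) {
  tl <- lapply(smilesVec, function(s)
    tokensToIds(tokenizeSmiles(s), vocab))
  L <- min(max(vapply(tl, length, 0L)), maxTokens)
  ids <- matrix(0L, length(tl), L)
  for (i in seq_along(tl)) {
    t <- head(tl[[i]], L)
    ids[i, seq_along(t)] <- t
  }
  ids
}

## batched encode: X is a matrix (1D modalities), 3D array (hsqc) or
## character vector of SMILES; returns n x d matrix of unit rows
encodeMatrix <- function(model, modality, X) {
  p <- model$params[[modality]]
  out <- switch(modality,
    c13 = c13Fwd(p, X),
    h1 = h1Fwd(p, X),
    ir = irFwd(p, X),
    hsqc = hsqcFwd(p, X, model$config$hsqcPool),
    molecule = molFwd(p, smilesToIds(X, model$vocab, model$config$maxTokens),
                      model$config$molLayers),
    stop("no encoder configured for modality: ", modality))
  out$E
}

#' Encode a spectrum or molecule into the shared embedding space
#'
#' @param model a trained (or freshly built) `specmolModel`.
#' @param x a [SpectrumVector], a [SpectrumSet] (returns one embedding per
#'   modality), or a SMILES string.
#' @return an [EmbeddingVector], or a named list of them for a
#'   [SpectrumSet].
#' @export
encode <- function(model, x) {
  if (is(x, "SpectrumSet")) {
    out <- lapply(x@spectra, function(sv) encode(model, sv))
    return(out)
  }
  if (is(x, "SpectrumVector")) {
    v <- x@values
    X <- if (x@modality == "hsqc") array(v, c(1, dim(v))) else
      matrix(v, 1, length(v))
    expect <- switch(x@modality, c13 = model$config$codec$c13Len,
                     h1 = model$config$codec$h1Len,
                     ir = model$config$codec$irLen,
                     hsqc = model$config$codec$hsqcDim)
    got <- if (x@modality == "hsqc") dim(v)[1] else length(v)
    if (got != expect)
      stop(sprintf("%s vector length %d does not match configured %d",
                   x@modality, got, expect))
    E <- encodeMatrix(model, x@modality, X)
    return(new("EmbeddingVector", values = as.numeric(E[1, ]),
               modality = x@modality))
  }
  if (is.character(x) && length(x) == 1) {
    E <- encodeMatrix(model, "molecule", x)
    return(new("EmbeddingVector", values = as.numeric(E[1, ]),
               modality = "molecule"))
  }
  stop("encode() accepts a SpectrumVector, SpectrumSet or SMILES string")
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration and vocabulary and is
#' version-stamped.
#'
#' @param model a `specmolModel`.
#' @param path file path.
#' @return `loadModel` returns the model; `saveModel` the path, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!identical(model$version, "SpectraMol-0.1"))
    warning("checkpoint version ", model$version,
            " differs from this package build")
  model
}
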