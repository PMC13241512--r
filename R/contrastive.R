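## Symmetric InfoNCE alignment training. Each spectral modality is aligned
## against the molecule embedding (hub design); the per-batch total loss is
## the sum over available modalities of the symmetric loss.

#' Contrastive training configuration
#'
#' @param tau softmax temperature of the InfoNCE loss (default 0.07).
#' @param lr Adam learning rate (default 1e-4).
#' @param batchSize minibatch size (default 64).
#' @param maxEpochs upper bound on training epochs.
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 3).
#' @param valFraction fraction of molecules held out for validation
#'   monitoring (default 0.1).
#' @param seed integer seed controlling the split, shuffling and any
#'   augmentation stream.
#' @return list of class `contrastiveConfig`.
#' @export
contrastiveConfig <- function(tau = 0.07, lr = 1e-4, batchSize = 32L,
                              maxEpochs = 50L, patience = 3L,
                              valFraction = 0.1, seed = 1L) {
  stopifnot(tau > 0, patience >= 1)
  structure(list(tau = tau, lr = lr, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), valFraction = valFraction,
                 seed = as.integer(seed)),
            class = "contrastiveConfig")
}

asEmbMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, function(e)
    if (is(e, "EmbeddingVector")) e@values else as.numeric(e))))
  stop("expected a matrix of embeddings or a list of EmbeddingVector")
}

## row-wise log-sum-exp
logSumExpRows <- function(S) {
  mx <- apply(S, 1, max)
  mx + log(rowSums(exp(S - mx)))
}

#' InfoNCE contrastive loss
#'
#' Mean over the batch of the softmax cross-entropy that scores each query
#' against its paired key among all keys:
#' `-log[ exp(q_i . k_i / tau) / sum_j exp(q_i . k_j / tau) ]`.
#' Row i of `queries` pairs with row i of `keys`.
#'
#' @param queries,keys numeric matrices (batch x d) or lists of
#'   [EmbeddingVector]; equal batch sizes >= 1.
#' @param tau temperature, > 0.
#' @param grad if TRUE, also return gradients with respect to queries and
#'   keys.
#' @return the scalar loss, or (with `grad`) a list `loss`, `dQ`, `dK`.
#' @export
infoNCE <- function(queries, keys, tau = 0.07, grad = FALSE) {
  Q <- asEmbMatrix(queries); K <- asEmbMatrix(keys)
  B <- nrow(Q)
  if (B < 1) stop("empty batch")
  if (nrow(K) != B) stop("queries and keys must have equal batch sizes")
  S <- tcrossprod(Q, K) / tau
  lse <- logSumExpRows(S)
  loss <- mean(lse - diag(S))
  if (!grad) return(loss)
  P <- exp(S - lse)                     # softmax rows
  dS <- (P - diag(B)) / B
  list(loss = loss, dQ = (dS %*% K) / tau, dK = crossprod(dS, Q) / tau)
}

#' Symmetric contrastive loss
#'
#' Sum of the two directed InfoNCE losses, spectra-to-molecules plus
#' molecules-to-spectra, on one paired batch.
#'
#' @param spectra,molecules paired embedding batches (matrix or list).
#' @param tau temperature.
#' @param grad if TRUE also return gradients `dS` (spectra) and `dM`.
#' @return scalar loss, or a list with gradients.
#' @export
symmetricLoss <- function(spectra, molecules, tau = 0.07, grad = FALSE) {
  S <- asEmbMatrix(spectra); M <- asEmbMatrix(molecules)
  a <- infoNCE(S, M, tau, grad = grad)
  b <- infoNCE(M, S, tau, grad = grad)
  if (!grad) return(a + b)
  list(loss = a$loss + b$loss,
       dS = a$dQ + b$dK,
       dM = a$dK + b$dQ)
}

#' Assemble model-ready training pairs from a corpus
#'
#' Simulates the requested modalities for every corpus molecule and stacks
#' them into the matrices the encoders consume.
#'
#' @param corpus data.frame from [generateCorpus].
#' @param modalities modalities to simulate.
#' @param seed seed for the augmentation streams.
#' @param augment logical or [augmentConfig], passed to [simulateSpectra].
#' @param config a [codecConfig].
#' @param valFraction fraction of molecules for which an independently
#'   augmented replicate spectrum set is generated as the convergence-
#'   monitoring validation set (0 disables it).
#' @return list with `smiles`, a named list `X` of input matrices (3D
#'   array for hsqc), and optionally `val` (fields `idx` and `X`): the
#'   replicate-spectrum validation pairs.
#' @export
prepareTrainingData <- function(corpus, modalities = c("c13", "h1"),
                                seed = 1L, augment = FALSE,
                                config = codecConfig(),
                                valFraction = 0.1) {
  simBlock <- function(rows, tag, aug) {
    store <- setNames(vector("list", length(modalities)), modalities)
    for (k in seq_along(rows)) {
      i <- rows[k]
      ss <- simulateSpectra(corpus$smiles[i], modalities,
                            seed = fanSeed(seed, tag, corpus$id[i]),
                            augment = aug, config = config)
      for (m in modalities) {
        v <- ss[[m]]@values
        if (m == "hsqc") {
          if (is.null(store[[m]]))
            store[[m]] <- array(0, c(length(rows), dim(v)))
          store[[m]][k, , ] <- v
        } else {
          if (is.null(store[[m]]))
            store[[m]] <- matrix(0, length(rows), length(v))
          store[[m]][k, ] <- v
        }
      }
    }
    store
  }
  n <- nrow(corpus)
  out <- list(smiles = corpus$smiles,
              X = simBlock(seq_len(n), "sim", augment))
  if (valFraction > 0 && n >= 2) {
    nVal <- max(2L, round(valFraction * n))
    idx <- withSeed(fanSeed(seed, "valsplit"), sample(n, nVal))
    out$val <- list(idx = idx, X = simBlock(idx, "val", TRUE))
  }
  out
}

sliceInput <- function(X, idx) {
  if (length(dim(X)) == 3) X[idx, , , drop = FALSE]
  else X[idx, , drop = FALSE]
}

## forward + loss + full backward/update for one batch; returns new
## params/state and the batch loss
trainStep <- function(model, data, idx, conCfg, adam) {
  mods <- names(data$X)
  p <- model$params
  ids <- smilesToIds(data$smiles[idx], model$vocab, model$config$maxTokens)
  mf <- molFwd(p$molecule, ids, model$config$molLayers)
  dEm <- mf$E * 0
  total <- 0
  grads <- list()
  for (m in mods) {
    Xb <- sliceInput(data$X[[m]], idx)
    fw <- switch(m, c13 = c13Fwd(p[[m]], Xb), h1 = h1Fwd(p[[m]], Xb),
                 ir = irFwd(p[[m]], Xb),
                 hsqc = hsqcFwd(p[[m]], Xb, model$config$hsqcPool))
    sl <- symmetricLoss(fw$E, mf$E, conCfg$tau, grad = TRUE)
    total <- total + sl$loss
    dEm <- dEm + sl$dM
    grads[[m]] <- switch(m, c13 = c13Bwd(p[[m]], fw$cache, sl$dS),
                         h1 = h1Bwd(p[[m]], fw$cache, sl$dS),
                         ir = irBwd(p[[m]], fw$cache, sl$dS),
                         hsqc = hsqcBwd(p[[m]], fw$cache, sl$dS))
  }
  grads$molecule <- molBwd(p$molecule, mf$cache, dEm, model$config$molLayers)
  active <- c(mods, "molecule")
  upd <- adamStep(p[active], grads[active], adam, lr = conCfg$lr)
  model$params[active] <- upd$params
  list(model = model, adam = upd$state, loss = total)
}

## forward-only total symmetric loss; `Xlist` defaults to the training
## spectra of the indexed molecules but can be a replicate block
evalLoss <- function(model, data, idx, conCfg, Xlist = NULL) {
  mods <- names(data$X)
  Em <- encodeMatrix(model, "molecule", data$smiles[idx])
  total <- 0
  for (m in mods) {
    Xb <- if (is.null(Xlist)) sliceInput(data$X[[m]], idx)
          else Xlist[[m]]
    Es <- encodeMatrix(model, m, Xb)
    total <- total + symmetricLoss(Es, Em, conCfg$tau)
  }
  total
}

#' Contrastively train the alignment model
#'
#' Runs symmetric InfoNCE training of all modality encoders against the
#' molecule encoder on simulated (or supplied) pairs. Convergence is
#' monitored on a validation set: by preference the independently
#' augmented replicate spectra provided by [prepareTrainingData] (all
#' molecules keep contributing gradient steps), otherwise a held-out 10%
#' molecule split. Training stops when the validation loss has not
#' improved for `patience` epochs (early stopping) and the
#' best-validation checkpoint is returned. Reproducible given the seeds
#' in the configs.
#'
#' @param data training pairs from [prepareTrainingData] (fields `smiles`
#'   and `X`).
#' @param encCfg an [encoderConfig].
#' @param conCfg a [contrastiveConfig].
#' @param verbose print per-epoch losses.
#' @return list of class `specmolFit`: `model` (best checkpoint), `history`
#'   (data.frame epoch/train/val), `bestEpoch`.
#' @export
trainModel <- function(data, encCfg = encoderConfig(),
                       conCfg = contrastiveConfig(), verbose = FALSE) {
  n <- length(data$smiles)
  if (n < 2) stop("training needs at least 2 molecules")
  model <- buildModel(encCfg, data$smiles)
  withSeed(conCfg$seed, {
    if (!is.null(data$val)) {
      val <- data$val$idx
      valX <- data$val$X
      tr <- seq_len(n)
    } else {
      nVal <- max(1L, round(conCfg$valFraction * n))
      val <- sample(n, nVal)
      valX <- NULL
      tr <- setdiff(seq_len(n), val)
    }
    if (length(tr) < 2)
      stop("too few training molecules after the validation split")
    adam <- adamInit(model$params[c(names(data$X), "molecule")])
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       val = numeric(0))
    bad <- 0L
    for (epoch in seq_len(conCfg$maxEpochs)) {
      ord <- sample(tr)
      bl <- numeric(0)
      for (s in seq(1, length(ord), by = conCfg$batchSize)) {
        idx <- ord[s:min(s + conCfg$batchSize - 1, length(ord))]
        if (length(idx) < 2) {
          logMsg("skipping degenerate batch of 1 (no negatives)")
          next
        }
        st <- trainStep(model, data, idx, conCfg, adam)
        model <- st$model; adam <- st$adam
        bl <- c(bl, st$loss)
      }
      vl <- evalLoss(model, data, val, conCfg, Xlist = valX)
      hist <- rbind(hist, data.frame(epoch = epoch, train = mean(bl),
                                     val = vl))
      if (verbose)
        logMsg("epoch %d: train %.4f val %.4f", epoch, mean(bl), vl)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= conCfg$patience) break
      }
    }
    model$params <- best$params
    structure(list(model = model, history = hist, bestEpoch = best$epoch),
              class = "specmolFit")
  })
}
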