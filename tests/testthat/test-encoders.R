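## Encoder contracts: tokenization, determinism, unit norm, shape checks,
## and gradient flow (numerical gradient checking on a reduced
## configuration).

tinyConfig <- function(seed = 3) {
  encoderConfig(d = 8, c13Hidden = c(16, 12), convChannels = c(2, 3, 4),
                fcHidden = 10, molDim = 8, molLayers = 2, molFF = 12,
                hsqcPool = 2, maxTokens = 32,
                codec = codecConfig(c13Len = 20, h1Len = 1000, irLen = 120,
                                    hsqcDim = 32),
                seed = seed)
}

test_that("SMILES tokenization is reversible and handles multi-char tokens", {
  expect_equal(tokenizeSmiles("CCO"), c("C", "C", "O"))
  tok <- tokenizeSmiles("c1ccccc1")
  expect_length(tok, 8L)
  expect_true(all(c("c", "1") %in% tok))
  expect_equal(tokenizeSmiles("CCl"), c("C", "Cl"))
  expect_equal(tokenizeSmiles("[nH]1cccc1")[1], "[nH]")
  corp <- generateCorpus(25, seed = 19)
  for (s in corp$smiles)
    expect_equal(detokenizeSmiles(tokenizeSmiles(s)), s)
})

test_that("embeddings are deterministic, unit-norm and dimension d", {
  smiles <- c("CCO", "CCN", "c1ccccc1", "CC(=O)O")
  model <- buildModel(tinyConfig(), smiles)
  cfg <- model$config$codec
  sv <- binC13(c(10, 150), codecConfig(c13Len = 20))
  e1 <- encode(model, sv)
  e2 <- encode(model, sv)
  expect_equal(embeddingValues(e1), embeddingValues(e2))
  expect_length(embeddingValues(e1), 8L)
  expect_equal(sqrt(sum(embeddingValues(e1)^2)), 1, tolerance = 1e-9)
  em <- encode(model, "CCO")
  expect_equal(modality(em), "molecule")
  expect_equal(sqrt(sum(embeddingValues(em)^2)), 1, tolerance = 1e-9)
  # untrained encoders still separate different molecules
  e3 <- encode(model, "c1ccccc1")
  expect_gt(sum(abs(embeddingValues(em) - embeddingValues(e3))), 1e-4)
})

test_that("shape mismatches are rejected", {
  model <- buildModel(tinyConfig(), c("CCO", "CCC"))
  wrong <- SpectrumVector("c13", rep(0, 512), 0, 300)
  expect_error(encode(model, wrong), "does not match")
})

test_that("all modality encoders produce unit-norm batches", {
  model <- buildModel(tinyConfig(), c("CCO", "CCC"))
  set.seed(1)
  checks <- list(
    c13 = matrix(rbinom(3 * 20, 1, 0.3), 3, 20),
    h1 = matrix(runif(3 * 1000), 3, 1000),
    ir = matrix(runif(3 * 120), 3, 120),
    hsqc = array(runif(3 * 32 * 32), c(3, 32, 32)))
  for (m in names(checks)) {
    E <- SpectraMol:::encodeMatrix(model, m, checks[[m]])
    expect_equal(dim(E), c(3L, 8L))
    expect_equal(rowSums(E^2), rep(1, 3), tolerance = 1e-9, info = m)
  }
})

test_that("analytic gradients match numerical derivatives for every encoder", {
  model <- buildModel(tinyConfig(), c("CCO", "CC(=O)O", "c1ccccc1", "CCN"))
  tau <- 0.07
  set.seed(11)
  B <- 3
  Em <- matrix(rnorm(B * 8), B, 8)
  Em <- Em / sqrt(rowSums(Em^2))
  fwd <- function(p, mod, X) switch(mod,
    c13 = c13Fwd2(p, X), h1 = SpectraMol:::h1Fwd(p, X),
    ir = SpectraMol:::irFwd(p, X),
    hsqc = SpectraMol:::hsqcFwd(p, X, 2))
  c13Fwd2 <- SpectraMol:::c13Fwd
  inputs <- list(c13 = matrix(rbinom(B * 20, 1, 0.4), B, 20),
                 h1 = matrix(runif(B * 1000), B, 1000),
                 ir = matrix(runif(B * 120), B, 120),
                 hsqc = array(runif(B * 32 * 32), c(B, 32, 32)))
  bwd <- list(c13 = SpectraMol:::c13Bwd, h1 = SpectraMol:::h1Bwd,
              ir = SpectraMol:::irBwd, hsqc = SpectraMol:::hsqcBwd)
  for (mod in names(inputs)) {
    p <- model$params[[mod]]
    X <- inputs[[mod]]
    fw <- fwd(p, mod, X)
    sl <- symmetricLoss(fw$E, Em, tau, grad = TRUE)
    g <- bwd[[mod]](p, fw$cache, sl$dS)
    gv <- SpectraMol:::paramFlatten(g)
    pv <- SpectraMol:::paramFlatten(p)
    # every parameter block receives gradient signal
    for (nm in names(g))
      expect_gt(sum(abs(SpectraMol:::paramFlatten(g[[nm]]))), 0,
                label = paste(mod, nm))
    set.seed(99)
    pick <- sample(length(pv), 12)
    num <- vapply(pick, function(i) {
      e <- 1e-5
      pp <- pv; pp[i] <- pv[i] + e
      l1 <- symmetricLoss(fwd(SpectraMol:::paramUnflatten(p, pp), mod, X)$E,
                          Em, tau)
      pp[i] <- pv[i] - e
      l0 <- symmetricLoss(fwd(SpectraMol:::paramUnflatten(p, pp), mod, X)$E,
                          Em, tau)
      (l1 - l0) / (2 * e)
    }, numeric(1))
    relerr <- abs(num - gv[pick]) / (abs(num) + abs(gv[pick]) + 1e-8)
    # central differences at step 1e-5 carry O(1e-4) cancellation noise
    expect_lt(max(relerr), 1e-3)
  }
})

test_that("molecule transformer gradients flow to embeddings and all layers", {
  smiles <- c("CCO", "CC(=O)O", "c1ccccc1", "CCN")
  model <- buildModel(tinyConfig(), smiles)
  p <- model$params$molecule
  ids <- SpectraMol:::smilesToIds(smiles, model$vocab, 32)
  Em <- matrix(rnorm(4 * 8), 4, 8)
  Em <- Em / sqrt(rowSums(Em^2))
  mf <- SpectraMol:::molFwd(p, ids, 2)
  sl <- symmetricLoss(Em, mf$E, 0.07, grad = TRUE)
  g <- SpectraMol:::molBwd(p, mf$cache, sl$dM, 2)
  expect_gt(sum(abs(g$emb)), 0)
  expect_gt(sum(abs(g$pos)), 0)
  for (l in 1:2)
    expect_gt(sum(abs(SpectraMol:::paramFlatten(g$layers[[l]]))), 0)
  gv <- SpectraMol:::paramFlatten(g)
  pv <- SpectraMol:::paramFlatten(p)
  set.seed(5)
  pick <- sample(length(pv), 15)
  num <- vapply(pick, function(i) {
    e <- 1e-5
    pp <- pv; pp[i] <- pv[i] + e
    l1 <- symmetricLoss(Em, SpectraMol:::molFwd(
      SpectraMol:::paramUnflatten(p, pp), ids, 2)$E, 0.07)
    pp[i] <- pv[i] - e
    l0 <- symmetricLoss(Em, SpectraMol:::molFwd(
      SpectraMol:::paramUnflatten(p, pp), ids, 2)$E, 0.07)
    (l1 - l0) / (2 * e)
  }, numeric(1))
  relerr <- abs(num - gv[pick]) / (abs(num) + abs(gv[pick]) + 1e-8)
  expect_lt(max(relerr), 1e-4)
})

test_that("checkpoints round-trip with config and vocabulary", {
  model <- buildModel(tinyConfig(), c("CCO", "CCC"))
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  back <- loadModel(f)
  expect_identical(back$vocab, model$vocab)
  expect_identical(back$config$d, model$config$d)
  sv <- binC13(42, codecConfig(c13Len = 20))
  expect_equal(embeddingValues(encode(model, sv)),
               embeddingValues(encode(back, sv)))
})
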