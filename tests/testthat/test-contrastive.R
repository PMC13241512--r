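## InfoNCE and symmetric loss against brute-force oracles; training-loop
## contracts (early stopping, determinism, learnability smoke test).

## naive double-loop InfoNCE oracle
bruteInfoNCE <- function(Q, K, tau) {
  B <- nrow(Q)
  mean(vapply(seq_len(B), function(i) {
    num <- exp(sum(Q[i, ] * K[i, ]) / tau)
    den <- sum(vapply(seq_len(B), function(j)
      exp(sum(Q[i, ] * K[j, ]) / tau), numeric(1)))
    -log(num / den)
  }, numeric(1)))
}

test_that("infoNCE matches the brute-force softmax cross-entropy", {
  set.seed(21)
  for (B in c(4, 8)) {
    Q <- matrix(rnorm(B * 8), B, 8)
    K <- matrix(rnorm(B * 8), B, 8)
    expect_equal(infoNCE(Q, K, 0.07), bruteInfoNCE(Q, K, 0.07),
                 tolerance = 1e-6)
    expect_equal(infoNCE(Q, K, 0.5), bruteInfoNCE(Q, K, 0.5),
                 tolerance = 1e-6)
  }
})

test_that("infoNCE limit cases: single pair, uniform similarities", {
  q <- matrix(rnorm(8), 1, 8)
  expect_equal(infoNCE(q, q, 0.07), 0)
  # all pairwise dot products equal -> softmax is uniform -> loss = log B
  B <- 6
  Q <- matrix(0, B, 4)
  K <- matrix(rnorm(4), B, 4, byrow = TRUE)
  expect_equal(infoNCE(Q, K, 0.07), log(B), tolerance = 1e-9)
  expect_error(infoNCE(matrix(numeric(0), 0, 4), matrix(numeric(0), 0, 4)),
               "batch")
})

test_that("infoNCE is non-negative and vanishes as positives dominate", {
  set.seed(3)
  for (k in 1:20) {
    Q <- matrix(rnorm(40), 5, 8)
    K <- matrix(rnorm(40), 5, 8)
    expect_gte(infoNCE(Q, K, 0.07), 0)
  }
  # scaling up the aligned pair similarity drives the loss to zero
  E <- diag(5) %*% matrix(rnorm(40), 5, 8)
  E <- E / sqrt(rowSums(E^2))
  l1 <- infoNCE(E, E, 0.07)
  l2 <- infoNCE(5 * E, 5 * E, 0.07)
  expect_lt(l2, l1)
  expect_lt(infoNCE(50 * E, 50 * E, 0.07), 1e-6)
})

test_that("loss is invariant under a common permutation of both batches", {
  set.seed(9)
  Q <- matrix(rnorm(48), 6, 8); K <- matrix(rnorm(48), 6, 8)
  p <- sample(6)
  expect_equal(infoNCE(Q, K, 0.07), infoNCE(Q[p, ], K[p, ], 0.07),
               tolerance = 1e-12)
  expect_equal(symmetricLoss(Q, K, 0.07), symmetricLoss(Q[p, ], K[p, ], 0.07),
               tolerance = 1e-12)
})

test_that("symmetric loss is the sum of the two directed losses", {
  set.seed(33)
  S <- matrix(rnorm(40), 5, 8); M <- matrix(rnorm(40), 5, 8)
  expect_equal(symmetricLoss(S, M, 0.07),
               infoNCE(S, M, 0.07) + infoNCE(M, S, 0.07), tolerance = 1e-12)
  expect_equal(symmetricLoss(S, M, 0.07),
               bruteInfoNCE(S, M, 0.07) + bruteInfoNCE(M, S, 0.07),
               tolerance = 1e-6)
  # symmetric similarity matrix -> the two directions agree
  A <- matrix(rnorm(40), 5, 8)
  expect_equal(infoNCE(A, A, 0.07), infoNCE(A, A, 0.07))
})

test_that("symmetricLoss gradients match numerical derivatives", {
  set.seed(4)
  S <- matrix(rnorm(32), 4, 8); M <- matrix(rnorm(32), 4, 8)
  g <- symmetricLoss(S, M, 0.07, grad = TRUE)
  e <- 1e-6
  for (k in 1:10) {
    i <- sample(4, 1); j <- sample(8, 1)
    Sp <- S; Sp[i, j] <- S[i, j] + e
    Sm <- S; Sm[i, j] <- S[i, j] - e
    num <- (symmetricLoss(Sp, M, 0.07) - symmetricLoss(Sm, M, 0.07)) / (2 * e)
    expect_equal(g$dS[i, j], num, tolerance = 1e-4)
  }
})

test_that("training configuration validates its invariants", {
  expect_error(contrastiveConfig(tau = 0), "tau")
  expect_error(contrastiveConfig(patience = 0), "patience")
  expect_error(trainModel(list(smiles = "CCO",
                               X = list(c13 = matrix(0, 1, 20)))),
               "at least 2")
})

test_that("toy training reduces the loss and is seed-reproducible", {
  corp <- generateCorpus(24, seed = 31)
  cfg <- codecConfig(c13Len = 64, h1Len = 500)
  data <- prepareTrainingData(corp, "c13", seed = 31, config = cfg)
  encCfg <- encoderConfig(d = 16, c13Hidden = c(32, 16), fcHidden = 16,
                          molDim = 16, molLayers = 1, molFF = 24,
                          codec = cfg, seed = 2)
  conCfg <- contrastiveConfig(batchSize = 8, maxEpochs = 12, patience = 12,
                              seed = 5, lr = 1e-3)
  fit <- trainModel(data, encCfg, conCfg)
  h <- fit$history
  expect_lt(h$train[nrow(h)], h$train[1])
  fit2 <- trainModel(data, encCfg, conCfg)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
})

test_that("early stopping halts after `patience` non-improving epochs", {
  corp <- generateCorpus(12, seed = 8)
  cfg <- codecConfig(c13Len = 32, h1Len = 500)
  data <- prepareTrainingData(corp, "c13", seed = 8, config = cfg)
  encCfg <- encoderConfig(d = 8, c13Hidden = c(8), fcHidden = 8,
                          molDim = 8, molLayers = 1, molFF = 8,
                          codec = cfg, seed = 2)
  # zero learning rate: the validation loss can never improve after the
  # first epoch, so training must stop at epoch 1 + patience
  conCfg <- contrastiveConfig(batchSize = 6, maxEpochs = 50, patience = 3,
                              seed = 5, lr = 0)
  fit <- trainModel(data, encCfg, conCfg)
  expect_equal(nrow(fit$history), 1L + 3L)
  expect_equal(fit$bestEpoch, 1L)
})
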