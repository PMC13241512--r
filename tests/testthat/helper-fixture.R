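## Shared trained fixture for the study-scale tests: a 300-molecule
## synthetic corpus with c13 + h1 spectra and contrastively trained d = 64
## encoders. Built once per test run and cached; the heavy tests reuse it.
## Spectrum embeddings of all training pairs are precomputed in one batch
## per modality.

FIXTURE_SEED <- 2026L

acceptanceFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seed <- FIXTURE_SEED
      corpus <- generateCorpus(300, seed = fanSeed(seed, "corpus"))
      # realism augmentations are always included in the training spectra
      data <- prepareTrainingData(corpus, c("c13", "h1"),
                                  seed = fanSeed(seed, "spectra"),
                                  augment = TRUE)
      fit <- trainModel(data,
                        encoderConfig(seed = fanSeed(seed, "enc")),
                        contrastiveConfig(seed = fanSeed(seed, "train")))
      model <- fit$model
      index <- buildIndex(corpus, model)
      emb <- lapply(setNames(names(data$X), names(data$X)), function(m)
        SpectraMol:::encodeMatrix(model, m, data$X[[m]]))
      cache <<- list(seed = seed, corpus = corpus, data = data,
                     fit = fit, model = model, index = index, emb = emb)
    }
    cache
  }
})

## per-query embedding list for one corpus row, from the cached batch
fixtureEmbedding <- function(fx, r, mods = c("c13", "h1")) {
  lapply(setNames(mods, mods), function(m) fx$emb[[m]][r, ])
}

## retrieval results for every training molecule under a modality subset
selfRetrieval <- function(fx, mods) {
  lapply(seq_len(nrow(fx$corpus)), function(i)
    rankCandidates(fx$index, fixtureEmbedding(fx, i, mods),
                   truth = fx$corpus$smiles[i]))
}
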