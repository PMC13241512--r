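## End-to-end orchestration: retrieve -> refine (GA) -> aggregate -> report,
## plus the benchmark loop used for rank metrics and calibration. Every
## stochastic stage consumes an explicit seed fanned out from one global
## seed, so reruns with the same configuration reproduce the rankings.

#' Elucidate a structure from spectra
#'
#' The retrieve-then-refine pipeline for one query: restrict the index to
#' the query's molecular formula (falling back to the full index if the
#' pool is empty), rank by fused cosine similarity, seed the genetic
#' algorithm with the top-ranked molecules, run it for the configured
#' seeds, and aggregate all populations with the retrieved candidates into
#' one deduplicated ranking.
#'
#' @param spectra a [SpectrumSet], or a named list of per-modality
#'   [EmbeddingVector].
#' @param formula query molecular formula (string or named counts).
#' @param index a [MoleculeIndex].
#' @param model a trained `specmolModel`.
#' @param ga a [gaConfig].
#' @param seed global seed for this query.
#' @param poolTolerance formula tolerance for [formulaPool].
#' @param initialSize number of top-ranked molecules that bootstrap the GA.
#' @param topN candidates returned (default 20).
#' @param reference optional true SMILES; adds match flags.
#' @return a [CandidateRanking].
#' @export
elucidate <- function(spectra, formula, index, model, ga = gaConfig(),
                      seed = 1L, poolTolerance = 0L, initialSize = 100L,
                      topN = 20L, reference = NULL) {
  emb <- if (is(spectra, "SpectrumSet")) encode(model, spectra) else spectra
  pool <- formulaPool(index, formula, poolTolerance)
  if (nrow(pool@molecules) == 0) {
    logMsg("formula pool is empty; falling back to the full index")
    pool <- index
  }
  ranked <- rankCandidates(pool, emb)
  initial <- head(ranked$smiles, initialSize)
  rewardFn <- function(smi, graphs = NULL)
    rewardBatch(smi, emb, formula, model, graphs)
  runs <- lapply(seq_len(ga$seeds), function(k)
    evolve(initial, rewardFn, ga, seed = fanSeed(seed, "ga", k)))
  poolRun <- data.frame(smiles = initial, R = rewardFn(initial),
                        provenance = "retrieved", stringsAsFactors = FALSE)
  ranking <- aggregateRuns(c(list(poolRun), runs), reference = reference)
  ranking@table <- head(ranking@table, topN)
  ranking
}

#' Benchmark the pipeline over a query set
#'
#' For each query molecule: simulate its spectra, run retrieval (and
#' optionally the full GA pipeline), and score the outcome against the
#' known structure. Reports top-k accuracy per modality combination and
#' the per-query best scores used for calibration.
#'
#' @param corpus data.frame of molecules (the queries are drawn from it).
#' @param model trained `specmolModel`.
#' @param index a [MoleculeIndex] to search.
#' @param queryIds ids of the corpus molecules used as queries (default:
#'   all).
#' @param modalities modalities simulated for the queries.
#' @param seed global seed.
#' @param refine run the GA stage (default FALSE: retrieval only).
#' @param ga a [gaConfig] when `refine` is TRUE.
#' @param ks ranks for the top-k table.
#' @return list with `retrieval` (per-query results), `metrics` (top-k),
#'   `scores` (per-query top fused score or reward), `correct` (top-1
#'   match flags), and `rankings` when `refine` is TRUE.
#' @export
benchmark <- function(corpus, model, index, queryIds = corpus$id,
                      modalities = c("c13", "h1"), seed = 1L,
                      refine = FALSE, ga = gaConfig(),
                      ks = c(1, 3, 5, 20)) {
  rows <- match(queryIds, corpus$id)
  retrieval <- list()
  rankings <- list()
  scores <- numeric(0)
  correct <- logical(0)
  for (r in rows) {
    id <- corpus$id[r]; truth <- corpus$smiles[r]
    ss <- simulateSpectra(truth, modalities,
                          seed = fanSeed(seed, "sim", id))
    emb <- encode(model, ss)
    pool <- formulaPool(index, corpus$formula[r])
    if (nrow(pool@molecules) == 0) pool <- index
    res <- rankCandidates(pool, emb, truth = truth)
    retrieval[[id]] <- res
    if (refine) {
      rk <- elucidate(emb, corpus$formula[r], index, model, ga = ga,
                      seed = fanSeed(seed, "query", id),
                      reference = truth)
      rankings[[id]] <- rk
      scores <- c(scores, rk@table$score[1])
      correct <- c(correct, isTRUE(rk@table$fpMatch[1]))
    } else {
      scores <- c(scores, res$score[1])
      correct <- c(correct, !is.na(attr(res, "trueRank")) &&
                             attr(res, "trueRank") == 1)
    }
  }
  out <- list(retrieval = retrieval, metrics = rankMetrics(retrieval, ks),
              scores = scores, correct = correct)
  if (refine) out$rankings <- rankings
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param outputDir directory for all artifacts.
#' @param seed global seed; every stage derives its own stream from it.
#' @param corpusSize,maxHeavyAtoms synthetic corpus parameters.
#' @param modalities modalities simulated and trained.
#' @param nQueries number of benchmark queries (capped at the corpus size).
#' @param encoder,contrastive,ga,codec stage configurations.
#' @param checkpoint optional path of a trained model to reuse.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(outputDir = "specmol_run", seed = 1L,
                      corpusSize = 300L, maxHeavyAtoms = 15L,
                      modalities = c("c13", "h1"), nQueries = 50L,
                      encoder = encoderConfig(), contrastive = contrastiveConfig(),
                      ga = gaConfig(), codec = codecConfig(),
                      checkpoint = NULL) {
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 corpusSize = as.integer(corpusSize),
                 maxHeavyAtoms = as.integer(maxHeavyAtoms),
                 modalities = modalities, nQueries = as.integer(nQueries),
                 encoder = encoder, contrastive = contrastive, ga = ga,
                 codec = codec, checkpoint = checkpoint),
            class = "runConfig")
}

#' Run the full pipeline end to end
#'
#' Generates (or loads) the corpus, trains the encoders (or loads a
#' checkpoint), builds the index, benchmarks retrieval and GA refinement
#' over the query set, fits the calibration curve, and writes all
#' artifacts (rankings CSV/JSON, metrics, calibration, config copy) into
#' the output directory.
#'
#' @param config a [runConfig].
#' @param verbose print stage progress.
#' @return list with `model`, `index`, `corpus`, `bench`, `curve`, and
#'   `paths` of written artifacts.
#' @export
runEndToEnd <- function(config = runConfig(), verbose = TRUE) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) logMsg(...)
  say("generating corpus of %d molecules", config$corpusSize)
  corpus <- generateCorpus(config$corpusSize, config$maxHeavyAtoms,
                           seed = fanSeed(config$seed, "corpus"))
  if (!is.null(config$checkpoint) && file.exists(config$checkpoint)) {
    say("loading checkpoint %s", config$checkpoint)
    model <- loadModel(config$checkpoint)
  } else {
    say("simulating training spectra (%s)",
        paste(config$modalities, collapse = ", "))
    data <- prepareTrainingData(corpus, config$modalities,
                                seed = fanSeed(config$seed, "spectra"),
                                config = config$codec)
    say("training encoders")
    enc <- config$encoder
    enc$seed <- fanSeed(config$seed, "init")
    con <- config$contrastive
    con$seed <- fanSeed(config$seed, "train")
    fit <- trainModel(data, enc, con, verbose = verbose)
    model <- fit$model
    utils::write.csv(fit$history,
                     file.path(config$outputDir, "training_history.csv"),
                     row.names = FALSE)
    saveModel(model, file.path(config$outputDir, "checkpoint.rds"))
  }
  say("building index")
  index <- buildIndex(corpus, model)
  nq <- min(config$nQueries, nrow(corpus))
  qids <- withSeed(fanSeed(config$seed, "queries"),
                   sample(corpus$id, nq))
  say("benchmarking %d queries (retrieve + refine)", nq)
  bench <- benchmark(corpus, model, index, qids, config$modalities,
                     seed = fanSeed(config$seed, "bench"), refine = TRUE,
                     ga = config$ga)
  scaled <- minmaxScale(bench$scores)
  curve <- calibrationCurve(scaled, bench$correct)
  paths <- list(
    metrics = file.path(config$outputDir, "metrics.json"),
    calibration = file.path(config$outputDir, "calibration.csv"),
    rankings = file.path(config$outputDir, "rankings.csv"),
    config = file.path(config$outputDir, "config.json"))
  jsonlite::write_json(list(topk = as.list(bench$metrics$topk),
                            nQueries = nq,
                            spearman = calibrationSpearman(curve)),
                       paths$metrics, auto_unbox = TRUE, digits = NA)
  writeCalibration(curve, paths$calibration)
  allRank <- do.call(rbind, lapply(names(bench$rankings), function(id) {
    tb <- bench$rankings[[id]]@table
    cbind(query = id, rank = seq_len(nrow(tb)), tb)
  }))
  utils::write.csv(allRank, paths$rankings, row.names = FALSE)
  jsonlite::write_json(configToList(config), paths$config,
                       auto_unbox = TRUE, digits = NA)
  list(model = model, index = index, corpus = corpus, bench = bench,
       curve = curve, paths = paths)
}

configToList <- function(x) {
  if (inherits(x, c("runConfig", "encoderConfig", "contrastiveConfig",
                    "gaConfig", "codecConfig", "augmentConfig")) ||
      is.list(x))
    lapply(unclass(x), configToList)
  else x
}
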