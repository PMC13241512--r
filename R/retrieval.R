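## Retrieval: formula-filtered candidate pools, cosine search of spectra
## against precomputed molecule embeddings, multimodal fusion and rank
## metrics.

#' Build a molecule index
#'
#' Embeds every molecule of a corpus with the molecule encoder and stores
#' the records together with the embedding matrix.
#'
#' @param corpus data.frame from [generateCorpus] (columns `id`, `smiles`,
#'   `formula`, ...).
#' @param model a trained `specmolModel`.
#' @param provenance label of the grounding database.
#' @param batchSize molecules embedded per forward pass.
#' @return a [MoleculeIndex].
#' @export
buildIndex <- function(corpus, model, provenance = "synthetic",
                       batchSize = 64L) {
  n <- nrow(corpus)
  E <- matrix(0, n, model$config$d)
  for (s in seq(1, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1, n)
    E[idx, ] <- encodeMatrix(model, "molecule", corpus$smiles[idx])
  }
  formulas <- lapply(corpus$formula, parseFormulaString)
  new("MoleculeIndex",
      molecules = corpus[, c("id", "smiles",
                             intersect("heavyAtoms", colnames(corpus)))],
      formulas = formulas, embeddings = E, provenance = provenance)
}

formulaDistance <- function(a, b) {
  els <- union(names(a), names(b))
  av <- setNames(rep(0L, length(els)), els); av[names(a)] <- a
  bv <- setNames(rep(0L, length(els)), els); bv[names(b)] <- b
  sum(abs(av - bv))
}

#' Formula-filtered sub-index
#'
#' Restricts an index to molecules whose composition matches the query
#' formula. The default tolerance 0 keeps exact matches only (the formula
#' is routinely known from high-resolution MS); tolerance `t` keeps
#' molecules whose per-element absolute count differences sum to at most
#' `t`.
#'
#' @param index a [MoleculeIndex].
#' @param formula named count vector or formula string (e.g. `"C2H6O"`).
#' @param tolerance non-negative integer (default 0).
#' @return a [MoleculeIndex] containing the matching subset (possibly with
#'   zero molecules; the caller decides any fallback).
#' @export
formulaPool <- function(index, formula, tolerance = 0L) {
  if (is.character(formula)) formula <- parseFormulaString(formula)
  if (sum(formula) < 1) stop("query formula must contain at least one atom")
  keep <- vapply(index@formulas, function(f)
    formulaDistance(f, formula) <= tolerance, logical(1))
  new("MoleculeIndex", molecules = index@molecules[keep, , drop = FALSE],
      formulas = index@formulas[keep],
      embeddings = index@embeddings[keep, , drop = FALSE],
      provenance = index@provenance)
}

#' Fused multimodal similarity score
#'
#' Arithmetic mean of the per-modality cosine similarities between the
#' spectrum embeddings present (1 to 4 modalities) and one molecule
#' embedding.
#'
#' @param spectrumEmbeddings named list of [EmbeddingVector] (or numeric
#'   vectors), one per modality.
#' @param moleculeEmbedding an [EmbeddingVector] or numeric vector.
#' @return scalar in [-1, 1].
#' @export
fusedScore <- function(spectrumEmbeddings, moleculeEmbedding) {
  if (is(spectrumEmbeddings, "EmbeddingVector"))
    spectrumEmbeddings <- list(spectrumEmbeddings)
  N <- length(spectrumEmbeddings)
  if (N < 1 || N > 4) stop("between 1 and 4 modalities required")
  m <- if (is(moleculeEmbedding, "EmbeddingVector"))
    moleculeEmbedding@values else as.numeric(moleculeEmbedding)
  mean(vapply(spectrumEmbeddings, function(e) {
    v <- if (is(e, "EmbeddingVector")) e@values else as.numeric(e)
    cosineSim(v, m)
  }, numeric(1)))
}

#' Rank an index against query spectra
#'
#' Scores every molecule of the index (or formula pool) by the fused cosine
#' similarity to the query's spectrum embeddings and sorts descending; ties
#' are broken by canonical SMILES ascending so rankings are reproducible.
#'
#' @param index a [MoleculeIndex] (non-empty).
#' @param spectrumEmbeddings named list of per-modality [EmbeddingVector]
#'   (as from `encode(model, spectrumSet)`).
#' @param truth optional SMILES of the true molecule; its rank is recorded.
#' @return data.frame of class `retrievalResult`: `id`, `smiles`, `score`,
#'   one `cos_<modality>` column per modality, with attributes `trueRank`
#'   and `truth`.
#' @export
rankCandidates <- function(index, spectrumEmbeddings, truth = NULL) {
  n <- nrow(index@molecules)
  if (n == 0) stop("empty candidate pool")
  S <- do.call(rbind, lapply(spectrumEmbeddings, function(e)
    if (is(e, "EmbeddingVector")) e@values else as.numeric(e)))
  if (ncol(S) != ncol(index@embeddings))
    stop("embedding dimension mismatch between query and index")
  C <- tcrossprod(index@embeddings, S)   # n x modalities cosine terms
  colnames(C) <- paste0("cos_", names(spectrumEmbeddings))
  score <- rowMeans(C)
  ord <- order(-score, index@molecules$smiles)
  out <- data.frame(index@molecules[ord, c("id", "smiles")],
                    score = score[ord], C[ord, , drop = FALSE],
                    row.names = NULL)
  class(out) <- c("retrievalResult", "data.frame")
  if (!is.null(truth)) {
    attr(out, "truth") <- truth
    r <- which(out$smiles == truth)
    attr(out, "trueRank") <- if (length(r)) min(r) else NA_integer_
  }
  out
}

#' Top-k accuracy over a set of retrieval results
#'
#' @param results list of `retrievalResult` objects annotated with truth.
#' @param ks ranks at which accuracy is reported (default 1, 3, 5, 20).
#' @return list with `topk` (named numeric fractions) and `ranks` (integer
#'   vector of true ranks, NA when the truth was absent from the pool).
#' @export
rankMetrics <- function(results, ks = c(1, 3, 5, 20)) {
  ranks <- vapply(results, function(r) {
    tr <- attr(r, "trueRank")
    if (is.null(tr)) NA_integer_ else as.integer(tr)
  }, integer(1))
  topk <- vapply(ks, function(k) mean(!is.na(ranks) & ranks <= k),
                 numeric(1))
  names(topk) <- paste0("top", ks)
  list(topk = topk, ranks = ranks)
}
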