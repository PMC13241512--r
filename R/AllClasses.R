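## Central data containers. Spectrum vectors and sets are the currency of the
## whole pipeline: every encoder consumes a SpectrumVector and every query is
## a SpectrumSet holding 1-4 modalities.

SPECTRUM_MODALITIES <- c("c13", "h1", "ir", "hsqc")

#' SpectrumVector: fixed-length numeric encoding of one spectral modality
#'
#' The unit every encoder consumes. 1D modalities (`c13`, `h1`, `ir`) store a
#' numeric vector; `hsqc` stores a square matrix (rows = carbon axis, columns
#' = proton axis). Axis metadata records the physical range in increasing
#' units; any reversed NMR-style display is a presentation concern.
#'
#' @slot modality one of `"c13"`, `"h1"`, `"ir"`, `"hsqc"`.
#' @slot values numeric vector, or matrix for `hsqc`.
#' @slot axisLo,axisHi numeric axis bounds (two values for `hsqc`: carbon
#'   axis first, proton axis second).
#' @slot units character axis units (`"ppm"` or `"cm-1"`).
#' @exportClass SpectrumVector
setClass("SpectrumVector",
  representation(modality = "character", values = "ANY",
                 axisLo = "numeric", axisHi = "numeric", units = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!(object@modality %in% SPECTRUM_MODALITIES))
      msg <- c(msg, "modality must be one of c13/h1/ir/hsqc")
    v <- object@values
    if (object@modality == "hsqc") {
      if (!is.matrix(v)) msg <- c(msg, "hsqc values must be a matrix")
    } else {
      if (!is.numeric(v) || is.matrix(v))
        msg <- c(msg, "1D modalities store a numeric vector")
    }
    if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
    if (object@modality == "c13") {
      if (!all(v %in% c(0, 1))) msg <- c(msg, "c13 vector must be binary")
    } else if (length(v) && (min(v) < 0 || max(v) > 1)) {
      msg <- c(msg, "normalized values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn SpectrumVector constructor.
#' @param modality,values,axisLo,axisHi,units see slots.
#' @export
SpectrumVector <- function(modality, values, axisLo, axisHi, units = "ppm") {
  new("SpectrumVector", modality = modality, values = values,
      axisLo = axisLo, axisHi = axisHi, units = units)
}

#' SpectrumSet: the 1-4 modalities measured for one query
#'
#' A flexible bag of modalities attached to one molecule or query; the
#' pipeline accepts any non-empty subset of the four supported techniques.
#'
#' @slot spectra named list of [SpectrumVector] objects, names are the
#'   modalities.
#' @exportClass SpectrumSet
setClass("SpectrumSet",
  representation(spectra = "list"),
  validity = function(object) {
    sp <- object@spectra
    if (length(sp) < 1 || length(sp) > 4)
      return("a SpectrumSet holds between 1 and 4 modalities")
    if (is.null(names(sp)) || anyDuplicated(names(sp)))
      return("spectra must be uniquely named by modality")
    for (m in names(sp)) {
      if (!is(sp[[m]], "SpectrumVector")) return("entries must be SpectrumVector")
      if (sp[[m]]@modality != m) return("list name must equal the modality tag")
    }
    TRUE
  })

#' @describeIn SpectrumSet constructor from SpectrumVector objects.
#' @param ... SpectrumVector objects (or one list of them).
#' @export
SpectrumSet <- function(...) {
  sp <- list(...)
  if (length(sp) == 1 && is.list(sp[[1]]) && !is(sp[[1]], "SpectrumVector"))
    sp <- sp[[1]]
  names(sp) <- vapply(sp, function(s) s@modality, "")
  new("SpectrumSet", spectra = sp)
}

#' EmbeddingVector: a point in the shared spectrum-molecule space
#'
#' @slot values numeric, unit Euclidean norm.
#' @slot modality source modality (`"molecule"` or a spectral modality).
#' @exportClass EmbeddingVector
setClass("EmbeddingVector",
  representation(values = "numeric", modality = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("embedding must be finite")
    n <- sqrt(sum(object@values^2))
    if (abs(n - 1) > 1e-6) return("embedding must have unit norm")
    TRUE
  })

#' MoleculeIndex: a grounding database of molecules with embeddings
#'
#' Ordered molecule records plus their precomputed molecule-encoder
#' embeddings; the search pool for retrieval and the seed pool for the
#' genetic algorithm.
#'
#' @slot molecules data.frame with columns `id`, `smiles`, `heavyAtoms`.
#' @slot formulas list of named integer vectors (element counts, H included).
#' @slot embeddings numeric matrix, one row per molecule, d columns.
#' @slot provenance character label of the grounding database.
#' @exportClass MoleculeIndex
setClass("MoleculeIndex",
  representation(molecules = "data.frame", formulas = "list",
                 embeddings = "matrix", provenance = "character"),
  validity = function(object) {
    n <- nrow(object@molecules)
    if (length(object@formulas) != n)
      return("one formula per molecule required")
    if (nrow(object@embeddings) != n)
      return("one embedding row per molecule required")
    if (!all(c("id", "smiles") %in% colnames(object@molecules)))
      return("molecules needs id and smiles columns")
    TRUE
  })

#' RewardBreakdown: the components of the GA reward
#'
#' Holds the per-modality cosine terms, the modality count N, the wrong-atom
#' count W against the target formula, the target atom total T, and the
#' scalar reward `R = mean(cosines) - W/T`.
#'
#' @slot cosines named numeric per-modality cosine similarities.
#' @slot W,T integer wrong-atom count and target atom total (H included).
#' @slot R numeric scalar reward.
#' @exportClass RewardBreakdown
setClass("RewardBreakdown",
  representation(cosines = "numeric", W = "numeric", T_ = "numeric",
                 R = "numeric"),
  validity = function(object) {
    N <- length(object@cosines)
    if (N < 1 || N > 4) return("between 1 and 4 modality cosines required")
    if (object@W < 0) return("W must be >= 0")
    if (object@T_ < 1) return("T must be >= 1")
    expect <- mean(object@cosines) - object@W / object@T_
    if (abs(object@R - expect) > 1e-9)
      return("R must equal mean(cosines) - W/T")
    if (object@R > 1 + 1e-9) return("R cannot exceed 1")
    TRUE
  })

#' CandidateRanking: the final ordered structure proposals
#'
#' Union of retrieved and GA-generated candidates, deduplicated by canonical
#' SMILES, sorted by reward descending (canonical-string tie-break).
#'
#' @slot table data.frame with columns `smiles`, `score`, `provenance`, and,
#'   when a reference structure is known, logical `fpMatch` / `exactMatch`.
#' @exportClass CandidateRanking
setClass("CandidateRanking",
  representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    if (!all(c("smiles", "score", "provenance") %in% colnames(tb)))
      return("table needs smiles, score, provenance columns")
    if (anyDuplicated(tb$smiles)) return("candidates must be deduplicated")
    if (is.unsorted(rev(tb$score), strictly = FALSE))
      return("scores must be non-increasing")
    TRUE
  })

#' CalibrationCurve: score-binned empirical accuracy
#'
#' @slot bins data.frame with columns `lo`, `hi`, `count`, `accuracy`
#'   (NA for empty bins), `meanScore`.
#' @slot nTotal integer evaluation size.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(bins = "data.frame", nTotal = "numeric"),
  validity = function(object) {
    b <- object@bins
    if (sum(b$count) != object@nTotal) return("bin counts must sum to nTotal")
    acc <- b$accuracy[!is.na(b$accuracy)]
    if (length(acc) && (min(acc) < 0 || max(acc) > 1))
      return("accuracies must lie in [0, 1]")
    TRUE
  })

## ---- show methods -------------------------------------------------------

setMethod("show", "SpectrumVector", function(object) {
  dims <- if (is.matrix(object@values))
    paste(dim(object@values), collapse = " x ") else length(object@values)
  cat(sprintf("SpectrumVector [%s] %s values, axis %s..%s %s\n",
              object@modality, dims, paste(object@axisLo, collapse = "/"),
              paste(object@axisHi, collapse = "/"), object@units))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet with %d modalities: %s\n",
              length(object@spectra), paste(names(object@spectra),
                                            collapse = ", ")))
})

setMethod("show", "MoleculeIndex", function(object) {
  cat(sprintf("MoleculeIndex '%s': %d molecules, embedding dim %d\n",
              object@provenance, nrow(object@molecules),
              ncol(object@embeddings)))
})

setMethod("show", "RewardBreakdown", function(object) {
  cat(sprintf("RewardBreakdown: R = %.4f (mean cos %.4f over N=%d, W=%d, T=%d)\n",
              object@R, mean(object@cosines), length(object@cosines),
              object@W, object@T_))
})

setMethod("show", "CandidateRanking", function(object) {
  cat(sprintf("CandidateRanking with %d candidates (%d generated, %d retrieved)\n",
              nrow(object@table), sum(object@table$provenance == "generated"),
              sum(object@table$provenance == "retrieved")))
  print(head(object@table, 5))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve over %d evaluations, %d bins\n",
              object@nTotal, nrow(object@bins)))
})

## ---- accessors ----------------------------------------------------------

#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))
#' Numeric payload of a SpectrumVector
#' @param x a SpectrumVector.
#' @return numeric vector or matrix.
#' @export
setMethod("spectrumValues", "SpectrumVector", function(x) x@values)

#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' Modality tag of a spectrum or embedding
#' @param x a SpectrumVector or EmbeddingVector.
#' @return character scalar.
#' @export
setMethod("modality", "SpectrumVector", function(x) x@modality)
#' @export
setMethod("modality", "EmbeddingVector", function(x) x@modality)

#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))
#' Modalities present in a SpectrumSet
#' @param x a SpectrumSet.
#' @return character vector.
#' @export
setMethod("modalities", "SpectrumSet", function(x) names(x@spectra))

#' @export
setGeneric("embeddingValues", function(x) standardGeneric("embeddingValues"))
#' Numeric values of an embedding
#' @param x an EmbeddingVector.
#' @return numeric vector of the shared dimension.
#' @export
setMethod("embeddingValues", "EmbeddingVector", function(x) x@values)

#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))
#' Ranked candidate table
#' @param x a CandidateRanking.
#' @return data.frame sorted by score descending.
#' @export
setMethod("rankingTable", "CandidateRanking", function(x) x@table)

#' @export
setGeneric("calibrationBins", function(x) standardGeneric("calibrationBins"))
#' Bin table of a calibration curve
#' @param x a CalibrationCurve.
#' @return data.frame of bins.
#' @export
setMethod("calibrationBins", "CalibrationCurve", function(x) x@bins)

#' @export
setGeneric("indexMolecules", function(x) standardGeneric("indexMolecules"))
#' Molecule table of an index
#' @param x a MoleculeIndex.
#' @return data.frame with id/smiles columns.
#' @export
setMethod("indexMolecules", "MoleculeIndex", function(x) x@molecules)

#' @export
setGeneric("indexEmbeddings", function(x) standardGeneric("indexEmbeddings"))
#' Embedding matrix of an index
#' @param x a MoleculeIndex.
#' @return numeric matrix (molecules x d).
#' @export
setMethod("indexEmbeddings", "MoleculeIndex", function(x) x@embeddings)

setMethod("length", "SpectrumSet", function(x) length(x@spectra))

#' Extract one modality from a SpectrumSet
#' @param x a SpectrumSet.
#' @param i modality name or position.
#' @param j,... unused.
#' @return a SpectrumVector.
#' @export
setMethod("[[", "SpectrumSet", function(x, i, j, ...) x@spectra[[i]])
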