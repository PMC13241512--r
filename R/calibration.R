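## Confidence calibration: min-max scaling of pipeline scores over an
## evaluation set and score-binned empirical accuracy curves.

#' Min-max scale a set of scores
#'
#' Maps scores affinely so the minimum hits 0 and the maximum hits 1. The
#' scaling constants are taken from the evaluation set itself unless frozen
#' constants are supplied (deployment mode).
#'
#' @param scores numeric vector with at least 2 distinct values.
#' @param constants optional `c(min, max)` to freeze the scaling.
#' @return numeric vector of scaled scores; attribute `constants` records
#'   the min/max used.
#' @export
minmaxScale <- function(scores, constants = NULL) {
  if (is.null(constants)) constants <- range(scores)
  if (diff(constants) <= 0)
    stop("all scores are equal; min-max scaling is undefined")
  structure((scores - constants[1]) / diff(constants),
            constants = constants)
}

#' Score-binned calibration curve
#'
#' Bins scaled scores into equal-width bins over [0, 1] and reports the
#' empirical accuracy (fraction correct) per bin. Empty bins are reported
#' with count 0 and accuracy NA.
#'
#' @param scaledScores numeric in [0, 1] (see [minmaxScale]).
#' @param correct logical flags aligned with `scaledScores`.
#' @param nBins number of bins (default 10).
#' @return a [CalibrationCurve].
#' @export
calibrationCurve <- function(scaledScores, correct, nBins = 10L) {
  if (length(scaledScores) != length(correct))
    stop("scores and correctness flags must be aligned")
  if (nBins < 2) stop("nBins must be >= 2")
  edges <- seq(0, 1, length.out = nBins + 1)
  bin <- pmin(pmax(findInterval(scaledScores, edges, rightmost.closed = TRUE),
                   1L), nBins)
  bins <- data.frame(lo = edges[-(nBins + 1)], hi = edges[-1],
                     count = 0L, accuracy = NA_real_,
                     meanScore = NA_real_)
  for (b in seq_len(nBins)) {
    in_b <- bin == b
    bins$count[b] <- sum(in_b)
    if (any(in_b)) {
      bins$accuracy[b] <- mean(correct[in_b])
      bins$meanScore[b] <- mean(scaledScores[in_b])
    }
  }
  new("CalibrationCurve", bins = bins, nTotal = length(scaledScores))
}

#' Rank correlation between score and accuracy across bins
#'
#' Spearman correlation of per-bin mean scaled score against per-bin
#' empirical accuracy (non-empty bins only); positive values indicate that
#' higher pipeline scores are empirically more trustworthy.
#'
#' @param curve a [CalibrationCurve].
#' @return numeric scalar in [-1, 1].
#' @export
calibrationSpearman <- function(curve) {
  b <- curve@bins[curve@bins$count > 0, ]
  if (nrow(b) < 2) return(NA_real_)
  cor(b$meanScore, b$accuracy, method = "spearman")
}

#' Expected accuracy above a score threshold
#'
#' Lookup helper: given a calibration curve, returns the pooled empirical
#' accuracy of all evaluations whose scaled score meets the threshold.
#'
#' @param curve a [CalibrationCurve].
#' @param threshold scaled-score threshold in [0, 1].
#' @return numeric accuracy estimate (NA if no bin lies above threshold).
#' @export
expectedAccuracy <- function(curve, threshold) {
  b <- curve@bins[curve@bins$count > 0 & curve@bins$lo >= threshold - 1e-12, ]
  if (!nrow(b)) return(NA_real_)
  sum(b$accuracy * b$count) / sum(b$count)
}

#' Plot a calibration curve
#'
#' @param curve a [CalibrationCurve].
#' @param ... passed to [plot].
#' @return invisibly, the bin table.
#' @export
plotCalibration <- function(curve, ...) {
  b <- curve@bins[curve@bins$count > 0, ]
  plot(b$meanScore, b$accuracy, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "min-max scaled score", ylab = "empirical accuracy",
       pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(curve@bins)
}

#' Export a calibration curve as CSV
#'
#' @param curve a [CalibrationCurve].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCalibration <- function(curve, path) {
  write.csv(curve@bins, path, row.names = FALSE)
  invisible(path)
}
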