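## Spectral codec: raw peak lists / continuous traces -> the fixed-length
## numeric representations the encoders consume.
##
## Axis conventions (one internal convention; reversed NMR display is a
## presentation concern only):
##   c13  : 0..300 ppm, binary occupancy vector (default 512 bins, so one bin
##          covers 300/512 ~ 0.59 ppm)
##   h1   : -2..10 ppm, length 10,000; element j (1-based) sits at
##          ppm = -2 + 12*(j-1)/9999
##   ir   : 600..3800 cm^-1, length 1600 (2 cm^-1 per element), transmittance
##   hsqc : 512 x 512 grid, rows = 13C 0..300 ppm, cols = 1H -2..10 ppm

#' Codec configuration
#'
#' Axis ranges and vector lengths for all four modalities. Defaults follow
#' the package-wide conventions above; everything is overridable.
#'
#' @param c13Len,h1Len,irLen vector lengths of the 1D modalities.
#' @param hsqcDim side length of the square HSQC grid.
#' @param c13Range,h1Range,irRange numeric length-2 axis ranges.
#' @param h1LineShape `"lorentzian"` (natural NMR line shape) or
#'   `"gaussian"`, used when a 1H peak list is rendered to a trace.
#' @return list of class `codecConfig`.
#' @export
codecConfig <- function(c13Len = 512L, h1Len = 10000L, irLen = 1600L,
                        hsqcDim = 512L, c13Range = c(0, 300),
                        h1Range = c(-2, 10), irRange = c(600, 3800),
                        h1LineShape = c("lorentzian", "gaussian")) {
  structure(list(c13Len = as.integer(c13Len), h1Len = as.integer(h1Len),
                 irLen = as.integer(irLen), hsqcDim = as.integer(hsqcDim),
                 c13Range = c13Range, h1Range = h1Range, irRange = irRange,
                 h1LineShape = match.arg(h1LineShape)),
            class = "codecConfig")
}

#' Augmentation configuration
#'
#' Controls the realism augmentations applied to simulated spectra: peak
#' position jitter, line broadening, additive noise and slow baseline drift.
#' All scales of zero make augmentation the identity; a fixed seed plus a
#' fixed config makes it deterministic.
#'
#' @param jitter standard deviation of zero-mean peak-position jitter, in
#'   axis units (ppm for NMR). Default 0.01 ppm.
#' @param broadening multiplicative width-broadening factor. Default 1.1.
#' @param noise additive noise scale as a fraction of the trace maximum.
#'   Default 0.01.
#' @param drift baseline-drift amplitude as a fraction of the trace maximum.
#'   Default 0.02.
#' @param seed integer RNG seed, or NULL to draw from the session stream.
#' @return list of class `augmentConfig`.
#' @export
augmentConfig <- function(jitter = 0.01, broadening = 1.1, noise = 0.01,
                          drift = 0.02, seed = NULL) {
  stopifnot(jitter >= 0, broadening >= 0, noise >= 0, drift >= 0)
  structure(list(jitter = jitter, broadening = broadening, noise = noise,
                 drift = drift, seed = seed), class = "augmentConfig")
}

#' Build a 1D peak list
#'
#' @param modality `"c13"`, `"h1"` or `"ir"`.
#' @param position peak positions (ppm, or cm^-1 for IR).
#' @param intensity non-negative intensities (arbitrary units).
#' @param width line widths (FWHM) in axis units, >= 0.
#' @return data.frame of class `PeakList` with a `modality` attribute.
#' @export
peakList <- function(modality = c("c13", "h1", "ir"), position,
                     intensity = rep(1, length(position)),
                     width = rep(0, length(position))) {
  modality <- match.arg(modality)
  if (any(!is.finite(position))) stop("peak positions must be finite")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (any(width < 0)) stop("widths must be >= 0")
  structure(data.frame(position = as.numeric(position),
                       intensity = as.numeric(intensity),
                       width = as.numeric(width)),
            modality = modality, class = c("PeakList", "data.frame"))
}

#' Build an HSQC peak table
#'
#' One row per cross peak: carbon centroid / extent and proton centroid /
#' extent, all in ppm.
#'
#' @param c_centroid,c_min,c_max carbon-axis centroid and extent.
#' @param h_centroid,h_min,h_max proton-axis centroid and extent.
#' @return data.frame of class `HSQCPeaks`.
#' @export
hsqcPeaks <- function(c_centroid, c_min = c_centroid, c_max = c_centroid,
                      h_centroid, h_min = h_centroid, h_max = h_centroid) {
  if (any(c_min > c_centroid) || any(c_centroid > c_max) ||
      any(h_min > h_centroid) || any(h_centroid > h_max))
    stop("peak extents must bracket the centroid (min <= centroid <= max)")
  structure(data.frame(c_centroid = c_centroid, c_min = c_min, c_max = c_max,
                       h_centroid = h_centroid, h_min = h_min, h_max = h_max),
            class = c("HSQCPeaks", "data.frame"))
}

## min-max scale to [0,1]; a constant trace (max == min) degenerates to the
## all-zero vector, with a message, so downstream code never sees NaN.
minmaxTrace <- function(v, what = "trace") {
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0) {
    logMsg("degenerate %s (constant values): emitting all-zero vector", what)
    return(rep(0, length(v)))
  }
  (v - lo) / (hi - lo)
}

#' Bin a 13C peak list into a binary shift-occupancy vector
#'
#' Each peak sets the bin containing its chemical shift; the result is a
#' binary positional encoding over 0-300 ppm. A shift exactly at the upper
#' axis bound clamps into the last bin; out-of-range shifts are dropped with
#' a warning (silent wrap-around would corrupt training pairs).
#'
#' @param peaks a `PeakList` with modality `"c13"`, or a numeric vector of
#'   shifts in ppm.
#' @param config a [codecConfig].
#' @return a [SpectrumVector] with binary values of length `config$c13Len`.
#' @export
binC13 <- function(peaks, config = codecConfig()) {
  pos <- if (is.data.frame(peaks)) {
    if (!identical(attr(peaks, "modality"), "c13"))
      stop("binC13 expects a c13 peak list")
    peaks$position
  } else as.numeric(peaks)
  if (any(!is.finite(pos))) stop("non-finite chemical shift")
  lo <- config$c13Range[1]; hi <- config$c13Range[2]; n <- config$c13Len
  out <- pos < lo | pos > hi
  if (any(out)) {
    warning(sprintf("dropping %d 13C peak(s) outside [%g, %g] ppm",
                    sum(out), lo, hi))
    pos <- pos[!out]
  }
  width <- (hi - lo) / n
  idx <- pmin(floor((pos - lo) / width) + 1L, n)  # hi clamps into last bin
  v <- numeric(n)
  v[idx] <- 1
  SpectrumVector("c13", v, lo, hi, "ppm")
}

## render a peak list as a sum of line shapes on a uniform grid
renderPeaks1D <- function(grid, peaks, shape = "lorentzian") {
  v <- numeric(length(grid))
  if (nrow(peaks) == 0) return(v)
  step <- grid[2] - grid[1]
  for (i in seq_len(nrow(peaks))) {
    p <- peaks$position[i]; I <- peaks$intensity[i]; w <- peaks$width[i]
    if (w <= 0) {                       # stick spectrum: nearest grid point
      j <- which.min(abs(grid - p))
      v[j] <- v[j] + I
    } else if (shape == "lorentzian") {
      g <- w / 2                        # width is FWHM; g is HWHM
      v <- v + I * g^2 / ((grid - p)^2 + g^2)
    } else {
      s <- w / 2.3548                   # FWHM -> sigma
      v <- v + I * exp(-(grid - p)^2 / (2 * s^2))
    }
  }
  v
}

## interpolate a measured trace (axis, value) onto a uniform grid; points
## outside the measured axis get `fill`
gridTrace <- function(grid, axis, value, fill = 0) {
  if (length(axis) < 2) stop("continuous trace needs at least 2 points")
  o <- order(axis)
  y <- approx(axis[o], value[o], xout = grid, rule = 1)$y
  y[is.na(y)] <- fill
  y
}

#' Vectorize a 1H NMR spectrum
#'
#' Produces the length-10,000 intensity vector over -2..10 ppm. Peak-list
#' input is rendered as a sum of Lorentzian line shapes (configurable
#' Gaussian alternative) before sampling; continuous traces are linearly
#' interpolated onto the grid. The result is min-max scaled to [0, 1]; a
#' constant trace degenerates to the all-zero vector.
#'
#' @param x a `PeakList` with modality `"h1"`, or a two-column data.frame /
#'   list with fields `axis` (ppm) and `value`.
#' @param config a [codecConfig].
#' @param scale min-max scale the result (default TRUE).
#' @return a [SpectrumVector] of length `config$h1Len`.
#' @export
vectorizeH1 <- function(x, config = codecConfig(), scale = TRUE) {
  lo <- config$h1Range[1]; hi <- config$h1Range[2]
  grid <- seq(lo, hi, length.out = config$h1Len)
  v <- if (inherits(x, "PeakList")) {
    if (!identical(attr(x, "modality"), "h1"))
      stop("vectorizeH1 expects an h1 peak list")
    renderPeaks1D(grid, x, config$h1LineShape)
  } else {
    x <- as.list(x)
    ax <- x[[if ("axis" %in% names(x)) "axis" else 1]]
    va <- x[[if ("value" %in% names(x)) "value" else 2]]
    gridTrace(grid, ax, va, fill = 0)
  }
  if (scale) v <- minmaxTrace(v, "1H trace")
  SpectrumVector("h1", v, lo, hi, "ppm")
}

#' Vectorize an IR transmittance spectrum
#'
#' Length-1600 vector over 600-3800 cm^-1 (2 cm^-1 per element). Regions
#' with no measurement are filled with baseline transmittance 1.0 (no
#' absorption). Peak-list input is interpreted as absorption bands
#' (Gaussian dips of the given depth and width) subtracted from the unit
#' baseline. The result is min-max scaled to [0, 1].
#'
#' @param x a `PeakList` with modality `"ir"` (position = band center,
#'   intensity = dip depth in [0,1], width = FWHM), or a trace as in
#'   [vectorizeH1] with `value` = transmittance.
#' @param config a [codecConfig].
#' @param scale min-max scale the result (default TRUE).
#' @return a [SpectrumVector] of length `config$irLen`.
#' @export
vectorizeIR <- function(x, config = codecConfig(), scale = TRUE) {
  lo <- config$irRange[1]; hi <- config$irRange[2]
  step <- (hi - lo) / config$irLen
  grid <- seq(lo, by = step, length.out = config$irLen)
  v <- if (inherits(x, "PeakList")) {
    if (!identical(attr(x, "modality"), "ir"))
      stop("vectorizeIR expects an ir peak list")
    pmax(1 - renderPeaks1D(grid, x, "gaussian"), 0)
  } else {
    x <- as.list(x)
    ax <- x[[if ("axis" %in% names(x)) "axis" else 1]]
    va <- x[[if ("value" %in% names(x)) "value" else 2]]
    if (length(ax) == 0) rep(1, length(grid))
    else gridTrace(grid, ax, va, fill = 1)
  }
  if (scale) v <- minmaxTrace(v, "IR trace")
  SpectrumVector("ir", v, lo, hi, "cm-1")
}

#' Rasterize HSQC cross peaks onto a 512 x 512 grid
#'
#' Each peak becomes a 2D Gaussian centered at its (optionally jittered)
#' centroid. The per-axis standard deviation is (max - min)/4, floored at
#' one grid cell, so the reported extent covers roughly +-2 sigma. The grid
#' is max-normalized to [0, 1]. Peaks whose centroid lies outside the axis
#' windows are dropped with a warning.
#'
#' @param peaks an `HSQCPeaks` table (may have zero rows).
#' @param augment optional [augmentConfig]; its `jitter` is applied to both
#'   centroid axes and `broadening` to the extents.
#' @param config a [codecConfig].
#' @return a [SpectrumVector] holding a `hsqcDim` x `hsqcDim` matrix
#'   (rows = 13C axis, columns = 1H axis).
#' @export
rasterizeHSQC <- function(peaks, augment = NULL, config = codecConfig()) {
  n <- config$hsqcDim
  cLo <- config$c13Range[1]; cHi <- config$c13Range[2]
  hLo <- config$h1Range[1]; hHi <- config$h1Range[2]
  cellC <- (cHi - cLo) / n; cellH <- (hHi - hLo) / n
  grid <- matrix(0, n, n)
  if (nrow(peaks) > 0) {
    doRaster <- function() {
      cc <- peaks$c_centroid; hc <- peaks$h_centroid
      cw <- peaks$c_max - peaks$c_min; hw <- peaks$h_max - peaks$h_min
      if (!is.null(augment)) {
        cc <- cc + rnorm(length(cc), 0, augment$jitter)
        hc <- hc + rnorm(length(hc), 0, augment$jitter)
        cw <- cw * augment$broadening; hw <- hw * augment$broadening
      }
      out <- cc < cLo | cc > cHi | hc < hLo | hc > hHi
      if (any(out))
        warning(sprintf("dropping %d HSQC peak(s) outside the axis windows",
                        sum(out)))
      for (i in which(!out)) {
        sC <- max(cw[i] / 4, cellC); sH <- max(hw[i] / 4, cellH)
        iC <- pmax(1, pmin(n, floor((cc[i] - cLo) / cellC) + 1))
        iH <- pmax(1, pmin(n, floor((hc[i] - hLo) / cellH) + 1))
        # evaluate on a +-4 sigma subwindow only
        rC <- max(1, iC - ceiling(4 * sC / cellC)):min(n, iC + ceiling(4 * sC / cellC))
        rH <- max(1, iH - ceiling(4 * sH / cellH)):min(n, iH + ceiling(4 * sH / cellH))
        ppmC <- cLo + (rC - 0.5) * cellC
        ppmH <- hLo + (rH - 0.5) * cellH
        g <- exp(-(ppmC - cc[i])^2 / (2 * sC^2)) %o%
             exp(-(ppmH - hc[i])^2 / (2 * sH^2))
        grid[rC, rH] <- grid[rC, rH] + g
      }
      grid
    }
    grid <- if (!is.null(augment) && !is.null(augment$seed))
      withSeed(augment$seed, doRaster()) else doRaster()
  }
  m <- max(grid)
  if (m > 0) grid <- grid / m
  SpectrumVector("hsqc", grid, c(cLo, hLo), c(cHi, hHi), "ppm")
}

#' Linear resampling of a numeric sequence
#'
#' Resamples a uniformly sampled sequence onto a uniform grid of a new
#' length by linear interpolation; endpoints are preserved exactly. Used to
#' reduce long instrument traces (e.g. 32,768 points) to the model's input
#' length (e.g. 10,000).
#'
#' @param values numeric sequence, length >= 2.
#' @param targetLen desired output length, >= 2.
#' @return numeric vector of length `targetLen`.
#' @export
resampleLinear <- function(values, targetLen) {
  if (length(values) < 2) stop("input must have at least 2 values")
  if (targetLen < 2) stop("targetLen must be >= 2")
  x <- seq(0, 1, length.out = length(values))
  approx(x, values, xout = seq(0, 1, length.out = targetLen))$y
}

#' Augment a 1H spectrum for realism
#'
#' Applies position jitter, width broadening, additive noise and slow
#' baseline drift. Peak-list input gets jitter/broadening on the peaks;
#' vector input (a raw length-`h1Len` trace or [SpectrumVector]) gets
#' noise and drift. All scales 0 is the identity; a fixed seed makes the
#' augmentation deterministic.
#'
#' @param x a `PeakList` (modality `"h1"`), numeric vector or
#'   [SpectrumVector].
#' @param config an [augmentConfig].
#' @return the same kind of object as `x`.
#' @export
augmentH1 <- function(x, config = augmentConfig()) {
  apply1 <- function() {
    if (inherits(x, "PeakList")) {
      p <- x
      if (config$jitter > 0)
        p$position <- p$position + rnorm(nrow(p), 0, config$jitter)
      if (config$broadening != 0) p$width <- p$width * config$broadening
      attr(p, "modality") <- attr(x, "modality")
      class(p) <- class(x)
      p
    } else {
      sv <- is(x, "SpectrumVector")
      v <- if (sv) x@values else as.numeric(x)
      m <- max(abs(v))
      if (m > 0 && (config$noise > 0 || config$drift > 0)) {
        if (config$noise > 0) v <- v + rnorm(length(v), 0, config$noise * m)
        if (config$drift > 0) {
          ph <- runif(1, 0, 2 * pi)
          v <- v + config$drift * m *
            sin(2 * pi * seq(0, 1, length.out = length(v)) + ph)
        }
        v <- pmax(v, 0)
        if (sv) v <- minmaxTrace(v, "augmented 1H trace")
      }
      if (sv) SpectrumVector("h1", v, x@axisLo, x@axisHi, x@units) else v
    }
  }
  if (!is.null(config$seed)) withSeed(config$seed, apply1()) else apply1()
}
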