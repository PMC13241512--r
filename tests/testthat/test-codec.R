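## Spectrum vectorization contracts: bin arithmetic, axis conventions,
## normalization and augmentation determinism.

test_that("13C binning maps shifts to the documented bins", {
  # lower boundary occupies the first bin
  v <- spectrumValues(binC13(0))
  expect_equal(which(v == 1), 1L)
  expect_equal(length(v), 512L)
  # 150 ppm: floor(150 / (300/512)) = 256 (0-based) -> index 257
  expect_equal(which(spectrumValues(binC13(150)) == 1), 257L)
  # exact upper boundary clamps into the last bin
  expect_equal(which(spectrumValues(binC13(300)) == 1), 512L)
  # empty peak list gives the all-zero vector
  expect_equal(sum(spectrumValues(binC13(numeric(0)))), 0)
  # out-of-range peaks are dropped with a warning, not wrapped
  expect_warning(v <- spectrumValues(binC13(c(150, 400))), "outside")
  expect_equal(which(v == 1), 257L)
  expect_error(binC13(NaN), "finite")
})

test_that("13C binning is monotone and binary", {
  shifts <- sort(runif(50, 0, 300))
  idx <- vapply(shifts, function(s) which(spectrumValues(binC13(s)) == 1),
                integer(1))
  expect_true(all(diff(idx) >= 0))
  v <- spectrumValues(binC13(shifts))
  expect_true(all(v %in% c(0, 1)))
})

test_that("1H vectorization has the documented grid and scaling", {
  pk <- peakList("h1", position = 2.0, intensity = 1, width = 0.01)
  v <- spectrumValues(vectorizeH1(pk))
  expect_length(v, 10000L)
  # ppm = -2 + 12*j/9999 -> j = 3333 (0-based), index 3334
  expect_equal(which.max(v), 3334L)
  expect_equal(range(v), c(0, 1))
  # flat trace degenerates to all zeros
  flat <- suppressMessages(vectorizeH1(list(axis = c(-2, 10),
                                            value = c(5, 5))))
  expect_equal(sum(spectrumValues(flat)), 0)
})

test_that("IR vectorization covers 600-3800 at 2 cm-1 per element", {
  pk <- peakList("ir", position = 2200, intensity = 0.8, width = 40)
  v <- spectrumValues(vectorizeIR(pk))
  expect_length(v, 1600L)
  # (2200 - 600) / 2 = 800 (0-based) -> index 801
  expect_equal(which.min(v), 801L)
  # empty trace is the unit baseline before scaling
  empty <- peakList("ir", position = numeric(0))
  raw <- spectrumValues(vectorizeIR(empty, scale = FALSE))
  expect_true(all(raw == 1))
})

test_that("HSQC rasterization places peaks at their centroid cell", {
  pk <- hsqcPeaks(c_centroid = 75.2, c_min = 73.2, c_max = 77.2,
                  h_centroid = 3.5, h_min = 3.4, h_max = 3.6)
  sv <- rasterizeHSQC(pk)
  g <- spectrumValues(sv)
  expect_equal(dim(g), c(512L, 512L))
  am <- which(g == max(g), arr.ind = TRUE)[1, ]
  # independent coordinate-to-cell mapping
  expect_equal(unname(am["row"]), floor(75.2 / (300 / 512)) + 1)
  expect_equal(unname(am["col"]), floor((3.5 + 2) / (12 / 512)) + 1)
  expect_equal(max(g), 1)
  # empty peak table -> all-zero grid; mass is positive iff a peak is in
  # the window
  empty <- rasterizeHSQC(hsqcPeaks(c_centroid = numeric(0),
                                   h_centroid = numeric(0)))
  expect_equal(sum(spectrumValues(empty)), 0)
  expect_warning(out <- rasterizeHSQC(hsqcPeaks(c_centroid = 400,
                                                h_centroid = 3)),
                 "outside")
  expect_equal(sum(spectrumValues(out)), 0)
})

test_that("linear resampling preserves endpoints, identity and linearity", {
  x <- c(0.2, 0.9, 0.1, 0.5, 1.4)
  expect_equal(resampleLinear(x, length(x)), x)
  y <- resampleLinear(seq(0, 1, length.out = 5), 9)
  expect_equal(y, seq(0, 1, length.out = 9))
  long <- sin(seq_len(32768) / 500)
  short <- resampleLinear(long, 10000)
  expect_length(short, 10000L)
  expect_equal(short[1], long[1])
  expect_equal(short[10000], long[32768])
  expect_error(resampleLinear(x, 1), "targetLen")
  # commutes with affine transforms of the values
  a <- 2.5; b <- -1.2
  expect_equal(resampleLinear(a * x + b, 9), a * resampleLinear(x, 9) + b)
})

test_that("1H augmentation is the identity at zero scales and seed-deterministic", {
  pk <- peakList("h1", position = c(1.2, 3.4), intensity = c(3, 1),
                 width = c(0.02, 0.02))
  idc <- augmentConfig(jitter = 0, broadening = 0, noise = 0, drift = 0,
                       seed = 7)
  expect_equal(augmentH1(pk, idc)$position, pk$position)
  v <- spectrumValues(vectorizeH1(pk))
  expect_equal(augmentH1(v, idc), v)
  cfg <- augmentConfig(seed = 42)
  expect_identical(augmentH1(v, cfg), augmentH1(v, cfg))
  a <- augmentH1(pk, augmentConfig(seed = 1))
  b <- augmentH1(pk, augmentConfig(seed = 2))
  expect_false(identical(a$position, b$position))
})

test_that("peak-position jitter has the configured standard deviation", {
  pk <- peakList("h1", position = 5, intensity = 1, width = 0.02)
  shifts <- vapply(seq_len(1000), function(i)
    augmentH1(pk, augmentConfig(jitter = 0.02, broadening = 0, noise = 0,
                                drift = 0, seed = i))$position,
    numeric(1))
  expect_equal(sd(shifts - 5), 0.02, tolerance = 0.1)
})

test_that("normalized vectors stay in [0,1] across random peak lists", {
  for (k in 1:10) {
    set.seed(k)
    pk <- peakList("h1", position = runif(5, -2, 10),
                   intensity = runif(5, 0, 10), width = runif(5, 0, 0.1))
    v <- spectrumValues(vectorizeH1(pk))
    expect_true(min(v) >= 0 && max(v) <= 1)
  }
})
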