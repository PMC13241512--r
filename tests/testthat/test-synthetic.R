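## Synthetic chemistry: corpus generation, formulas, rule-based spectra.

## independent valence-based oracle: count atoms from the SMILES via the
## OpenBabel formula string, H completed by default valences
oracleFormula <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  f <- suppressWarnings(ChemmineR::propOB(sdf))$formula
  parseFormula(f)
}

test_that("molecular formulas include implicit hydrogens", {
  expect_equal(molecularFormula("CCO"), c(C = 2L, H = 6L, O = 1L))
  expect_equal(molecularFormula("C"), c(C = 1L, H = 4L))
  expect_equal(molecularFormula("c1ccccc1"), c(C = 6L, H = 6L))
  for (s in c("CC(=O)OC", "Clc1ccccc1", "N#CCO", "CC(N)C(=O)O"))
    expect_equal(molecularFormula(s), oracleFormula(s), info = s)
})

test_that("formula strings round-trip through the parser", {
  f <- molecularFormula("CC(=O)Nc1ccccc1")
  expect_equal(parseFormula(SpectraMol:::formulaToString(f)), f)
  expect_equal(parseFormula("C6H5Cl"), c(C = 6L, H = 5L, Cl = 1L))
})

test_that("corpus generation yields n distinct valid molecules within caps", {
  corp <- generateCorpus(60, maxHeavyAtoms = 15, seed = 42)
  expect_equal(nrow(corp), 60L)
  expect_equal(anyDuplicated(corp$smiles), 0L)
  expect_true(all(corp$heavyAtoms <= 15))
  expect_true(all(corp$heavyAtoms >= 3))
  # canonicalize-and-dedupe oracle: re-canonicalization is a fixed point
  recan <- vapply(corp$smiles[1:10], function(s)
    as.character(suppressWarnings(
      ChemmineR::propOB(ChemmineR::smiles2sdf(s)))$cansmi), "")
  expect_equal(unname(recan), corp$smiles[1:10])
  # element caps of the target chemical space
  for (i in seq_len(nrow(corp))) {
    f <- parseFormula(corp$formula[i])
    for (e in c("O", "N", "Cl"))
      expect_lte(if (e %in% names(f)) f[[e]] else 0L, 5L)
    expect_true(f[["H"]] >= 4 && f[["H"]] <= 42)
  }
})

test_that("corpus generation is deterministic given the seed", {
  a <- generateCorpus(20, seed = 7)
  b <- generateCorpus(20, seed = 7)
  expect_identical(a, b)
  c <- generateCorpus(20, seed = 8)
  expect_false(identical(a$smiles, c$smiles))
})

test_that("tiny enumerable request succeeds and infeasible request fails", {
  one <- generateCorpus(1, maxHeavyAtoms = 3, palette = "C", seed = 1)
  expect_equal(nrow(one), 1L)
  g <- SpectraMol:::graphFromSmiles(one$smiles)
  expect_true(SpectraMol:::graphValid(g))
  expect_error(generateCorpus(50, maxHeavyAtoms = 3, palette = "C",
                              seed = 1), "molecules")
})

test_that("13C peak counts equal carbon symmetry classes", {
  expect_equal(nrow(simulatePeaks("c1ccccc1", "c13")$c13), 1L)
  expect_equal(nrow(simulatePeaks("CCO", "c13")$c13), 2L)
  # oracle: para-xylene has 3 distinct carbons
  expect_equal(nrow(simulatePeaks("Cc1ccc(C)cc1", "c13")$c13), 3L)
})

test_that("1H intensities are proportional to hydrogen counts", {
  h1 <- simulatePeaks("CCO", "h1")$h1
  expect_equal(sort(h1$intensity), c(1, 2, 3))  # OH : CH2 : CH3
  benz <- simulatePeaks("c1ccccc1", "h1")$h1
  expect_equal(benz$intensity, 6)
})

test_that("spectrum simulation is a pure function of structure and seed", {
  a <- simulateSpectra("CC(=O)O", c("c13", "h1"), seed = 3, augment = TRUE)
  b <- simulateSpectra("CC(=O)O", c("c13", "h1"), seed = 3, augment = TRUE)
  expect_identical(spectrumValues(a[["h1"]]), spectrumValues(b[["h1"]]))
  c <- simulateSpectra("CC(=O)O", c("c13", "h1"), seed = 4, augment = TRUE)
  expect_false(identical(spectrumValues(a[["h1"]]),
                         spectrumValues(c[["h1"]])))
})

test_that("molecules without the probed nuclei give valid empty spectra", {
  # tetrachloromethane has no hydrogens: empty 1H peaks, all-zero vector
  pk <- simulatePeaks("ClC(Cl)(Cl)Cl", c("h1", "hsqc"))
  expect_equal(nrow(pk$h1), 0L)
  expect_equal(nrow(pk$hsqc), 0L)
  ss <- simulateSpectra("ClC(Cl)(Cl)Cl", c("h1", "hsqc"))
  expect_equal(sum(spectrumValues(ss[["h1"]])), 0)
  expect_equal(sum(spectrumValues(ss[["hsqc"]])), 0)
})

test_that("different molecules are pairwise distinguishable by 13C patterns", {
  corp <- generateCorpus(80, seed = 13)
  keys <- vapply(corp$smiles, function(s) {
    pk <- simulatePeaks(s, "c13")$c13
    paste(sort(round(pk$position, 2)), collapse = ",")
  }, "")
  n <- length(keys)
  pairs <- combn(n, 2)
  distinct <- mean(keys[pairs[1, ]] != keys[pairs[2, ]])
  expect_gte(distinct, 0.95)
})

test_that("corpus export writes SMILES, SDF, spectra and manifest", {
  dir <- withr::local_tempdir()
  corp <- generateCorpus(3, seed = 2)
  mf <- writeCorpus(corp, dir, modalities = c("c13", "h1"))
  expect_true(file.exists(file.path(dir, "corpus.smi")))
  expect_true(file.exists(file.path(dir, "corpus.sdf")))
  man <- jsonlite::read_json(mf)
  expect_equal(length(man), 3L)
  expect_true(file.exists(file.path(dir, man[[1]]$spectra$c13)))
})
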