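## Formula pools, fused scoring and ranking against brute-force oracles.

unitRows <- function(M) M / sqrt(rowSums(M^2))

fakeIndex <- function(smiles, formulas, E) {
  new("MoleculeIndex",
      molecules = data.frame(id = sprintf("M%03d", seq_along(smiles)),
                             smiles = smiles, stringsAsFactors = FALSE),
      formulas = lapply(formulas, parseFormula),
      embeddings = E, provenance = "test")
}

test_that("formula pool keeps exact matches at tolerance 0", {
  E <- unitRows(matrix(rnorm(2 * 8), 2, 8))
  idx <- fakeIndex(c("CCO", "c1ccccc1"), c("C2H6O", "C6H6"), E)
  pool <- formulaPool(idx, "C2H6O")
  expect_equal(indexMolecules(pool)$smiles, "CCO")
  # huge tolerance keeps the whole index
  all <- formulaPool(idx, "C2H6O", tolerance = 100)
  expect_equal(nrow(indexMolecules(all)), 2L)
  none <- formulaPool(idx, "C10H22")
  expect_equal(nrow(indexMolecules(none)), 0L)
})

test_that("formula pool membership matches a brute-force per-element tally", {
  corp <- generateCorpus(20, seed = 17)
  E <- unitRows(matrix(rnorm(20 * 8), 20, 8))
  idx <- fakeIndex(corp$smiles, corp$formula, E)
  target <- parseFormula(corp$formula[7])
  pool <- formulaPool(idx, target, tolerance = 2)
  brute <- vapply(corp$formula, function(fs) {
    f <- parseFormula(fs)
    els <- union(names(f), names(target))
    d <- sum(vapply(els, function(e) {
      a <- if (e %in% names(f)) f[[e]] else 0L
      b <- if (e %in% names(target)) target[[e]] else 0L
      abs(a - b)
    }, numeric(1)))
    d <= 2
  }, logical(1))
  expect_setequal(indexMolecules(pool)$smiles, corp$smiles[brute])
})

test_that("fused score is the mean of per-modality cosines", {
  d <- 8
  m <- rnorm(d); m <- m / sqrt(sum(m^2))
  expect_equal(fusedScore(list(c13 = m), m), 1, tolerance = 1e-12)
  # construct embeddings with prescribed cosines 0.8 and 0.6 to m
  mk <- function(target) {
    o <- rnorm(d); o <- o - sum(o * m) * m; o <- o / sqrt(sum(o^2))
    target * m + sqrt(1 - target^2) * o
  }
  e1 <- mk(0.8); e2 <- mk(0.6)
  expect_equal(fusedScore(list(a = e1, b = e2), m), 0.7, tolerance = 1e-9)
  # single modality equals that modality's cosine
  expect_equal(fusedScore(list(a = e1), m), 0.8, tolerance = 1e-9)
  # permutation invariance and min/max bounds
  expect_equal(fusedScore(list(b = e2, a = e1), m),
               fusedScore(list(a = e1, b = e2), m))
  s <- fusedScore(list(a = e1, b = e2), m)
  expect_true(s >= 0.6 - 1e-9 && s <= 0.8 + 1e-9)
  expect_error(fusedScore(list(), m), "modalities")
})

test_that("self-retrieval ranks the true molecule first", {
  d <- 16
  E <- unitRows(diag(5)[, rep(1:5, length.out = d)] +
                matrix(0, 5, d))
  # orthogonal-ish rows: use an explicit orthonormal set
  E <- diag(5)
  E <- cbind(E, matrix(0, 5, d - 5))
  idx <- fakeIndex(sprintf("C%s", strrep("C", 1:5)),
                   sprintf("C%dH%d", 1:5, 2 * (1:5) + 2), E)
  q <- list(c13 = E[3, ])
  res <- rankCandidates(idx, q, truth = indexMolecules(idx)$smiles[3])
  expect_equal(attr(res, "trueRank"), 1L)
  expect_equal(res$smiles[1], indexMolecules(idx)$smiles[3])
})

test_that("ranking equals a brute-force sort of pairwise cosines", {
  set.seed(12)
  n <- 20; d <- 8
  E <- unitRows(matrix(rnorm(n * d), n, d))
  smiles <- sprintf("S%02d", 1:n)
  idx <- fakeIndex(smiles, rep("C2H6O", n), E)
  q <- list(a = unitRows(matrix(rnorm(d), 1, d))[1, ],
            b = unitRows(matrix(rnorm(d), 1, d))[1, ])
  res <- rankCandidates(idx, q)
  brute <- (E %*% q$a + E %*% q$b) / 2
  expect_equal(res$smiles, smiles[order(-brute, smiles)])
  expect_equal(res$score, sort(brute, decreasing = TRUE)[
    rank(-res$score, ties.method = "first")], tolerance = 1e-12)
  # scores are non-increasing
  expect_true(all(diff(res$score) <= 1e-12))
  # dimension mismatch is rejected
  expect_error(rankCandidates(idx, list(a = rnorm(5))), "dimension")
})

test_that("ties break by canonical SMILES ascending", {
  E <- matrix(rep(c(1, 0), each = 3), 3, 2)[, 1:2]
  E <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE)
  idx <- fakeIndex(c("ZZZ", "AAA", "MMM"), rep("C2H6O", 3), E)
  res <- rankCandidates(idx, list(a = c(1, 0)))
  expect_equal(res$smiles, c("AAA", "MMM", "ZZZ"))
})

test_that("adding a perfectly matching modality never hurts the truth", {
  set.seed(5)
  n <- 15; d <- 8
  E <- unitRows(matrix(rnorm(n * d), n, d))
  idx <- fakeIndex(sprintf("S%02d", 1:n), rep("C2H6O", n), E)
  truth <- 4L
  q1 <- list(a = unitRows(matrix(rnorm(d), 1, d))[1, ])
  r1 <- rankCandidates(idx, q1, truth = sprintf("S%02d", truth))
  # second modality: cosine 1 to the truth, <= its cosine to competitors
  q2 <- c(q1, list(b = E[truth, ]))
  r2 <- rankCandidates(idx, q2, truth = sprintf("S%02d", truth))
  expect_lte(attr(r2, "trueRank"), attr(r1, "trueRank"))
})

test_that("top-k accuracy counts nested rank events", {
  mkres <- function(rank) structure(data.frame(), trueRank = rank)
  m <- rankMetrics(list(mkres(1L), mkres(2L), mkres(6L)))
  expect_equal(unname(m$topk["top1"]), 1 / 3)
  expect_equal(unname(m$topk["top5"]), 2 / 3)
  expect_equal(unname(m$topk["top20"]), 1)
  expect_true(all(diff(m$topk) >= 0))
  all1 <- rankMetrics(list(mkres(1L), mkres(1L)))
  expect_equal(unname(all1$topk["top1"]), 1)
})
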