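## Reward identities, GA operator validity, elitism monotonicity, and
## aggregation against a brute-force oracle.

test_that("reward identities hold exactly", {
  d <- 8
  m <- rnorm(d); m <- m / sqrt(sum(m^2))
  mk <- function(target) {
    o <- rnorm(d); o <- o - sum(o * m) * m; o <- o / sqrt(sum(o^2))
    target * m + sqrt(1 - target^2) * o
  }
  # all cosines 1, W = 0 -> R = 1
  rb <- new("RewardBreakdown", cosines = c(c13 = 1, h1 = 1), W = 0,
            T_ = 12, R = 1)
  expect_equal(rb@R, 1)
  # cosines (0.8, 0.6), W = 3, T = 12 -> R = 0.7 - 0.25 = 0.45
  rb2 <- new("RewardBreakdown", cosines = c(a = 0.8, b = 0.6), W = 3,
             T_ = 12, R = 0.45)
  expect_equal(rb2@R, 0.45)
  # the class enforces the identity R = mean(cos) - W/T
  expect_error(new("RewardBreakdown", cosines = c(a = 0.8), W = 0, T_ = 12,
                   R = 0.5), "mean")
  # single modality, W = 0 -> R equals that cosine
  rb3 <- new("RewardBreakdown", cosines = c(h1 = 0.9), W = 0, T_ = 10,
             R = 0.9)
  expect_equal(rb3@R, 0.9)
})

test_that("reward() computes R from embeddings and formulas", {
  model <- buildModel(
    encoderConfig(d = 8, c13Hidden = 8, fcHidden = 8, molDim = 8,
                  molLayers = 1, molFF = 8,
                  codec = codecConfig(c13Len = 16, h1Len = 200, irLen = 120,
                                      hsqcDim = 32), seed = 1),
    c("CCO", "CCC", "c1ccccc1"))
  em <- encode(model, "CCO")
  # the candidate scored against its own embedding with its own formula
  rb <- reward("CCO", list(c13 = em), "C2H6O", model)
  expect_equal(rb@R, 1, tolerance = 1e-9)
  expect_equal(rb@W, 0)
  expect_equal(rb@T_, 9)
  # wrong formula: penalty subtracts W/T; R = cos - W/T may be negative
  rb2 <- reward("CCO", list(c13 = em), "C6H6", model)
  expect_equal(rb2@W, unname(wrongAtomCount("C2H6O", "C6H6")["W"]))
  expect_equal(rb2@R, mean(rb2@cosines) - rb2@W / rb2@T_, tolerance = 1e-12)
  expect_lte(rb2@R, 1)
})

test_that("mutation operators produce valid connected structures", {
  set.seed(23)
  for (smi in c("CCO", "c1ccccc1", "CC(=O)OC", "ClCC(N)C=O")) {
    g <- SpectraMol:::graphFromSmiles(smi)
    for (k in 1:25) {
      g2 <- SpectraMol:::mutateGraph(g)
      if (!is.null(g2))
        expect_true(SpectraMol:::graphValid(g2, 15), label = smi)
    }
  }
})

test_that("crossover children are valid and inherit fragments", {
  set.seed(31)
  ga <- SpectraMol:::graphFromSmiles("CCOC(=O)C")
  gb <- SpectraMol:::graphFromSmiles("NCCc1ccccc1")
  kids <- 0
  for (k in 1:40) {
    ch <- SpectraMol:::crossoverGraphs(ga, gb, 20)
    if (!is.null(ch)) {
      kids <- kids + 1
      expect_true(SpectraMol:::graphValid(ch, 20))
    }
  }
  expect_gt(kids, 10)
})

test_that("elitist survivor selection makes best reward non-decreasing", {
  set.seed(2)
  target <- morganFingerprint("CCOC(=O)c1ccccc1", radius = 2)
  rew <- function(smi) vapply(smi, function(s) {
    fp <- morganFingerprint(s, radius = 2)
    sum(fp & target) / max(1, sum(fp | target))
  }, numeric(1))
  pop <- evolve(c("CCO", "CCC", "c1ccccc1"), rew,
                gaConfig(populationSize = 20, offspring = 30,
                         generations = 6), seed = 9)
  tr <- attr(pop, "trace")
  expect_true(all(diff(tr$best) >= 0))
  expect_true(all(pop$R[order(-pop$R)] == pop$R))
})

test_that("GA runs are deterministic given the seed", {
  rew <- function(smi) -abs(nchar(smi) - 8)
  a <- evolve("CCO", rew, gaConfig(populationSize = 10, offspring = 15,
                                   generations = 3), seed = 4)
  b <- evolve("CCO", rew, gaConfig(populationSize = 10, offspring = 15,
                                   generations = 3), seed = 4)
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$R, b$R)
})

test_that("aggregation matches the brute-force union-sort oracle", {
  set.seed(44)
  runs <- lapply(1:3, function(k) {
    smi <- sample(sprintf("MOL%02d", 1:15), 10)
    data.frame(smiles = smi, R = round(runif(10), 3),
               provenance = sample(c("retrieved", "generated"), 10,
                                   replace = TRUE),
               stringsAsFactors = FALSE)
  })
  agg <- aggregateRuns(runs)
  tb <- rankingTable(agg)
  all <- do.call(rbind, runs)
  bruteBest <- tapply(all$R, all$smiles, max)
  bruteOrder <- names(bruteBest)[order(-bruteBest, names(bruteBest))]
  expect_equal(tb$smiles, bruteOrder)
  expect_equal(tb$score, as.numeric(bruteBest[tb$smiles]))
  expect_equal(anyDuplicated(tb$smiles), 0L)
  expect_true(all(diff(tb$score) <= 0))
})

test_that("duplicate candidates keep their best reward across seeds", {
  runs <- list(
    data.frame(smiles = c("A", "B"), R = c(0.6, 0.2),
               provenance = "generated", stringsAsFactors = FALSE),
    data.frame(smiles = c("A", "C"), R = c(0.7, 0.5),
               provenance = "generated", stringsAsFactors = FALSE))
  tb <- rankingTable(aggregateRuns(runs))
  expect_equal(tb$score[tb$smiles == "A"], 0.7)
  expect_equal(nrow(tb), 3L)
  # single run: ranking is that population sorted
  one <- aggregateRuns(runs[2])
  expect_equal(rankingTable(one)$smiles, c("A", "C"))
})

test_that("match flags appear when a reference is supplied", {
  runs <- list(data.frame(smiles = c("CCO", "CCC"), R = c(0.9, 0.1),
                          provenance = "generated",
                          stringsAsFactors = FALSE))
  tb <- rankingTable(aggregateRuns(runs, reference = "OCC"))
  expect_true(tb$fpMatch[tb$smiles == "CCO"])
  expect_true(tb$exactMatch[tb$smiles == "CCO"])
  expect_false(tb$fpMatch[tb$smiles == "CCC"])
})
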