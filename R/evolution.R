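## Graph genetic algorithm refinement. Candidates are molecular graphs
## evolved by atom/bond/fragment edits and fragment-recombination crossover;
## fitness is the multimodal embedding similarity minus the molecular-
## formula penalty W/T. Invalid offspring (valence, connectivity) are
## discarded; formula violations are penalized, not filtered, so the GA can
## explore compositions around the target.

#' Wrong-atom count against a target formula
#'
#' `W` is the summed per-element absolute count difference between the
#' candidate and the target formula (hydrogens included); `T` is the total
#' atom count of the target.
#'
#' @param candidate,target named count vectors or formula strings.
#' @return named numeric vector `c(W, T)`.
#' @export
wrongAtomCount <- function(candidate, target) {
  if (is.character(candidate)) candidate <- parseFormulaString(candidate)
  if (is.character(target)) target <- parseFormulaString(target)
  if (sum(candidate) < 1 || sum(target) < 1)
    stop("formulas must be non-empty")
  c(W = formulaDistance(candidate, target), T = sum(target))
}

#' GA reward with formula penalty
#'
#' `R = mean(cos) - W/T`: the mean cosine similarity between the candidate
#' molecule's embedding and the query's 1-4 spectrum embeddings, minus the
#' wrong-atom fraction. Equals the fused retrieval score exactly when the
#' candidate has the target composition (W = 0); can be negative.
#'
#' @param candidate candidate SMILES.
#' @param spectrumEmbeddings named list of per-modality embeddings.
#' @param targetFormula named counts or formula string of the query.
#' @param model a trained `specmolModel`.
#' @return a [RewardBreakdown].
#' @export
reward <- function(candidate, spectrumEmbeddings, targetFormula, model) {
  emb <- encodeMatrix(model, "molecule", candidate)[1, ]
  cosines <- vapply(spectrumEmbeddings, function(e) {
    v <- if (is(e, "EmbeddingVector")) e@values else as.numeric(e)
    cosineSim(v, emb)
  }, numeric(1))
  wt <- wrongAtomCount(molecularFormula(candidate), targetFormula)
  new("RewardBreakdown", cosines = cosines, W = wt[["W"]], T_ = wt[["T"]],
      R = mean(cosines) - wt[["W"]] / wt[["T"]])
}

#' Genetic-algorithm configuration
#'
#' @param populationSize survivors kept per generation (default 100).
#' @param offspring children generated per generation (default 200).
#' @param mutationRate probability that a crossover child is additionally
#'   mutated; mutation-only children are produced when crossover fails.
#' @param generations number of generations per run (default 15).
#' @param seeds number of independent GA runs to aggregate (default 3).
#' @param elitism minimum number of best candidates carried over unchanged
#'   (>= 1; survivor selection is elitist, so the best reward is
#'   non-decreasing).
#' @param crossoverRate fraction of offspring produced by crossover.
#' @param maxHeavyAtoms heavy-atom cap for offspring.
#' @return list of class `gaConfig`.
#' @export
gaConfig <- function(populationSize = 100L, offspring = 200L,
                     mutationRate = 0.05, generations = 15L, seeds = 3L,
                     elitism = 5L, crossoverRate = 0.7,
                     maxHeavyAtoms = 15L) {
  stopifnot(generations >= 1, seeds >= 1, elitism >= 1, populationSize >= 1)
  structure(list(populationSize = as.integer(populationSize),
                 offspring = as.integer(offspring),
                 mutationRate = mutationRate,
                 generations = as.integer(generations),
                 seeds = as.integer(seeds), elitism = as.integer(elitism),
                 crossoverRate = crossoverRate,
                 maxHeavyAtoms = as.integer(maxHeavyAtoms)),
            class = "gaConfig")
}

## ---- graph edit operators ----------------------------------------------

freeValences <- function(g) ELEMENT_VALENCE[g$elem] - bondOrderSums(g)

## ring-bond flags with memoization: population graphs are immutable, so
## evolve() attaches the flags once and the operators reuse them
ringFlagsOf <- function(g) {
  f <- attr(g, "ringFlags")
  if (is.null(f)) ringBondFlags(g) else f
}

withRingFlags <- function(g) {
  attr(g, "ringFlags") <- ringBondFlags(g)
  g
}

## one random structural edit; returns an edited graph or NULL
mutateGraph <- function(g, palette = c("C", "O", "N", "Cl"),
                        maxHeavy = 15L) {
  ops <- sample(c("element", "addAtom", "delAtom", "bondOrder", "addBond",
                  "delBond"))
  fv <- freeValences(g)
  for (op in ops) {
    g2 <- switch(op,
      element = {
        i <- sample(length(g$elem), 1)
        bs <- bondOrderSums(g)[i]
        alts <- setdiff(palette[ELEMENT_VALENCE[palette] >= bs], g$elem[i])
        if (!length(alts)) NULL else {
          gg <- g; gg$elem[i] <- if (length(alts) == 1) alts else
            sample(alts, 1)
          gg
        }
      },
      addAtom = {
        hosts <- which(fv >= 1)
        if (!length(hosts) || length(g$elem) >= maxHeavy) NULL else {
          gg <- g
          host <- if (length(hosts) == 1) hosts else sample(hosts, 1)
          gg$elem <- c(gg$elem, sample(palette, 1))
          gg$bonds <- rbind(gg$bonds, c(host, length(gg$elem), 1))
          gg
        }
      },
      delAtom = {
        deg <- vapply(adjacency(g), nrow, 0L)
        term <- which(deg == 1)
        if (!length(term) || length(g$elem) <= 2) NULL else {
          i <- if (length(term) == 1) term else sample(term, 1)
          gg <- g
          keep <- setdiff(seq_along(g$elem), i)
          map <- match(seq_along(g$elem), keep)
          gg$elem <- gg$elem[keep]
          b <- gg$bonds[gg$bonds[, 1] != i & gg$bonds[, 2] != i, ,
                        drop = FALSE]
          b[, 1] <- map[b[, 1]]; b[, 2] <- map[b[, 2]]
          gg$bonds <- b
          gg
        }
      },
      bondOrder = {
        if (!nrow(g$bonds)) NULL else {
          i <- sample(nrow(g$bonds), 1)
          gg <- g
          a <- g$bonds[i, 1]; b <- g$bonds[i, 2]
          up <- g$bonds[i, 3] < 3 && fv[a] >= 1 && fv[b] >= 1
          down <- g$bonds[i, 3] > 1
          if (up && (!down || runif(1) < 0.5))
            gg$bonds[i, 3] <- gg$bonds[i, 3] + 1
          else if (down) gg$bonds[i, 3] <- gg$bonds[i, 3] - 1
          else gg <- NULL
          gg
        }
      },
      addBond = {
        cand <- which(fv >= 1)
        if (length(cand) < 2) NULL else {
          pair <- sample(cand, 2)
          key <- paste(pmin(g$bonds[, 1], g$bonds[, 2]),
                       pmax(g$bonds[, 1], g$bonds[, 2]))
          if (paste(min(pair), max(pair)) %in% key) NULL else {
            gg <- g
            gg$bonds <- rbind(gg$bonds, c(pair[1], pair[2], 1))
            gg
          }
        }
      },
      delBond = {
        rb <- which(ringFlagsOf(g))
        if (!length(rb)) NULL else {
          i <- if (length(rb) == 1) rb else sample(rb, 1)
          gg <- g
          gg$bonds <- gg$bonds[-i, , drop = FALSE]
          gg
        }
      })
    if (!is.null(g2) && graphValid(g2, maxHeavy)) {
      attr(g2, "ringFlags") <- NULL    # edits invalidate cached flags
      return(g2)
    }
  }
  NULL
}

## split a graph at a random non-ring single bond; returns the two atom
## sets and the cut endpoints, or NULL if no cuttable bond exists
cutGraph <- function(g) {
  flags <- ringFlagsOf(g)
  cuttable <- which(!flags & g$bonds[, 3] == 1)
  if (!length(cuttable)) return(NULL)
  i <- if (length(cuttable) == 1) cuttable else sample(cuttable, 1)
  a <- g$bonds[i, 1]; b <- g$bonds[i, 2]
  g2 <- g; g2$bonds <- g$bonds[-i, , drop = FALSE]
  adj <- adjacency(g2)
  seen <- logical(length(g$elem)); seen[a] <- TRUE; queue <- a
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    nb <- adj[[x]][, 1]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  list(sideA = which(seen), sideB = which(!seen), cutA = a, cutB = b)
}

extractFragment <- function(g, atoms, attach) {
  map <- match(seq_along(g$elem), atoms)
  keep <- g$bonds[g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms, ,
                  drop = FALSE]
  keep[, 1] <- map[keep[, 1]]; keep[, 2] <- map[keep[, 2]]
  list(g = molGraph(g$elem[atoms], keep), attach = map[attach])
}

## fragment-recombination crossover: one fragment from each parent joined
## at the cut attachment points by a single bond
crossoverGraphs <- function(ga, gb, maxHeavy = 15L) {
  ca <- cutGraph(ga); cb <- cutGraph(gb)
  if (is.null(ca) || is.null(cb)) return(NULL)
  fa <- local({
    side <- if (runif(1) < 0.5) ca$sideA else ca$sideB
    att <- if (ca$cutA %in% side) ca$cutA else ca$cutB
    extractFragment(ga, side, att)
  })
  fb <- local({
    side <- if (runif(1) < 0.5) cb$sideA else cb$sideB
    att <- if (cb$cutA %in% side) cb$cutA else cb$cutB
    extractFragment(gb, side, att)
  })
  na <- length(fa$g$elem)
  child <- molGraph(c(fa$g$elem, fb$g$elem),
                    rbind(fa$g$bonds,
                          cbind(fb$g$bonds[, 1, drop = FALSE] + na,
                                fb$g$bonds[, 2, drop = FALSE] + na,
                                fb$g$bonds[, 3, drop = FALSE]),
                          c(fa$attach, fb$attach + na, 1)))
  if (graphValid(child, maxHeavy)) child else NULL
}

## ---- GA driver ----------------------------------------------------------

## batched reward evaluation for a vector of SMILES; `graphs` (parallel
## list of molgraphs) avoids re-parsing when the caller already has them
rewardBatch <- function(smilesVec, spectrumEmbeddings, targetFormula,
                        model, graphs = NULL) {
  S <- do.call(rbind, lapply(spectrumEmbeddings, function(e)
    if (is(e, "EmbeddingVector")) e@values else as.numeric(e)))
  E <- encodeMatrix(model, "molecule", smilesVec)
  cosMean <- rowMeans(tcrossprod(E, S))
  wt <- if (is.null(graphs))
    vapply(smilesVec, function(s)
      wrongAtomCount(molecularFormula(s), targetFormula), numeric(2))
  else
    vapply(graphs, function(g)
      wrongAtomCount(molecularFormula(g), targetFormula), numeric(2))
  cosMean - wt[1, ] / wt[2, ]
}

#' Evolve a candidate population under the reward
#'
#' Runs the configured number of generations. Each generation selects
#' parents with probability proportional to their reward rank, produces
#' offspring by fragment crossover and structural mutations, discards
#' invalid structures, and keeps the best `populationSize` of parents plus
#' offspring (elitist survivor selection, deduplicated by canonical
#' SMILES), so the best reward never decreases. Deterministic given `seed`.
#'
#' @param initial character vector of seed SMILES (non-empty).
#' @param rewardFn function(character vector of SMILES) -> numeric rewards.
#' @param config a [gaConfig].
#' @param seed integer RNG seed for this run.
#' @param palette heavy-element palette for mutations.
#' @return data.frame `smiles`, `R`, `provenance`, plus a `trace`
#'   attribute with per-generation best/mean reward.
#' @export
evolve <- function(initial, rewardFn, config = gaConfig(), seed = 1L,
                   palette = c("C", "O", "N", "Cl")) {
  stopifnot(length(initial) >= 1)
  rew <- if (length(formals(rewardFn)) >= 2) rewardFn
         else function(smi, gr) rewardFn(smi)
  withSeed(seed, {
    can <- unique(canonicalSmiles(initial))
    graphs <- lapply(can, graphFromSmiles)
    ok <- vapply(graphs, function(g) graphValid(g, config$maxHeavyAtoms),
                 logical(1))
    if (!any(ok)) stop("no valid structures in the initial population")
    graphs <- lapply(graphs[ok], withRingFlags)
    pop <- data.frame(smiles = can[ok], stringsAsFactors = FALSE)
    pop$R <- rew(pop$smiles, graphs)
    pop$provenance <- "retrieved"
    # a short initial population is padded with mutated copies up to the
    # population size, so cold starts still explore a full first generation
    if (nrow(pop) < config$populationSize) {
      padG <- list(); tries <- 0L
      while (nrow(pop) + length(padG) < config$populationSize &&
             tries < 20L * config$populationSize) {
        tries <- tries + 1L
        src <- graphs[[sample(length(graphs), 1)]]
        g2 <- mutateGraph(src, palette, config$maxHeavyAtoms)
        if (!is.null(g2)) padG[[length(padG) + 1L]] <- g2
      }
      if (length(padG)) {
        padSmi <- obProps(padG)$cansmi
        newIdx <- !is.na(padSmi) & padSmi != "" &
                  !(padSmi %in% pop$smiles) & !duplicated(padSmi)
        if (any(newIdx)) {
          pop <- rbind(pop, data.frame(smiles = padSmi[newIdx],
                                       R = rew(padSmi[newIdx],
                                               padG[newIdx]),
                                       provenance = "generated",
                                       stringsAsFactors = FALSE))
          graphs <- c(graphs, lapply(padG[newIdx], withRingFlags))
        }
      }
    }
    trace <- data.frame(generation = 0L, best = max(pop$R),
                        mean = mean(pop$R))
    for (gen in seq_len(config$generations)) {
      n <- nrow(pop)
      rk <- rank(pop$R, ties.method = "first")
      pSel <- rk / sum(rk)
      children <- list()
      attempts <- 0L
      while (length(children) < config$offspring &&
             attempts < 10L * config$offspring) {
        attempts <- attempts + 1L
        child <- NULL
        if (runif(1) < config$crossoverRate && n >= 2) {
          pr <- sample(n, 2, prob = pSel)
          child <- crossoverGraphs(graphs[[pr[1]]], graphs[[pr[2]]],
                                   config$maxHeavyAtoms)
          if (!is.null(child) && runif(1) < config$mutationRate)
            child <- mutateGraph(child, palette, config$maxHeavyAtoms) %||%
              child
        } else {
          pr <- sample(n, 1, prob = pSel)
          child <- mutateGraph(graphs[[pr]], palette, config$maxHeavyAtoms)
        }
        if (!is.null(child) && graphValid(child, config$maxHeavyAtoms))
          children[[length(children) + 1L]] <- child
      }
      if (!length(children)) {
        logMsg("generation %d: all offspring invalid; carrying population over",
               gen)
        trace <- rbind(trace, data.frame(generation = gen,
                                         best = max(pop$R),
                                         mean = mean(pop$R)))
        next
      }
      childSmi <- obProps(children)$cansmi
      new <- !(childSmi %in% pop$smiles) & !duplicated(childSmi) &
             !is.na(childSmi) & childSmi != ""
      if (any(new)) {
        newSmi <- childSmi[new]
        newR <- rew(newSmi, children[new])
        pop <- rbind(pop, data.frame(smiles = newSmi, R = newR,
                                     provenance = "generated",
                                     stringsAsFactors = FALSE))
        graphs <- c(graphs, children[new])
      }
      keep <- head(order(-pop$R, pop$smiles), config$populationSize)
      pop <- pop[keep, , drop = FALSE]
      graphs <- lapply(graphs[keep], withRingFlags)
      rownames(pop) <- NULL
      trace <- rbind(trace, data.frame(generation = gen, best = max(pop$R),
                                       mean = mean(pop$R)))
    }
    attr(pop, "trace") <- trace
    pop
  })
}

#' Aggregate GA runs into a final candidate ranking
#'
#' Union of all populations across seeds, deduplicated by canonical SMILES
#' keeping each candidate's best reward, sorted by reward descending with a
#' canonical-string tie-break. Provenance is preserved ("retrieved" wins
#' over "generated" for identical structures).
#'
#' @param runs list of populations from [evolve] (or any data.frames with
#'   `smiles`, `R`, `provenance`).
#' @param reference optional SMILES of the known structure; adds
#'   fingerprint and canonical match flags.
#' @return a [CandidateRanking].
#' @export
aggregateRuns <- function(runs, reference = NULL) {
  stopifnot(length(runs) >= 1)
  all <- do.call(rbind, lapply(runs, function(r)
    r[, c("smiles", "R", "provenance"), drop = FALSE]))
  # retrieved provenance dominates; then best R first
  all <- all[order(all$smiles, all$provenance != "retrieved", -all$R), ]
  best <- tapply(all$R, all$smiles, max)
  first <- all[!duplicated(all$smiles), ]
  first$R <- as.numeric(best[first$smiles])
  ord <- order(-first$R, first$smiles)
  tb <- data.frame(smiles = first$smiles[ord], score = first$R[ord],
                   provenance = first$provenance[ord],
                   stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  if (!is.null(reference)) {
    refFp <- morganFingerprint(reference)
    refCan <- canonicalSmiles(reference)
    tb$fpMatch <- vapply(tb$smiles, function(s)
      all(morganFingerprint(s) == refFp), logical(1))
    tb$exactMatch <- tb$smiles == refCan
  }
  new("CandidateRanking", table = tb)
}
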