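## Synthetic chemistry: molecule corpora assembled from a small element
## palette, and rule-based toy spectra. The spectra are synthetic by design:
## peak positions come from fixed local-environment tables plus a
## deterministic environment-hash offset. Their only contract is consistency
## (a pure function of structure and seed) and discriminability (different
## molecules receive distinguishable peak patterns); no chemical-shift
## accuracy is claimed.

#' Molecular formula of a structure
#'
#' Element counts of the hydrogen-complete structure (implicit hydrogens
#' filled to the default valence of each neutral atom).
#'
#' @param x a SMILES string.
#' @return named integer vector of element counts, hydrogens included,
#'   ordered C, H, then alphabetically (Hill order).
#' @export
molecularFormula <- function(x) {
  g <- if (inherits(x, "molgraph")) x else graphFromSmiles(x)
  counts <- table(g$elem)
  f <- setNames(as.integer(counts), names(counts))
  hTot <- sum(implicitH(g))
  f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + as.integer(hTot)
  f <- f[f > 0]
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  f[hill]
}

#' Parse a molecular-formula string
#'
#' @param s a formula string such as `"C2H6O"`.
#' @return named integer vector of element counts.
#' @export
parseFormula <- function(s) parseFormulaString(s)

formulaToString <- function(f) {
  f <- f[f > 0]
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  paste0(vapply(hill, function(e)
    paste0(e, if (f[[e]] > 1) f[[e]] else ""), ""), collapse = "")
}

## benzene skeleton used as an aromatic seed motif
benzeneGraph <- function() {
  molGraph(rep("C", 6),
           cbind(1:6, c(2:6, 1), c(2, 1, 2, 1, 2, 1)))
}

## grow one random molecule: tree growth over the palette, then optional
## ring closures and bond-order upgrades; returns a molgraph or NULL
randomMolGraph <- function(nHeavy, palette, caps, pRing = 0.35,
                           pUnsat = 0.35) {
  freeVal <- function(g) ELEMENT_VALENCE[g$elem] - bondOrderSums(g)
  g <- if ("C" %in% palette && nHeavy >= 7 && runif(1) < 0.3)
    benzeneGraph() else molGraph("C", matrix(numeric(0), ncol = 3))
  while (length(g$elem) < nHeavy) {
    fv <- freeVal(g)
    hosts <- which(fv >= 1)
    if (!length(hosts)) break
    host <- if (length(hosts) == 1) hosts else sample(hosts, 1)
    used <- table(factor(g$elem, levels = names(caps)))
    avail <- palette[used[palette] < caps[palette]]
    if (!length(avail)) break
    w <- c(C = 0.62, O = 0.14, N = 0.12, Cl = 0.12, F = 0.06, S = 0.06,
           Br = 0.04)[avail]
    w[is.na(w)] <- 0.05
    el <- if (length(avail) == 1) avail else sample(avail, 1, prob = w)
    g$elem <- c(g$elem, el)
    g$bonds <- rbind(g$bonds, c(host, length(g$elem), 1))
  }
  if (length(g$elem) < 3) return(NULL)
  # ring closures
  for (k in seq_len(rbinom(1, 2, pRing))) {
    fv <- freeVal(g)
    cand <- which(fv >= 1)
    if (length(cand) >= 2) {
      D <- graphDistances(g)
      pairs <- which(outer(seq_along(g$elem), seq_along(g$elem), "<") &
                     D >= 2 & is.finite(D) &
                     outer(fv >= 1, fv >= 1, "&"), arr.ind = TRUE)
      if (nrow(pairs)) {
        p <- pairs[sample(nrow(pairs), 1), ]
        g$bonds <- rbind(g$bonds, c(p[1], p[2], 1))
      }
    }
  }
  # bond-order upgrades
  for (k in seq_len(rbinom(1, 3, pUnsat))) {
    fv <- freeVal(g)
    up <- which(g$bonds[, 3] < 3 &
                fv[g$bonds[, 1]] >= 1 & fv[g$bonds[, 2]] >= 1)
    if (length(up)) {
      i <- if (length(up) == 1) up else sample(up, 1)
      g$bonds[i, 3] <- g$bonds[i, 3] + 1
    }
  }
  g
}

#' Generate a synthetic molecule corpus
#'
#' Assembles `n` distinct valid molecules from a fragment grammar (random
#' tree growth with optional aromatic seed, ring closures and unsaturation)
#' over the element palette, mirroring small drug-like pools filtered to
#' C3-15 H4-42 O0-5 N0-5 Cl0-5. Structures are canonicalized and
#' deduplicated; generation is deterministic given the seed.
#'
#' @param n number of distinct molecules.
#' @param maxHeavyAtoms heavy-atom cap per molecule (default 15).
#' @param palette heavy-element palette (default C, O, N, Cl; hydrogens are
#'   implicit).
#' @param seed integer RNG seed.
#' @param minHeavyAtoms lower bound on heavy atoms (default 3).
#' @return data.frame with columns `id`, `smiles`, `heavyAtoms`, `formula`.
#' @export
generateCorpus <- function(n, maxHeavyAtoms = 15L,
                           palette = c("C", "O", "N", "Cl"), seed = 1L,
                           minHeavyAtoms = 3L) {
  stopifnot(n >= 1)
  caps <- setNames(rep(5L, length(ELEMENT_VALENCE)), names(ELEMENT_VALENCE))
  caps["C"] <- maxHeavyAtoms
  withSeed(seed, {
    seen <- character(0)
    rows <- list()
    tries <- 0L; maxTries <- 50L * n + 2000L
    stagnant <- 0L
    while (length(seen) < n) {
      nBefore <- length(seen)
      batchN <- min(max(16L, n - length(seen)), 512L)
      graphs <- list()
      while (length(graphs) < batchN && tries < maxTries) {
        tries <- tries + 1L
        nh <- sample(minHeavyAtoms:maxHeavyAtoms, 1)
        g <- randomMolGraph(nh, palette, caps)
        if (is.null(g)) next
        if (!graphValid(g, maxHeavyAtoms)) next
        f <- molecularFormula(g)
        hN <- if ("H" %in% names(f)) f[["H"]] else 0L
        if (hN < 4 || hN > 42) next
        graphs[[length(graphs) + 1L]] <- g
      }
      if (!length(graphs)) break
      can <- obProps(graphs)$cansmi
      for (i in seq_along(graphs)) {
        if (length(seen) >= n) break
        if (is.na(can[i]) || can[i] == "" || can[i] %in% seen) next
        # re-parse the canonical form to guard against exotic output
        g2 <- tryCatch(graphFromSmiles(can[i]), error = function(e) NULL)
        if (is.null(g2) || !graphValid(g2, maxHeavyAtoms)) next
        seen <- c(seen, can[i])
        rows[[length(rows) + 1L]] <- data.frame(
          smiles = can[i], heavyAtoms = length(g2$elem),
          formula = formulaToString(molecularFormula(g2)),
          stringsAsFactors = FALSE)
      }
      stagnant <- if (length(seen) > nBefore) 0L else stagnant + 1L
      if ((tries >= maxTries || stagnant >= 3L) && length(seen) < n)
        stop(sprintf("could not assemble %d distinct molecules (got %d); ",
                     n, length(seen)),
             "constraints may be infeasible for this palette")
    }
    if (length(seen) < n)
      stop("corpus generation exhausted without reaching n molecules")
    out <- do.call(rbind, rows)
    out <- cbind(id = sprintf("M%04d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

## ---- rule-based spectrum simulation -------------------------------------

## neighbor feature summary for one atom
atomFeatures <- function(g, adj, hs, ring, i, arom = NULL) {
  nb <- adj[[i]]
  el <- if (nrow(nb)) g$elem[nb[, 1]] else character(0)
  or <- if (nrow(nb)) nb[, 2] else numeric(0)
  list(dblO = any(el == "O" & or == 2), trpN = any(el == "N" & or == 3),
       dblC = any(el == "C" & or == 2), trpC = any(el == "C" & or == 3),
       sglO = sum(el == "O" & or == 1), sglN = sum(el == "N" & or == 1),
       nCl = sum(el == "Cl"), nC = sum(el == "C"),
       arom = if (is.null(arom)) FALSE else arom[i],
       ring = ring[i], nH = hs[i],
       alphaCO = any(vapply(seq_len(nrow(nb)), function(k) {
         j <- nb[k, 1]
         if (g$elem[j] != "C") return(FALSE)
         nb2 <- adj[[j]]
         any(g$elem[nb2[, 1]] == "O" & nb2[, 2] == 2)
       }, logical(1))))
}

## deterministic per-environment offset in [-half, half] from a hash id
hashOffset <- function(id, half) ((id %% 1009) / 1009 - 0.5) * 2 * half

## base 13C shift (ppm) from local environment
c13Base <- function(ft) {
  if (ft$trpN) return(117)
  if (ft$dblO) {
    if (ft$nH > 0) return(192)
    if (ft$sglO >= 1) return(171)
    if (ft$sglN >= 1) return(168)
    return(202)
  }
  if (ft$arom) return(128)
  if (ft$dblC && ft$ring) return(130)
  if (ft$dblC) return(122)
  if (ft$trpC) return(72)
  if (ft$sglO > 0) return(62 + 6 * (ft$sglO - 1))
  if (ft$sglN > 0) return(47)
  if (ft$nCl > 0) return(44)
  8 + 7 * ft$nC
}

## base 1H shift (ppm) for hydrogens on one heavy atom
h1Base <- function(elem, ft) {
  if (elem == "O") return(3.2)
  if (elem == "N") return(1.9)
  if (ft$dblO) return(9.6)
  if (ft$arom) return(7.3)
  if (ft$dblC && ft$ring) return(6.4)
  if (ft$dblC) return(5.6)
  if (ft$sglO > 0) return(3.8)
  if (ft$nCl > 0) return(3.6)
  if (ft$sglN > 0) return(2.9)
  if (ft$alphaCO) return(2.3)
  0.9 + 0.25 * ft$nC
}

## per-environment analysis shared by all modalities
analyzeEnvironments <- function(g) {
  adj <- adjacency(g)                       # kekulized, for group features
  adjC <- adjacency(g, bondOrderCodes(g))   # aromatic-adjusted invariants
  hs <- implicitH(g)
  ring <- ringAtomFlags(g)
  arom <- aromaticAtomFlags(g)
  cls <- symmetryClasses(g)
  envId <- vapply(seq_along(g$elem), function(i) {
    nb <- adjC[[i]]
    nbr <- if (nrow(nb))
      sort(paste(nb[, 2], g$elem[nb[, 1]], cls[nb[, 1]])) else character(0)
    hashString(paste(g$elem[i], cls[i], hs[i],
                     paste(nbr, collapse = "|")))
  }, numeric(1))
  list(adj = adj, hs = hs, ring = ring, arom = arom, cls = cls,
       envId = envId)
}

#' Simulate rule-based peak lists for a molecule
#'
#' Produces synthetic peak/band lists for the requested modalities: one 13C
#' peak per symmetry-distinct carbon, one 1H multiplet per distinct
#' hydrogen environment (intensity proportional to the hydrogen count), one
#' IR band per functional group present, and one HSQC cross peak per
#' hydrogen-bearing carbon environment. Positions are fixed environment-
#' table values plus a deterministic environment-hash offset, so the output
#' is a pure function of the structure.
#'
#' @param x a SMILES string.
#' @param modalities subset of `c("c13","h1","ir","hsqc")`.
#' @return named list of `PeakList` / `HSQCPeaks` tables.
#' @export
simulatePeaks <- function(x, modalities = c("c13", "h1", "ir", "hsqc")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  g <- if (inherits(x, "molgraph")) x else graphFromSmiles(x)
  env <- analyzeEnvironments(g)
  out <- list()
  carbons <- which(g$elem == "C")
  cReps <- carbons[!duplicated(env$cls[carbons])]
  cShift <- setNames(vapply(cReps, function(i) {
    ft <- atomFeatures(g, env$adj, env$hs, env$ring, i, env$arom)
    min(max(c13Base(ft) + hashOffset(env$envId[i], 5), 0), 300)
  }, numeric(1)), env$cls[cReps])
  hCarriers <- which(env$hs > 0)
  hReps <- hCarriers[!duplicated(env$cls[hCarriers])]
  hShift <- setNames(vapply(hReps, function(i) {
    ft <- atomFeatures(g, env$adj, env$hs, env$ring, i, env$arom)
    min(max(h1Base(g$elem[i], ft) + hashOffset(env$envId[i] * 7 + 3, 0.3),
            -2), 10)
  }, numeric(1)), env$cls[hReps])

  if ("c13" %in% modalities)
    out$c13 <- peakList("c13", position = unname(cShift),
                        intensity = rep(1, length(cShift)))
  if ("h1" %in% modalities) {
    inten <- vapply(hReps, function(i)
      sum(env$hs[env$cls == env$cls[i] & g$elem == g$elem[i]]), numeric(1))
    out$h1 <- peakList("h1", position = unname(hShift), intensity = inten,
                       width = rep(0.03, length(hShift)))
  }
  if ("ir" %in% modalities) out$ir <- simulateIRBands(g, env)
  if ("hsqc" %in% modalities) {
    chReps <- hReps[g$elem[hReps] == "C"]
    if (length(chReps)) {
      cc <- vapply(chReps, function(i) unname(cShift[as.character(env$cls[i])]),
                   numeric(1))
      hh <- vapply(chReps, function(i) unname(hShift[as.character(env$cls[i])]),
                   numeric(1))
      out$hsqc <- hsqcPeaks(c_centroid = cc, c_min = cc - 1, c_max = cc + 1,
                            h_centroid = hh, h_min = hh - 0.04,
                            h_max = hh + 0.04)
    } else {
      out$hsqc <- hsqcPeaks(c_centroid = numeric(0), h_centroid = numeric(0))
    }
  }
  out
}

## functional-group IR band table (synthetic band positions)
simulateIRBands <- function(g, env) {
  feats <- lapply(seq_along(g$elem), function(i)
    atomFeatures(g, env$adj, env$hs, env$ring, i, env$arom))
  bands <- list()
  addBand <- function(pos, depth, width, count, tag) {
    if (count <= 0) return()
    eff <- min(depth * (1 - 0.55^count) / 0.45, 0.95)
    off <- hashOffset(hashString(tag, init = sum(env$envId) %% MOD31), 8)
    bands[[length(bands) + 1L]] <<- c(pos + off, eff, width)
  }
  isC <- g$elem == "C"; isO <- g$elem == "O"; isN <- g$elem == "N"
  addBand(3350, 0.65, 160, sum(isO & env$hs > 0), "OH")
  addBand(3380, 0.50, 110, sum(isN & env$hs > 0), "NH")
  addBand(2925, 0.55, 70, sum(isC & env$hs > 0), "CH")
  nCO <- sum(vapply(which(isC), function(i) feats[[i]]$dblO, logical(1)))
  addBand(1715, 0.85, 35, nCO, "C=O")
  nCCring <- sum(vapply(which(isC), function(i)
    feats[[i]]$dblC && feats[[i]]$ring, logical(1))) / 2
  addBand(1600, 0.35, 30, floor(nCCring), "C=C ring")
  nCC <- sum(vapply(which(isC), function(i)
    feats[[i]]$dblC && !feats[[i]]$ring, logical(1))) / 2
  addBand(1652, 0.30, 25, floor(nCC), "C=C")
  addBand(2250, 0.40, 25,
          sum(vapply(which(isC), function(i) feats[[i]]$trpN, logical(1))),
          "C#N")
  addBand(1085, 0.50, 45,
          sum(vapply(which(isC), function(i) feats[[i]]$sglO, numeric(1))),
          "C-O")
  addBand(1230, 0.35, 40,
          sum(vapply(which(isC), function(i) feats[[i]]$sglN, numeric(1))),
          "C-N")
  addBand(745, 0.45, 30,
          sum(vapply(which(isC), function(i) feats[[i]]$nCl, numeric(1))),
          "C-Cl")
  if (!length(bands))
    return(peakList("ir", position = numeric(0)))
  m <- do.call(rbind, bands)
  peakList("ir", position = m[, 1], intensity = m[, 2], width = m[, 3])
}

#' Simulate a SpectrumSet for a molecule
#'
#' Runs [simulatePeaks] and the spectral codec to produce model-ready
#' vectors. With `augment = TRUE`, realism augmentations (position jitter,
#' broadening, additive noise, baseline drift for 1H; centroid jitter for
#' HSQC) are applied with per-modality seeds fanned out from `seed`, so the
#' same molecule and seed always give identical spectra.
#'
#' @param x a SMILES string.
#' @param modalities subset of `c("c13","h1","ir","hsqc")`.
#' @param seed integer seed for the augmentation streams.
#' @param augment logical, or an [augmentConfig] to override the defaults.
#' @param config a [codecConfig].
#' @return a [SpectrumSet].
#' @export
simulateSpectra <- function(x, modalities = c("c13", "h1"), seed = 1L,
                            augment = FALSE, config = codecConfig()) {
  peaks <- simulatePeaks(x, modalities)
  aug <- if (isTRUE(augment)) augmentConfig()
         else if (inherits(augment, "augmentConfig")) augment else NULL
  sv <- list()
  if ("c13" %in% modalities) sv$c13 <- binC13(peaks$c13, config)
  if ("h1" %in% modalities) {
    p <- peaks$h1
    if (!is.null(aug)) {
      a <- aug; a$seed <- fanSeed(seed, "h1", "peaks")
      p <- augmentH1(p, a)
      p$position <- pmin(pmax(p$position, config$h1Range[1]),
                         config$h1Range[2])
    }
    v <- vectorizeH1(p, config)
    if (!is.null(aug)) {
      a <- aug; a$seed <- fanSeed(seed, "h1", "trace")
      v <- augmentH1(v, a)
    }
    sv$h1 <- v
  }
  if ("ir" %in% modalities) sv$ir <- vectorizeIR(peaks$ir, config)
  if ("hsqc" %in% modalities) {
    a <- if (!is.null(aug)) {
      a2 <- aug; a2$seed <- fanSeed(seed, "hsqc"); a2
    } else NULL
    sv$hsqc <- rasterizeHSQC(peaks$hsqc, augment = a, config = config)
  }
  SpectrumSet(sv)
}

#' Write a corpus and its spectra to disk
#'
#' Exports the molecule list as SMILES text and SDF, per-molecule peak
#' lists as CSV, and a manifest JSON linking molecule ids to spectrum
#' files.
#'
#' @param corpus data.frame from [generateCorpus].
#' @param dir output directory (created if missing).
#' @param modalities modalities to simulate and write.
#' @return invisibly, the manifest path.
#' @export
writeCorpus <- function(corpus, dir, modalities = c("c13", "h1")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(corpus$smiles, file.path(dir, "corpus.smi"))
  graphs <- lapply(corpus$smiles, graphFromSmiles)
  sdfset <- graphsToSDFset(graphs)
  suppressWarnings(ChemmineR::cid(sdfset) <- corpus$id)
  ChemmineR::write.SDF(sdfset, file.path(dir, "corpus.sdf"))
  manifest <- list()
  for (i in seq_len(nrow(corpus))) {
    peaks <- simulatePeaks(corpus$smiles[i], modalities)
    files <- list()
    for (m in names(peaks)) {
      f <- file.path(dir, sprintf("%s_%s.csv", corpus$id[i], m))
      write.csv(as.data.frame(peaks[[m]]), f, row.names = FALSE)
      files[[m]] <- basename(f)
    }
    manifest[[corpus$id[i]]] <- list(smiles = corpus$smiles[i],
                                     formula = corpus$formula[i],
                                     spectra = files)
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
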