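## Internal molecular graph machinery. SMILES parsing and canonicalization
## go through ChemmineR/ChemmineOB (OpenBabel); everything graph-level --
## valence accounting, implicit hydrogens, connectivity, symmetry classes,
## ring-bond detection -- is done here because the genetic algorithm edits
## these graphs directly and OpenBabel does not enforce valence on input.

## default valences of the supported (neutral, organic-subset) elements
ELEMENT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                     F = 1, Cl = 1, Br = 1, I = 1, H = 1)

## a molgraph is list(elem = character, bonds = matrix[, c(from, to, order)])
molGraph <- function(elem, bonds) {
  bonds <- matrix(as.numeric(bonds), ncol = 3,
                  dimnames = list(NULL, c("from", "to", "order")))
  structure(list(elem = as.character(elem), bonds = bonds),
            class = "molgraph")
}

## per-atom sum of bond orders
bondOrderSums <- function(g) {
  s <- numeric(length(g$elem))
  if (nrow(g$bonds)) for (i in seq_len(nrow(g$bonds))) {
    s[g$bonds[i, 1]] <- s[g$bonds[i, 1]] + g$bonds[i, 3]
    s[g$bonds[i, 2]] <- s[g$bonds[i, 2]] + g$bonds[i, 3]
  }
  s
}

## implicit hydrogen count per heavy atom (default valence minus bond orders)
implicitH <- function(g) {
  val <- ELEMENT_VALENCE[g$elem]
  pmax(0, val - bondOrderSums(g))
}

## adjacency list: for each atom, matrix of (neighbor, order); `orders`
## can substitute per-bond values (e.g. aromatic-adjusted codes)
adjacency <- function(g, orders = NULL) {
  n <- length(g$elem)
  if (is.null(orders)) orders <- g$bonds[, 3]
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(numeric(0), ncol = 2)
  if (nrow(g$bonds)) for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- orders[i]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  adj
}

graphConnected <- function(g) {
  n <- length(g$elem)
  if (n <= 1) return(TRUE)
  adj <- adjacency(g)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    nb <- adj[[a]][, 1]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

## structural validity: known elements, valence bounds respected, orders in
## 1..3, no duplicate/self bonds, connected
graphValid <- function(g, maxHeavy = Inf) {
  n <- length(g$elem)
  if (n < 1 || n > maxHeavy) return(FALSE)
  if (!all(g$elem %in% names(ELEMENT_VALENCE))) return(FALSE)
  b <- g$bonds
  if (nrow(b)) {
    if (any(b[, 3] < 1 | b[, 3] > 3)) return(FALSE)
    if (any(b[, 1] == b[, 2])) return(FALSE)
    if (any(b[, 1:2] < 1 | b[, 1:2] > n)) return(FALSE)
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key)) return(FALSE)
  }
  if (any(bondOrderSums(g) > ELEMENT_VALENCE[g$elem])) return(FALSE)
  graphConnected(g)
}

## bonds that sit on a cycle (non-bridges): removing the bond keeps the
## graph connected
ringBondFlags <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  vapply(seq_len(nb), function(i) {
    g2 <- g; g2$bonds <- g$bonds[-i, , drop = FALSE]
    graphConnected(g2)
  }, logical(1))
}

ringAtomFlags <- function(g) {
  fl <- logical(length(g$elem))
  rb <- ringBondFlags(g)
  if (any(rb)) {
    at <- unique(as.vector(g$bonds[rb, 1:2]))
    fl[at] <- TRUE
  }
  fl
}

## benzene-like aromaticity: bonds of six-membered C/N rings whose bond
## orders alternate single/double around the ring. Used only for atom
## environment invariants (symmetry classes, fingerprints, shift tables);
## valence accounting always uses the kekulized orders.
aromaticBondFlags <- function(g) {
  nb <- nrow(g$bonds)
  flags <- logical(nb)
  if (nb == 0) return(flags)
  rb <- ringBondFlags(g)
  adj <- adjacency(g)
  bondIdx <- function(a, b)
    which((g$bonds[, 1] == a & g$bonds[, 2] == b) |
          (g$bonds[, 1] == b & g$bonds[, 2] == a))[1]
  for (i in which(rb)) {
    if (flags[i]) next
    a <- g$bonds[i, 1]; b <- g$bonds[i, 2]
    # shortest cycle through bond i: BFS from b to a avoiding the bond
    par <- rep(NA_integer_, length(g$elem)); par[b] <- 0L
    queue <- b
    while (length(queue) && is.na(par[a])) {
      x <- queue[1]; queue <- queue[-1]
      for (y in adj[[x]][, 1]) {
        if ((x == a && y == b) || (x == b && y == a)) next
        if (is.na(par[y])) { par[y] <- x; queue <- c(queue, y) }
      }
    }
    if (is.na(par[a])) next
    path <- a; x <- a
    while (par[x] != 0L) { x <- par[x]; path <- c(path, x) }
    if (length(path) != 6) next
    if (!all(g$elem[path] %in% c("C", "N"))) next
    cyc <- c(path, path[1])
    bidx <- vapply(1:6, function(k) bondIdx(cyc[k], cyc[k + 1]), 0)
    if (anyNA(bidx)) next
    ords <- g$bonds[bidx, 3]
    alt <- all(ords[c(1, 3, 5)] == ords[1]) &&
           all(ords[c(2, 4, 6)] == ords[2]) &&
           sort(unique(ords)) [1] == 1 && length(unique(ords)) == 2 &&
           max(ords) == 2
    if (alt) flags[bidx] <- TRUE
  }
  flags
}

## per-bond integer order codes for environment invariants: 2/4/6 for
## single/double/triple, 3 for aromatic
bondOrderCodes <- function(g) {
  codes <- g$bonds[, 3] * 2
  ar <- aromaticBondFlags(g)
  codes[ar] <- 3
  codes
}

aromaticAtomFlags <- function(g) {
  fl <- logical(length(g$elem))
  ar <- aromaticBondFlags(g)
  if (any(ar)) fl[unique(as.vector(g$bonds[ar, 1:2]))] <- TRUE
  fl
}

## graph distance matrix by BFS (small molecules; O(n^2))
graphDistances <- function(g) {
  n <- length(g$elem)
  adj <- adjacency(g)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0; queue <- s
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in adj[[a]][, 1]) if (D[s, b] > D[s, a] + 1) {
        D[s, b] <- D[s, a] + 1
        queue <- c(queue, b)
      }
    }
  }
  D
}

## Symmetry (topological equivalence) classes by iterative invariant
## refinement to a fixed point -- the canonical-ranking backbone used for
## distinct NMR environments and the circular fingerprint.
symmetryClasses <- function(g) {
  n <- length(g$elem)
  adj <- adjacency(g, bondOrderCodes(g))
  hs <- implicitH(g)
  inv <- paste(g$elem, vapply(adj, nrow, 0L), hs,
               vapply(adj, function(m) sum(m[, 2]), numeric(1)))
  cls <- match(inv, unique(inv))
  # refinement only splits classes, so a stable class count means the
  # partition is at its fixed point
  repeat {
    inv2 <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      nbr <- if (nrow(nb)) sort(paste(nb[, 2], cls[nb[, 1]])) else character(0)
      paste(cls[i], paste(nbr, collapse = "|"))
    }, "")
    cls2 <- match(inv2, unique(inv2))
    done <- length(unique(cls2)) == length(unique(cls))
    cls <- cls2
    if (done) break
  }
  cls
}

## ---- ChemmineOB bridge --------------------------------------------------

## molgraph from a SMILES string (kekulized by OpenBabel)
graphFromSmiles <- function(smiles) {
  # single heavy atoms confuse the SDF round trip; build them directly
  m <- regmatches(smiles,
                  regexec("^\\[?([A-Z][a-z]?)H?[0-9]*\\]?$", smiles))[[1]]
  if (length(m) == 2 && m[2] %in% names(ELEMENT_VALENCE))
    return(molGraph(m[2], matrix(numeric(0), ncol = 3)))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  g <- graphFromSDF(sdf[[1]])
  if (!length(g$elem) || !all(g$elem %in% names(ELEMENT_VALENCE)))
    stop("could not parse SMILES into a supported molecular graph: ",
         smiles)
  g
}

graphFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  keep <- elem != "H"
  if (!all(keep)) {
    # drop explicit hydrogens; they are tracked implicitly
    map <- cumsum(keep)
    bb <- bb[keep[bb[, 1]] & keep[bb[, 2]], , drop = FALSE]
    bb[, 1] <- map[bb[, 1]]; bb[, 2] <- map[bb[, 2]]
    elem <- elem[keep]
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3)
    matrix(numeric(0), ncol = 3) else bb[, 1:3, drop = FALSE]
  # OpenBabel marks aromatic bonds as order 4 in some inputs; treat as 1.5
  # rounded to kekulized orders is not possible here, so reject them --
  # smiles2sdf kekulizes, so order 4 should not occur in practice.
  if (nrow(bonds) && any(bonds[, 3] > 3))
    stop("unkekulized aromatic bond encountered")
  molGraph(elem, bonds)
}

## molgraph -> ChemmineR SDFset (zero coordinates; connectivity only)
graphToSDF <- function(g, id = "mol") {
  n <- length(g$elem)
  ab <- matrix(0, nrow = n, ncol = 15)
  rownames(ab) <- paste(g$elem, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", "C5", "C6", "C7", "C8", "C9", "C10",
                    "C11", "C12", "C13", "C14", "C15", "C16")
  nb <- nrow(g$bonds)
  bb <- matrix(0, nrow = nb, ncol = 7)
  colnames(bb) <- paste0("C", 1:7)
  if (nb) {
    bb[, 1:3] <- g$bonds
    rownames(bb) <- seq_len(nb)
  }
  h <- c(Molecule_Name = id, Source = "SpectraMol", Comment = "",
         Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                               n, nb))
  sdf <- new("SDF", header = h, atomblock = ab,
             bondblock = bb, datablock = character(0))
  new("SDFset", SDF = list(sdf), ID = id)
}

## combine several molgraphs into one SDFset with unique ids
graphsToSDFset <- function(graphs) {
  ids <- sprintf("m%06d", seq_along(graphs))
  sdfs <- lapply(seq_along(graphs), function(i)
    graphToSDF(graphs[[i]], ids[i])[[1]])
  sdfset <- new("SDFset", SDF = sdfs, ID = ids)
  sdfset
}

## parse OpenBabel "SMILES<TAB>title" output lines and realign by title so
## an unreadable molecule yields NA instead of shifting the vector
alignByTitle <- function(out, ids) {
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1)
  ttl <- trimws(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, ""))
  res <- rep(NA_character_, length(ids))
  m <- match(ids, ttl)
  res[!is.na(m)] <- smi[m[!is.na(m)]]
  res
}

## canonical SMILES for a list of molgraphs or a character vector of
## SMILES (one OpenBabel conversion per batch); returns a data.frame with
## column cansmi, one row per input, NA where conversion failed
obProps <- function(x) {
  if (inherits(x, "molgraph")) x <- list(x)
  ids <- sprintf("m%06d", seq_along(x))
  can <- if (is.character(x)) {
    src <- paste(paste(x, ids), collapse = "\n")
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src))
    alignByTitle(out, ids)
  } else {
    blocks <- vapply(seq_along(x), function(i)
      paste(ChemmineR::sdf2str(graphToSDF(x[[i]], ids[i])[[1]]),
            collapse = "\n"), "")
    out <- suppressWarnings(ChemmineOB::convertFormat(
      "SDF", "CAN", paste(blocks, collapse = "\n")))
    alignByTitle(out, ids)
  }
  data.frame(cansmi = can, stringsAsFactors = FALSE)
}

## canonical SMILES of one molgraph or SMILES string
canonicalSmiles <- function(x) {
  if (is.character(x) && length(x) > 1) return(obProps(x)$cansmi)
  obProps(if (is.character(x)) x else list(x))$cansmi
}

## parse a molecular-formula string like "C2H6O" or "C6H5Cl" into a named
## integer vector of element counts, in Hill order (C, H, then alphabetical)
parseFormulaString <- function(s) {
  parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(sub("^[A-Za-z]+", "", parts))
  ct[is.na(ct)] <- 1L
  counts <- tapply(ct, el, sum)
  f <- setNames(as.integer(counts), names(counts))
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  f[hill]
}
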