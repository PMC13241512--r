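## Circular (Morgan-style) fingerprints, authored here on the package's own
## molecular graphs. Atom identifiers start from local invariants (element,
## heavy degree, implicit H count, bond-order sum, ring membership) and are
## iteratively re-hashed together with the sorted (bond order, neighbor id)
## pairs out to the configured radius; every identifier from every radius is
## folded into a fixed-length bit vector. The construction only uses
## graph-invariant information, so isomorphic graphs (any SMILES writing of
## the same molecule) give identical fingerprints.

#' Morgan-style circular fingerprint
#'
#' @param x a SMILES string (parsed and kekulized via OpenBabel) or an
#'   internal molecular graph.
#' @param radius neighborhood radius (default 6).
#' @param nbits fingerprint length in bits (default 2048).
#' @return integer vector of `nbits` zeros/ones.
#' @export
morganFingerprint <- function(x, radius = 6L, nbits = 2048L) {
  g <- if (inherits(x, "molgraph")) x else graphFromSmiles(x)
  n <- length(g$elem)
  adj <- adjacency(g, bondOrderCodes(g))
  hs <- implicitH(g)
  ring <- ringAtomFlags(g)
  deg <- vapply(adj, nrow, 0L)
  codeSum <- vapply(adj, function(m) sum(m[, 2]), numeric(1))
  elemNum <- match(g$elem, names(ELEMENT_VALENCE))
  ids <- vapply(seq_len(n), function(i)
    hashInts(c(elemNum[i], deg[i], hs[i], codeSum[i],
               as.integer(ring[i]))), numeric(1))
  all_ids <- ids
  if (radius >= 1) for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (nrow(nb)) {
        pairs <- paste(nb[, 2], ids[nb[, 1]])
        o <- order(pairs)
        hashInts(c(r, ids[i],
                   as.vector(t(cbind(nb[o, 2], ids[nb[o, 1]])))))
      } else hashInts(c(r, ids[i]))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(nbits)
  bits[(unique(all_ids) %% nbits) + 1] <- 1L
  bits
}

#' Structure match check
#'
#' Primary criterion: equality of circular fingerprints (radius 6, 2048
#' bits). The stricter canonical-SMILES equality is reported alongside as a
#' collision guard (identical canonical strings always imply a fingerprint
#' match; the converse can fail only on a hash collision).
#'
#' @param candidate,reference SMILES strings.
#' @param radius,nbits fingerprint parameters.
#' @return logical flag (fingerprint criterion) with attribute
#'   `"canonical"` holding the canonical-equality flag.
#' @export
isMatch <- function(candidate, reference, radius = 6L, nbits = 2048L) {
  fp <- all(morganFingerprint(candidate, radius, nbits) ==
            morganFingerprint(reference, radius, nbits))
  canon <- identical(canonicalSmiles(candidate), canonicalSmiles(reference))
  structure(fp, canonical = canon)
}
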