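# ECFC4-style count fingerprints.
#
# The engine enumerates circular atom environments of radius 0, 1 and 2
# (diameter 4) per heavy atom. Atom identifiers start from the invariant
# (atomic number, heavy degree, total H count, formal charge, ring
# membership) and are iteratively refined by hashing the sorted
# (bond label, neighbour identifier) pairs. Bond labels are 1/2/3 for kekule
# orders and 4 for aromatic bonds (see the aromaticity model in mol-graph.R),
# so symmetry-equivalent aromatic environments collapse to one identifier.
#
# An environment of radius r >= 1 covers the set of bonds within r of its
# centre; environments whose bond set was already covered by an earlier
# environment (previous round, or earlier atom in the same round) are
# duplicates of the same substructure and are dropped. Radius-0 environments
# (empty bond set) are always kept. Identifiers of surviving environments are
# folded into 1024 buckets; counts accumulate per bucket.
#
# Identifiers are 31-bit values from a polynomial rolling hash modulo the
# Mersenne prime 2^31-1, computed exactly in double precision via 16-bit
# split multiplication.

.FP_BUCKETS <- 1024L
.HASH_P <- 2147483647      # 2^31 - 1, prime
.HASH_A <- 1103515245      # fixed odd multiplier

# (a * b) mod .HASH_P, exact for 0 <= a < 2^31, 0 <= b < 2^31
.mulmod <- function(a, b) {
  hi <- a %/% 65536
  lo <- a %% 65536
  (((hi * b) %% .HASH_P) * 65536 + lo * b) %% .HASH_P
}

# Rolling hash of the rows of an integer matrix (vectorised across rows).
.hash_rows <- function(mat) {
  h <- rep(17, nrow(mat))
  for (j in seq_len(ncol(mat))) {
    h <- (.mulmod(h, .HASH_A) + mat[, j] + 1) %% .HASH_P
  }
  h
}

.hash_vec <- function(v) {
  h <- 17
  for (x in v) h <- (.mulmod(h, .HASH_A) + x + 1) %% .HASH_P
  h
}

#' Count fingerprint of a molecule (ECFC4, 1024 buckets)
#'
#' @param mol a `molgraph` (from [parse_smiles()]) or a single SMILES string.
#' @return an object of class `count_fp`: a list with `buckets` (named
#'   integer vector, bucket index 0-1023 to count), `cardinality` (number of
#'   nonzero buckets) and `total_count` (sum of counts). The unfolded
#'   environment identifiers are kept in the `classes` attribute.
#' @examples
#' fp <- count_fingerprint("CC(C)(C)NCC(O)c1ccc(O)c(CO)c1")
#' fp$cardinality   # 33
#' fp$total_count   # 45
#' @export
count_fingerprint <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.null(mol) || !inherits(mol, "molgraph")) {
    stop("count_fingerprint() requires a valid molecule")
  }
  n <- length(mol$elem)
  z <- unname(.atomic_number[mol$elem])
  inv <- cbind(z, mol$degree, mol$nH, mol$charge + 8L,
               as.integer(mol$ring_atom))
  ids <- .hash_rows(inv)

  kept_ids <- ids                      # radius-0 environments, all kept
  seen <- new.env(hash = TRUE, parent = emptyenv())

  bond_label <- integer(nrow(mol$bonds))
  if (nrow(mol$bonds) > 0) {
    bond_label <- ifelse(mol$arom_bond, 4L, mol$bonds[, 3])
  }

  for (r in 1:2) {
    new_ids <- numeric(n)
    for (a in seq_len(n)) {
      nb <- mol$adj[[a]]
      bb <- mol$bond_adj[[a]]
      if (length(nb) == 0) {
        new_ids[a] <- .hash_vec(c(r, ids[a]))
        next
      }
      ord <- order(bond_label[bb], ids[nb])
      pairs <- rbind(bond_label[bb][ord], ids[nb][ord])
      new_ids[a] <- .hash_vec(c(r, ids[a], as.vector(pairs)))
    }
    # environment bond sets at this radius (bonds within r of the centre:
    # bonds incident to the centre for r = 1, to its closed neighbourhood
    # for r = 2), deduplicated across and within rounds
    for (a in seq_len(n)) {
      if (length(mol$adj[[a]]) == 0) next
      env_bonds <- if (r == 1) {
        sort(mol$bond_adj[[a]])
      } else {
        sort(unique(unlist(mol$bond_adj[c(a, mol$adj[[a]])])))
      }
      if (length(env_bonds) == 0) next
      key <- paste(env_bonds, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      kept_ids <- c(kept_ids, new_ids[a])
    }
    ids <- new_ids
  }

  classes <- table(kept_ids)
  bucket_idx <- as.numeric(names(classes)) %% .FP_BUCKETS
  buckets <- tapply(as.integer(classes), bucket_idx, sum)
  buckets <- buckets[order(as.integer(names(buckets)))]
  storage.mode(buckets) <- "integer"
  structure(
    list(buckets = buckets,
         cardinality = length(buckets),
         total_count = sum(buckets)),
    classes = classes,
    class = "count_fp"
  )
}

#' @export
print.count_fp <- function(x, ...) {
  cat("ECFC4_1024 count fingerprint: cardinality", x$cardinality,
      "total", x$total_count, "\n")
  invisible(x)
}
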