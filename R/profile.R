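#' Complexity profile of a molecule
#'
#' The five features used to match target molecules across experiments:
#' number of heavy atoms, number of aliphatic and aromatic rings (smallest
#' set of smallest rings after aromaticity perception), fingerprint
#' cardinality (nonzero buckets of the ECFC4_1024 count fingerprint) and the
#' total fingerprint count (sum over buckets).
#'
#' @param mol a `molgraph` or a single SMILES string.
#' @return a tibble row with `heavy_atoms`, `aliphatic_rings`,
#'   `aromatic_rings`, `cardinality`, `total_fingerprints`.
#' @examples
#' complexity_profile("CC(C)(C)NCC(O)c1ccc(O)c(CO)c1")  # 17, 0, 1, 33, 45
#' @export
complexity_profile <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.null(mol) || !inherits(mol, "molgraph")) {
    stop("complexity_profile() requires a valid molecule")
  }
  fp <- count_fingerprint(mol)
  n_arom <- sum(mol$sssr_arom)
  tibble::tibble(
    heavy_atoms = length(mol$elem),
    aliphatic_rings = length(mol$sssr) - n_arom,
    aromatic_rings = n_arom,
    cardinality = fp$cardinality,
    total_fingerprints = fp$total_count
  )
}

#' Are two complexity profiles equivalent?
#'
#' Strict equality on all five features, the criterion used to select
#' complexity-equivalent target molecules.
#'
#' @param a,b single-row profiles from [complexity_profile()].
#' @return `TRUE` iff all five features are pairwise equal.
#' @export
complexity_equivalent <- function(a, b) {
  cols <- c("heavy_atoms", "aliphatic_rings", "aromatic_rings",
            "cardinality", "total_fingerprints")
  all(vapply(cols, function(cl) a[[cl]][1] == b[[cl]][1], logical(1)))
}

#' Select complexity-equivalent candidate molecules
#'
#' @param reference a valid SMILES string or `molgraph`.
#' @param candidates character vector of SMILES strings.
#' @return the subset of `candidates` (input order preserved) whose
#'   complexity profile equals the reference's.
#' @export
select_equivalent_targets <- function(reference, candidates) {
  ref <- complexity_profile(reference)
  keep <- vapply(candidates, function(s) {
    g <- parse_smiles(s)
    if (is.null(g)) return(FALSE)
    complexity_equivalent(complexity_profile(g), ref)
  }, logical(1), USE.NAMES = FALSE)
  candidates[keep]
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them, with terminal substituents
#' removed; atoms double- or triple-bonded directly to a framework atom are
#' retained. Acyclic molecules map to the empty-scaffold sentinel `""`,
#' which counts as one shared scaffold class in ratio computations.
#'
#' @param mol a `molgraph` or single SMILES string.
#' @return canonical SMILES of the scaffold, or `""` for acyclic molecules.
#' @examples
#' murcko_scaffold("Cc1ccccc1")  # "c1ccccc1"
#' murcko_scaffold("CCO")        # ""
#' @export
murcko_scaffold <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.null(mol) || !inherits(mol, "molgraph")) {
    stop("murcko_scaffold() requires a valid molecule")
  }
  if (!any(mol$ring_atom)) return("")
  n <- length(mol$elem)
  keep <- rep(TRUE, n)
  deg <- mol$degree
  # iteratively strip terminal atoms regardless of bond order -> rings+linkers
  repeat {
    term <- which(keep & deg <= 1 & !mol$ring_atom)
    if (length(term) == 0) break
    for (a in term) {
      keep[a] <- FALSE
      for (w in mol$adj[[a]]) if (keep[w]) deg[w] <- deg[w] - 1L
    }
  }
  # re-attach atoms multiple-bonded directly to the framework
  if (nrow(mol$bonds) > 0) {
    for (b in seq_len(nrow(mol$bonds))) {
      if (mol$bonds[b, 3] >= 2L) {
        a1 <- mol$bonds[b, 1]; a2 <- mol$bonds[b, 2]
        if (keep[a1] != keep[a2]) {
          keep[a1] <- TRUE; keep[a2] <- TRUE
        }
      }
    }
  }
  sub_g <- .subgraph(mol, which(keep))
  out <- molgraph_to_smiles(list(finalize_molgraph(sub_g)))
  if (is.na(out)) stop("scaffold canonicalization failed")
  out
}

# induced subgraph on a set of atom indices
.subgraph <- function(g, atoms) {
  remap <- integer(length(g$elem))
  remap[atoms] <- seq_along(atoms)
  bonds <- g$bonds[g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms, ,
                   drop = FALSE]
  bonds[, 1] <- remap[bonds[, 1]]
  bonds[, 2] <- remap[bonds[, 2]]
  list(elem = g$elem[atoms], charge = g$charge[atoms], bonds = bonds,
       extraH = integer(length(atoms)))
}

#' Reference complexity profiles of the five benchmark drugs
#'
#' The published per-level features (heavy atoms, aliphatic and aromatic
#' rings, fingerprint cardinality and total count) for albuterol (L1),
#' celecoxib (L2), thiothixene (L3), aripiprazole (L4) and troglitazone
#' (L5), used as the fidelity anchors of the fingerprint engine.
#'
#' @return a tibble with `level`, `name`, `smiles` and the five reference
#'   features.
#' @export
reference_profiles <- function() {
  tibble::tibble(
    level = paste0("L", 1:5),
    name = c("albuterol", "celecoxib", "thiothixene", "aripiprazole",
             "troglitazone"),
    smiles = c(
      "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
      "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1",
      "CN(C)S(=O)(=O)c1ccc2c(c1)C(=CCCN1CCN(C)CC1)c1ccccc1S2",
      "O=C1CCc2ccc(OCCCCN3CCN(c4cccc(Cl)c4Cl)CC3)cc2N1",
      "Cc1c(C)c2c(c(C)c1O)CCC(C)(COc1ccc(CC3SC(=O)NC3=O)cc1)O2"
    ),
    heavy_atoms = c(17L, 26L, 30L, 30L, 31L),
    aliphatic_rings = c(0L, 0L, 2L, 2L, 2L),
    aromatic_rings = c(1L, 3L, 2L, 2L, 2L),
    cardinality = c(33L, 41L, 51L, 53L, 54L),
    total_fingerprints = c(45L, 71L, 85L, 87L, 86L)
  )
}

#' Fingerprint-engine fidelity report
#'
#' Recomputes the complexity profile of each reference drug and compares it
#' feature by feature with the published values. Cardinality depends on how
#' a toolkit's environment identifiers collide when folded into 1024
#' buckets, so engines differing only in their hash can disagree there; any
#' deviation is reported per molecule rather than silently accepted.
#'
#' @return a tibble with one row per (molecule, feature): `computed`,
#'   `reference` and `match`.
#' @export
profile_fidelity <- function() {
  ref <- reference_profiles()
  feats <- c("heavy_atoms", "aliphatic_rings", "aromatic_rings",
             "cardinality", "total_fingerprints")
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    prof <- complexity_profile(ref$smiles[i])
    tibble::tibble(
      level = ref$level[i], name = ref$name[i], feature = feats,
      computed = unname(vapply(feats, function(f) prof[[f]][1], integer(1))),
      reference = unname(vapply(feats, function(f) ref[[f]][i], integer(1)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$match <- out$computed == out$reference
  out
}
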