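#' Canonicalize SMILES into molecule records
#'
#' Validates each input as a single covalent organic structure and derives
#' the canonical SMILES, the 27-character standard InChIKey (the uniqueness
#' key used throughout), and the heavy-atom count. Inputs that fail syntax or
#' structural validation yield a record with `valid = FALSE` and `NA` derived
#' fields; no condition is signalled, so dirty experiment logs can be
#' ingested event by event.
#'
#' @param smiles character vector of SMILES strings.
#' @return a tibble with one row per input: `smiles_input`,
#'   `smiles_canonical`, `inchikey`, `heavy_atom_count`, `valid`.
#' @examples
#' canonicalize(c("OCC", "CCO", "C("))
#' @export
canonicalize <- function(smiles) {
  n <- length(smiles)
  out <- tibble::tibble(
    smiles_input = as.character(smiles),
    smiles_canonical = NA_character_,
    inchikey = NA_character_,
    heavy_atom_count = NA_integer_,
    valid = FALSE
  )
  if (n == 0) return(out)
  ok <- !is.na(smiles) & nzchar(smiles) & smiles_syntax_ok(smiles)
  if (any(ok)) {
    idx <- which(ok)
    graphs <- lapply(smiles[idx], parse_smiles)
    parsed <- !vapply(graphs, is.null, logical(1))
    idx <- idx[parsed]
    graphs <- graphs[parsed]
    if (length(idx) > 0) {
      can <- .ob_canonical(smiles[idx])
      ikey <- .ob_inchikey(smiles[idx])
      good <- !is.na(can) & !is.na(ikey)
      idx <- idx[good]
      if (length(idx) > 0) {
        out$smiles_canonical[idx] <- can[good]
        out$inchikey[idx] <- ikey[good]
        out$heavy_atom_count[idx] <-
          vapply(graphs[good], function(g) length(g$elem), integer(1))
        out$valid[idx] <- TRUE
      }
    }
  }
  out
}

#' Number of unique molecules in a set of SMILES
#'
#' Uniqueness follows the full 27-character standard InChIKey. Invalid
#' entries are excluded from the count and reported in the `n_invalid`
#' attribute.
#'
#' @param smiles_list character vector of SMILES strings.
#' @return integer count of distinct InChIKeys among valid entries, with
#'   attribute `n_invalid`.
#' @export
unique_molecule_count <- function(smiles_list) {
  if (length(smiles_list) == 0) {
    return(structure(0L, n_invalid = 0L))
  }
  rec <- canonicalize(smiles_list)
  structure(
    length(unique(rec$inchikey[rec$valid])),
    n_invalid = sum(!rec$valid)
  )
}
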