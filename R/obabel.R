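#' @importFrom ChemmineOB convertFormat
NULL

# Characters legal in a SMILES body. Used by the syntax pre-check only; full
# chemical interpretation is left to OpenBabel and the connection-table layer.
.smiles_organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.smiles_bracket_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al", "Si",
  "P", "S", "Cl", "Ar", "K", "Ca", "Se", "Br", "I", "Zn",
  "b", "c", "n", "o", "p", "s", "se", "as"
)

#' Check that a SMILES string is syntactically well formed
#'
#' OpenBabel silently repairs some malformed inputs (an unbalanced `C(` parses
#' as methane), so structural validity cannot be delegated to the conversion
#' layer alone. This check enforces the lexical rules a strict reader would:
#' balanced parentheses and brackets, matched ring-closure digits, known atom
#' symbols, and no dangling bond symbols. It deliberately does not attempt
#' chemical perception.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string is well formed.
#' @export
smiles_syntax_ok <- function(smiles) {
  vapply(smiles, .smiles_syntax_ok1, logical(1), USE.NAMES = FALSE)
}

.smiles_syntax_ok1 <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  ring <- integer(0)        # open ring-closure labels
  i <- 1L
  n <- length(chars)
  prev_atom <- FALSE        # an atom has been emitted at this point
  pending_bond <- FALSE     # a bond symbol awaits an atom/ring closure
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (!prev_atom) return(FALSE)
      depth <- depth + 1L
      i <- i + 1L
      next
    }
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0 || pending_bond) return(FALSE)
      i <- i + 1L
      next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]*[A-Za-z][a-z]?", body)) return(FALSE)
      sym <- sub("^[0-9]*", "", body)
      sym <- regmatches(sym, regexpr("^[A-Za-z][a-z]?", sym))
      if (length(sym) == 0 ||
          !(sym %in% .smiles_bracket_elements ||
            sym %in% .smiles_organic_subset)) return(FALSE)
      prev_atom <- TRUE
      pending_bond <- FALSE
      i <- j + 1L
      next
    }
    if (ch == "]") return(FALSE)
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!prev_atom) return(FALSE)
      pending_bond <- TRUE
      i <- i + 1L
      next
    }
    if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        return(FALSE)
      }
      lab <- as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      ring <- .toggle_ring(ring, lab)
      pending_bond <- FALSE
      i <- i + 3L
      next
    }
    if (grepl("[0-9]", ch)) {
      if (!prev_atom) return(FALSE)
      ring <- .toggle_ring(ring, as.integer(ch))
      pending_bond <- FALSE
      i <- i + 1L
      next
    }
    if (ch == ".") {
      prev_atom <- FALSE
      pending_bond <- FALSE
      i <- i + 1L
      next
    }
    # two-letter organic-subset symbols
    if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        prev_atom <- TRUE
        pending_bond <- FALSE
        i <- i + 2L
        next
      }
    }
    if (ch %in% c(.smiles_organic_subset, "b", "c", "n", "o", "p", "s")) {
      prev_atom <- TRUE
      pending_bond <- FALSE
      i <- i + 1L
      next
    }
    return(FALSE)
  }
  depth == 0L && length(ring) == 0L && !pending_bond
}

.toggle_ring <- function(ring, lab) {
  if (lab %in% ring) ring[ring != lab] else c(ring, lab)
}

# Convert a vector of inputs through OpenBabel, one output line per input.
# Inputs that fail conversion yield NA. A single batched call is attempted
# first; if OpenBabel drops or aborts records the batch falls back to
# per-record conversion so alignment is never guessed.
.ob_lines <- function(inputs, from, to) {
  if (length(inputs) == 0) return(character(0))
  batch <- function(x) {
    src <- paste0(paste(x, collapse = "\n"), "\n")
    out <- tryCatch(
      suppressWarnings(convertFormat(from, to, source = src)),
      error = function(e) ""
    )
    strsplit(out, "\n", fixed = TRUE)[[1]]
  }
  lines <- batch(inputs)
  if (length(lines) == length(inputs)) return(lines)
  vapply(inputs, function(x) {
    one <- batch(x)
    if (length(one) == 1 && nzchar(one)) one else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Canonical SMILES via OpenBabel. Titles are not passed through; the caller
# aligns by position.
.ob_canonical <- function(smiles) {
  out <- .ob_lines(smiles, "SMI", "CAN")
  sub("\t.*$", "", out)
}

# Standard InChIKey (27 characters) via OpenBabel's InChI plugin.
.ob_inchikey <- function(smiles) {
  out <- .ob_lines(smiles, "SMI", "INCHIKEY")
  out <- sub("\\s+$", "", out)
  ifelse(!is.na(out) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out),
         out, NA_character_)
}

# SMILES -> V2000 molblocks (kekulised, atom order preserved). Returns a
# character vector of molblocks, NA where conversion failed.
.ob_molblocks <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  out <- tryCatch(
    suppressWarnings(convertFormat("SMI", "SDF", source = src)),
    error = function(e) ""
  )
  blocks <- strsplit(out, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) == length(smiles)) return(blocks)
  vapply(smiles, function(s) {
    one <- tryCatch(
      suppressWarnings(convertFormat("SMI", "SDF", source = paste0(s, "\n"))),
      error = function(e) ""
    )
    one <- strsplit(one, "\\$\\$\\$\\$\n?")[[1]]
    one <- one[nzchar(trimws(one))]
    if (length(one) == 1) one else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Molblocks -> canonical SMILES.
.ob_molblock_to_smiles <- function(molblocks) {
  if (length(molblocks) == 0) return(character(0))
  src <- paste(paste0(molblocks, "\n$$$$"), collapse = "\n")
  out <- tryCatch(
    suppressWarnings(convertFormat("SDF", "CAN", source = paste0(src, "\n"))),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("\t.*$", "", lines)
  if (length(lines) == length(molblocks)) return(lines)
  vapply(molblocks, function(b) {
    one <- tryCatch(
      suppressWarnings(convertFormat("SDF", "CAN",
                                     source = paste0(b, "\n$$$$\n"))),
      error = function(e) ""
    )
    one <- strsplit(one, "\n", fixed = TRUE)[[1]]
    if (length(one) >= 1 && nzchar(one[1])) sub("\t.*$", "", one[1]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
}
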