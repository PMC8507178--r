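# Report-rendering entry points: complexity-profile tables, full
# experiment analyses, and the chemical-space embedding.

#' Complexity-profile table for a set of molecules
#'
#' One profile row per molecule. Invalid SMILES are kept as flagged rows
#' with `NA` features rather than dropped, so partial success is visible.
#'
#' @param smiles character vector, or the path of a SMILES file (one
#'   molecule per line, optional tab-separated identifier, `#` comments).
#' @return a tibble with `id`, `smiles`, `valid` and the five profile
#'   features.
#' @export
profile_table <- function(smiles) {
  if (length(smiles) == 1 && file.exists(smiles)) {
    parsed <- read_smiles_file(smiles)
    ids <- parsed$id
    smiles <- parsed$smiles
  } else {
    ids <- names(smiles)
    if (is.null(ids)) ids <- sprintf("mol%02d", seq_along(smiles))
    smiles <- unname(smiles)
  }
  if (length(smiles) == 0) stop("no molecules to profile")
  rows <- lapply(seq_along(smiles), function(i) {
    g <- parse_smiles(smiles[i])
    if (is.null(g)) {
      return(tibble::tibble(id = ids[i], smiles = smiles[i], valid = FALSE,
                            heavy_atoms = NA_integer_,
                            aliphatic_rings = NA_integer_,
                            aromatic_rings = NA_integer_,
                            cardinality = NA_integer_,
                            total_fingerprints = NA_integer_))
    }
    prof <- complexity_profile(g)
    dplyr::bind_cols(tibble::tibble(id = ids[i], smiles = smiles[i],
                                    valid = TRUE), prof)
  })
  dplyr::bind_rows(rows)
}

#' Read a SMILES file
#'
#' One molecule per line, optional tab-separated identifier; `#` comment
#' lines and blank lines are ignored.
#'
#' @param path file path.
#' @return a tibble with `smiles` and `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    smiles = vapply(parts, `[`, character(1), 1),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%02d", i)
    }, character(1))
  )
}

#' Analyze an experiment log end to end
#'
#' Parses (or accepts) a log, computes the full metrics report and writes
#' it as JSON and markdown. The effective scoring configuration is embedded
#' in the JSON so every number is reproducible from the report alone.
#'
#' @param log an `experiment_log`, or a path passed to [parse_log()].
#' @param target target SMILES (required when `log` is a path).
#' @param mapping optional column mapping for [parse_log()].
#' @param mode experiment mode when parsing from a path.
#' @param out_dir optional output directory; when given,
#'   `<experiment_id>_report.json` and `.md` are written there.
#' @param idle_threshold_seconds idle cutoff for time played.
#' @return the `metrics_report`, invisibly when writing files.
#' @export
analyze_log <- function(log, target = NULL, mapping = NULL,
                        mode = "collective", out_dir = NULL,
                        idle_threshold_seconds = 60) {
  if (is.character(log)) {
    log <- parse_log(log, mapping = mapping, mode = mode, target = target)
  }
  rep <- metrics_report(log, idle_threshold_seconds = idle_threshold_seconds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    base <- file.path(out_dir, paste0(log$experiment_id, "_report"))
    report_json(rep, paste0(base, ".json"))
    writeLines(report_markdown(rep), paste0(base, ".md"))
    return(invisible(rep))
  }
  rep
}

#' Chemical-space map of an experiment log
#'
#' Embeds the ECFC4_1024 count fingerprints of the unique valid molecules
#' of a log with fixed-seed t-SNE, annotated with each molecule's first
#' creator and creation order (the two colourings used to inspect
#' individual vs collective coverage).
#'
#' @param log an `experiment_log`.
#' @param seed embedding seed.
#' @param perplexity t-SNE perplexity.
#' @param min_molecules minimum number of unique molecules required.
#' @return a tibble with `inchikey`, `smiles`, `participant_id`,
#'   `creation_order`, `x`, `y`.
#' @export
embed_chemical_space <- function(log, seed = 42, perplexity = 30,
                                 min_molecules = 10) {
  ev <- log$events
  rec <- canonicalize(ev$smiles)
  valid <- which(rec$valid)
  first <- valid[!duplicated(rec$inchikey[valid])]
  if (length(first) < min_molecules) {
    stop("need at least ", min_molecules, " unique molecules, got ",
         length(first))
  }
  fps <- lapply(rec$smiles_canonical[first], count_fingerprint)
  mat <- matrix(0, length(fps), .FP_BUCKETS)
  for (i in seq_along(fps)) {
    b <- fps[[i]]$buckets
    mat[i, as.integer(names(b)) + 1L] <- b
  }
  coords <- tsne_embed(mat, perplexity = perplexity, seed = seed)
  tibble::tibble(
    inchikey = rec$inchikey[first],
    smiles = rec$smiles_canonical[first],
    participant_id = ev$participant_id[first],
    creation_order = seq_along(first),
    x = coords[, 1],
    y = coords[, 2]
  )
}
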