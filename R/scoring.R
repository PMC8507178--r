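#' Count-fingerprint Tanimoto similarity
#'
#' Default variant is the common count-vector generalization
#' \eqn{\sum_k \min(a_k,b_k) / \sum_k \max(a_k,b_k)} over the union of
#' buckets. The dot-product generalization
#' \eqn{a \cdot b / (|a|^2 + |b|^2 - a \cdot b)} is available as
#' `variant = "dot"`; which of the two the original scoring toolkit used is
#' not documented, so the choice is a recorded configuration value.
#'
#' @param a,b `count_fp` objects from [count_fingerprint()].
#' @param variant `"minmax"` (default) or `"dot"`.
#' @return similarity in \[0, 1\].
#' @export
tanimoto_count <- function(a, b, variant = c("minmax", "dot")) {
  variant <- match.arg(variant)
  if (!inherits(a, "count_fp") || !inherits(b, "count_fp")) {
    stop("tanimoto_count() requires count_fp objects")
  }
  if (a$total_count == 0 && b$total_count == 0) {
    stop("similarity of two empty fingerprints is undefined")
  }
  keys <- union(names(a$buckets), names(b$buckets))
  av <- bv <- numeric(length(keys))
  av[match(names(a$buckets), keys)] <- a$buckets
  bv[match(names(b$buckets), keys)] <- b$buckets
  if (variant == "minmax") {
    sum(pmin(av, bv)) / sum(pmax(av, bv))
  } else {
    ab <- sum(av * bv)
    ab / (sum(av^2) + sum(bv^2) - ab)
  }
}

#' Normalized in-app molecular score
#'
#' The score shown to participants: count-Tanimoto similarity of the
#' ECFC4_1024 fingerprints of a molecule and the target, linearly normalized
#' into the 0-1000 range. Normalization rounds half away from zero, so a
#' similarity of exactly 0.7216 displays as 722.
#'
#' @param mol,target `molgraph` objects or SMILES strings.
#' @param variant Tanimoto variant, see [tanimoto_count()].
#' @return a list with `similarity` (real in \[0,1\]) and `normalized`
#'   (integer in \[0,1000\]).
#' @examples
#' normalized_score("CCO", "CCO")$normalized  # 1000
#' @export
normalized_score <- function(mol, target, variant = "minmax") {
  sim <- tanimoto_count(count_fingerprint(mol), count_fingerprint(target),
                        variant = variant)
  list(similarity = sim, normalized = .round_half_up(1000 * sim))
}

.round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Thresholded similarity modifier
#'
#' The goal-directed similarity benchmarks score raw similarity through this
#' modifier: full score (1.0) at or above the threshold, decreasing linearly
#' to zero below it.
#'
#' @param similarity real in \[0, 1\].
#' @param threshold positive threshold, default 0.75.
#' @return modified score in \[0, 1\].
#' @examples
#' thresholded_modifier(0.80)   # 1.0
#' thresholded_modifier(0.375)  # 0.5
#' @export
thresholded_modifier <- function(similarity, threshold = 0.75) {
  if (any(similarity < 0 | similarity > 1, na.rm = TRUE)) {
    stop("similarity must lie in [0, 1]")
  }
  if (threshold <= 0) stop("threshold must be positive")
  pmin(similarity, threshold) / threshold
}

#' Effective scoring configuration
#'
#' The fixed engine settings embedded into every report so any number can be
#' reproduced from the report alone.
#'
#' @param tanimoto_variant `"minmax"` or `"dot"`.
#' @param idle_threshold_seconds idle cutoff used by time-played.
#' @param session_rule session segmentation rule identifier.
#' @return a named list of configuration values.
#' @export
score_config <- function(tanimoto_variant = "minmax",
                         idle_threshold_seconds = 60,
                         session_rule = "latest-own-molecule") {
  list(
    fingerprint = "ECFC4_1024",
    fingerprint_diameter = 4L,
    fingerprint_buckets = 1024L,
    aromaticity_model = "sssr-hueckel",
    tanimoto_variant = tanimoto_variant,
    score_normalization = "round-half-away-from-zero",
    idle_threshold_seconds = idle_threshold_seconds,
    session_rule = session_rule
  )
}
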