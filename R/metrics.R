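# Experiment-level metrics: efficacy (max score), efficiency (unique
# molecules, scoring calls, time played), search breadth (scaffold/molecule
# ratio), and collaboration structure (leader changes, forefront set,
# evolution steps, collaboration degree).

#' Maximum score reached in an experiment
#'
#' @param log an `experiment_log` with at least one event.
#' @return integer top-1 score.
#' @export
max_score <- function(log) {
  if (nrow(log$events) == 0) stop("empty log has no maximum score")
  max(log$events$score)
}

#' Number of scoring-function calls
#'
#' Every molecule-creation event is one evaluation of the molecular score;
#' redrawn duplicates count each time.
#'
#' @param log an `experiment_log`.
#' @return integer event count.
#' @export
scoring_calls <- function(log) {
  nrow(log$events)
}

#' Time played per participant
#'
#' Sums, per participant, the gaps between that participant's consecutive
#' events, omitting idle gaps longer than the threshold (default 60 s,
#' strictly greater omitted). A participant's first event contributes
#' nothing.
#'
#' @param log an `experiment_log`.
#' @param idle_threshold_seconds idle cutoff in seconds.
#' @return a list with `per_participant` (named numeric, seconds) and
#'   `total_seconds`.
#' @export
time_played <- function(log, idle_threshold_seconds = 60) {
  ev <- log$events
  per <- vapply(split(as.numeric(ev$timestamp), ev$participant_id),
                function(tt) {
                  gaps <- diff(sort(tt))
                  sum(gaps[gaps <= idle_threshold_seconds])
                }, numeric(1))
  list(per_participant = per, total_seconds = sum(per))
}

#' Scaffold/molecule ratio
#'
#' Unique Murcko scaffolds divided by unique molecules (InChIKey classes);
#' values are at most 1. All acyclic molecules share one empty-scaffold
#' class. Invalid SMILES are excluded. Set `invert = TRUE` for the
#' molecules-per-scaffold reading.
#'
#' @param log an `experiment_log`.
#' @param invert return molecules/scaffolds instead.
#' @return a real ratio.
#' @export
scaffold_molecule_ratio <- function(log, invert = FALSE) {
  rec <- canonicalize(log$events$smiles)
  valid <- which(rec$valid)
  if (length(valid) == 0) stop("no valid molecules in log")
  keys <- rec$inchikey[valid]
  first <- valid[!duplicated(keys)]
  scaffolds <- vapply(rec$smiles_canonical[first], murcko_scaffold,
                      character(1), USE.NAMES = FALSE)
  n_mol <- length(first)
  n_scaf <- length(unique(scaffolds))
  if (invert) n_mol / n_scaf else n_scaf / n_mol
}

#' Leader changes and forefront creators
#'
#' Scans events in order, tracking the running best score and its leader.
#' An event strictly exceeding the best score whose creator differs from
#' the current leader counts as one leader change. The first event installs
#' the initial leader without counting. The forefront creator set collects
#' creators of every strict running-maximum improvement (including the
#' first event).
#'
#' @param log an `experiment_log` with at least one event.
#' @return a list with `changes` (integer), `forefront_creators`
#'   (character) and `forefront_participation_pct`.
#' @export
leader_changes <- function(log) {
  ev <- log$events
  if (nrow(ev) == 0) stop("empty log has no leader")
  leader <- ev$participant_id[1]
  best <- ev$score[1]
  changes <- 0L
  forefront <- leader
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev$score[i] > best) {
      if (ev$participant_id[i] != leader) {
        changes <- changes + 1L
        leader <- ev$participant_id[i]
      }
      best <- ev$score[i]
      forefront <- c(forefront, ev$participant_id[i])
    }
  }
  forefront <- unique(forefront)
  list(
    changes = changes,
    forefront_creators = forefront,
    forefront_participation_pct =
      100 * length(forefront) / length(log$participants)
  )
}

#' Molecule evolution steps
#'
#' Number of distinct design sessions along the provenance path of an
#' event: how many editing episodes were needed for the molecule to come
#' into existence.
#'
#' @param log an `experiment_log`.
#' @param event_id focal event.
#' @param sessions optional precomputed [assign_sessions()].
#' @return integer number of sessions.
#' @export
evolution_steps <- function(log, event_id, sessions = NULL) {
  length(provenance_path(log, event_id, sessions)$session_sequence)
}

#' Collaboration degree of a molecule
#'
#' Percentage of the experiment's engaged participants (creators of at
#' least one event) appearing as creators along the provenance path.
#'
#' @param log an `experiment_log`.
#' @param event_id focal event.
#' @param sessions optional precomputed [assign_sessions()].
#' @return real percentage in \[0, 100\].
#' @export
collaboration_degree <- function(log, event_id, sessions = NULL) {
  path <- provenance_path(log, event_id, sessions)
  100 * length(path$creators) / length(log$participants)
}

#' Full metrics report for one experiment
#'
#' Assembles the experiment-level metric suite. Target detection uses
#' InChIKey equality with the log's target molecule (never the score alone,
#' which hashed fingerprints could in principle saturate spuriously); the
#' evolution-step and collaboration fields are populated only when the
#' target was found, using its earliest creation event.
#'
#' @param log an `experiment_log` (with a `target` for target detection).
#' @param idle_threshold_seconds idle cutoff for time played.
#' @param tanimoto_variant recorded scoring configuration.
#' @return a `metrics_report` list; see fields in the source and the
#'   rendered markdown from [report_markdown()].
#' @export
metrics_report <- function(log, idle_threshold_seconds = 60,
                           tanimoto_variant = "minmax") {
  if (nrow(log$events) == 0) stop("empty log")
  rec <- canonicalize(log$events$smiles)
  uniq <- length(unique(rec$inchikey[rec$valid]))
  lead <- leader_changes(log)
  sessions <- assign_sessions(log)

  target_event <- NA_character_
  if (!is.null(log$target)) {
    hit <- which(rec$valid & rec$inchikey == log$target$inchikey[1])
    if (length(hit) > 0) target_event <- log$events$event_id[hit[1]]
  }
  found <- !is.na(target_event)
  structure(
    list(
      experiment_id = log$experiment_id,
      mode = log$mode,
      n_participants = length(log$participants),
      max_score = max_score(log),
      unique_molecules = uniq,
      invalid_events = sum(!rec$valid),
      scoring_calls = scoring_calls(log),
      time_played_seconds = time_played(log, idle_threshold_seconds)$total_seconds,
      scaffold_molecule_ratio = scaffold_molecule_ratio(log),
      leader_changes = lead$changes,
      forefront_participation_pct = lead$forefront_participation_pct,
      target_found = found,
      target_event_id = target_event,
      target_evolution_steps =
        if (found) evolution_steps(log, target_event, sessions) else NULL,
      target_collaboration_pct =
        if (found) collaboration_degree(log, target_event, sessions) else NULL,
      config = score_config(tanimoto_variant = tanimoto_variant,
                            idle_threshold_seconds = idle_threshold_seconds)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a metrics report as a markdown table
#'
#' @param report a `metrics_report` or a list of them (one table row each).
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  if (inherits(report, "metrics_report")) report <- list(report)
  hdr <- c("Experiment", "Mode", "Time played", "Unique molecules",
           "Scaffold/molecule ratio", "Leader changes", "Max score",
           "Evolution steps", "Collaboration degree (%)")
  fmt_time <- function(s) sprintf("%dH %02dm", s %/% 3600, (s %% 3600) %/% 60)
  rows <- vapply(report, function(r) {
    paste("|", paste(c(
      r$experiment_id, r$mode, fmt_time(round(r$time_played_seconds)),
      format(r$unique_molecules, big.mark = ","),
      sprintf("%.3f", r$scaffold_molecule_ratio),
      r$leader_changes, r$max_score,
      if (is.null(r$target_evolution_steps)) "-" else r$target_evolution_steps,
      if (is.null(r$target_collaboration_pct)) "-"
      else sprintf("%.1f", r$target_collaboration_pct)
    ), collapse = " | "), "|")
  }, character(1))
  c(paste("|", paste(hdr, collapse = " | "), "|"),
    paste("|", paste(rep("---", length(hdr)), collapse = " | "), "|"),
    rows)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
report_json <- function(report, path = NULL) {
  x <- unclass(report)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
    invisible(path)
  }
}
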