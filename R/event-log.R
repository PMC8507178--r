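# Experiment event-log model.
#
# An experiment_log holds one experiment's ordered molecule-creation events:
# every event records who drew which structure at what time, from which
# earlier molecule it was derived (parent pointer, NA for scratch starts)
# and the normalized score it obtained. Ordering is total: events sort by
# timestamp with ties broken by event_id lexicographically, so all
# downstream metrics are deterministic.

.native_fields <- c("event_id", "timestamp", "participant_id", "smiles",
                    "parent_event_id", "score")

#' Construct an experiment log
#'
#' @param events a data frame with the native columns `event_id`,
#'   `timestamp`, `participant_id`, `smiles`, `parent_event_id`, `score`.
#' @param mode `"individual"` or `"collective"`.
#' @param target target molecule SMILES (resolved via [canonicalize()]).
#' @param experiment_id identifier for the experiment.
#' @return an object of class `experiment_log`: list with `experiment_id`,
#'   `mode`, `target` (a molecule record row), `events` (ordered tibble)
#'   `participants`, and a `validation` report.
#' @export
experiment_log <- function(events, mode = c("individual", "collective"),
                           target = NULL, experiment_id = "exp") {
  mode <- match.arg(mode)
  missing_cols <- setdiff(.native_fields, names(events))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  ev <- tibble::as_tibble(events)[.native_fields]
  ev$event_id <- as.character(ev$event_id)
  ev$participant_id <- as.character(ev$participant_id)
  ev$smiles <- as.character(ev$smiles)
  ev$parent_event_id <- as.character(ev$parent_event_id)
  ev$parent_event_id[!is.na(ev$parent_event_id) &
                       ev$parent_event_id == ""] <- NA_character_
  if (!inherits(ev$timestamp, "POSIXct")) {
    ts <- as.character(ev$timestamp)
    parsed <- as.POSIXct(ts, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%d"))
    if (any(is.na(parsed) & !is.na(ts))) {
      stop("unparseable timestamp(s), expected ISO-8601")
    }
    ev$timestamp <- parsed
  }
  ev$score <- as.integer(ev$score)
  if (any(is.na(ev$event_id)) || anyDuplicated(ev$event_id)) {
    stop("event_id must be present and unique")
  }
  ev <- ev[order(ev$timestamp, ev$event_id), ]

  warn <- character(0)
  dangling <- setdiff(ev$parent_event_id[!is.na(ev$parent_event_id)],
                      ev$event_id)
  if (length(dangling) > 0) {
    warn <- c(warn, paste0("dangling parent reference(s) treated as scratch: ",
                           paste(dangling, collapse = ", ")))
    ev$parent_event_id[ev$parent_event_id %in% dangling] <- NA_character_
    warning("dangling parent reference(s): ",
            paste(dangling, collapse = ", "), call. = FALSE)
  }
  pidx <- match(ev$parent_event_id, ev$event_id)
  has_parent <- !is.na(pidx)
  late_parent <- which(has_parent & ev$timestamp[pidx] > ev$timestamp)
  if (length(late_parent) > 0) {
    warn <- c(warn, paste0("parent later than child for event(s): ",
                           paste(ev$event_id[late_parent], collapse = ", ")))
  }
  cross <- which(has_parent &
                   ev$participant_id[pidx] != ev$participant_id)
  if (mode == "individual" && length(cross) > 0) {
    warn <- c(warn, paste0("individual-mode events with foreign parents: ",
                           paste(ev$event_id[cross], collapse = ", ")))
  }
  if (any(is.na(ev$score)) || any(ev$score < 0 | ev$score > 1000)) {
    stop("score must be an integer in [0, 1000]")
  }

  target_rec <- NULL
  if (!is.null(target)) {
    target_rec <- canonicalize(target)
    if (!target_rec$valid[1]) stop("target SMILES does not parse")
  }
  structure(
    list(
      experiment_id = experiment_id,
      mode = mode,
      target = target_rec,
      events = ev,
      participants = sort(unique(ev$participant_id)),
      validation = list(
        n_events = nrow(ev),
        n_dangling_parents = length(dangling),
        dangling_parents = dangling,
        warnings = warn
      )
    ),
    class = "experiment_log"
  )
}

#' @export
print.experiment_log <- function(x, ...) {
  cat("experiment_log '", x$experiment_id, "': ", nrow(x$events),
      " events, ", length(x$participants), " participants, mode=", x$mode,
      "\n", sep = "")
  invisible(x)
}

#' Parse an experiment log from CSV or JSONL
#'
#' @param path path to a CSV (header row) or JSON-lines file.
#' @param mapping optional column mapping: a named character vector
#'   `c(native_field = "source_column")`, or the path of a flat
#'   `key=value` mapping file. Unmapped native fields are read from columns
#'   of the same name.
#' @param mode,target,experiment_id experiment metadata (see
#'   [experiment_log()]).
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return an `experiment_log`.
#' @export
parse_log <- function(path, mapping = NULL, mode = "collective",
                      target = NULL, experiment_id = NULL,
                      format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  } else {
    rows <- lapply(readLines(path, warn = FALSE), function(l) {
      if (!nzchar(trimws(l))) return(NULL)
      x <- jsonlite::fromJSON(l)
      x[vapply(x, is.null, logical(1))] <- NA
      as.data.frame(x, stringsAsFactors = FALSE)
    })
    dplyr::bind_rows(rows)
  }
  if (!is.null(mapping)) {
    if (is.character(mapping) && is.null(names(mapping)) &&
        length(mapping) == 1 && file.exists(mapping)) {
      mapping <- .read_mapping_file(mapping)
    }
    for (fld in names(mapping)) {
      src <- mapping[[fld]]
      if (!src %in% names(raw)) {
        stop("mapped source column not found: ", src)
      }
      raw[[fld]] <- raw[[src]]
    }
  }
  if (is.null(experiment_id)) {
    experiment_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  }
  experiment_log(raw, mode = mode, target = target,
                 experiment_id = experiment_id)
}

.read_mapping_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(
    vapply(kv, function(x) trimws(x[2]), character(1)),
    vapply(kv, function(x) trimws(x[1]), character(1))
  )
}

#' Write an experiment log in the native schema
#'
#' @param log an `experiment_log`.
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  ev <- log$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (format == "csv") {
    utils::write.csv(ev, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(ev))) {
      writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' Assign design sessions to events
#'
#' A design session is a contiguous editing chain by one participant. An
#' event opens a new session iff it starts from scratch (no parent), its
#' parent was created by someone else, or its parent is not the most recent
#' molecule this participant had created at that moment; otherwise it
#' continues its parent's session.
#'
#' @param log an `experiment_log`.
#' @return a tibble `event_id`, `participant_id`, `session_id` in event
#'   order.
#' @export
assign_sessions <- function(log) {
  ev <- log$events
  n <- nrow(ev)
  session <- character(n)
  next_session <- 1L
  last_own <- list()   # participant -> event_id of their latest event
  sess_of <- list()    # event_id -> session_id
  pidx <- match(ev$parent_event_id, ev$event_id)
  for (i in seq_len(n)) {
    p <- ev$participant_id[i]
    parent_i <- pidx[i]
    new_sess <-
      is.na(parent_i) ||
      ev$participant_id[parent_i] != p ||
      is.null(last_own[[p]]) ||
      ev$event_id[parent_i] != last_own[[p]]
    if (new_sess) {
      session[i] <- sprintf("s%04d", next_session)
      next_session <- next_session + 1L
    } else {
      session[i] <- sess_of[[ev$event_id[parent_i]]]
    }
    sess_of[[ev$event_id[i]]] <- session[i]
    last_own[[p]] <- ev$event_id[i]
  }
  tibble::tibble(event_id = ev$event_id,
                 participant_id = ev$participant_id,
                 session_id = session)
}

#' Provenance path of an event
#'
#' Follows parent pointers from the focal event back to its scratch root.
#'
#' @param log an `experiment_log`.
#' @param event_id focal event identifier.
#' @param sessions optional precomputed [assign_sessions()] result.
#' @return a list with `event_ids` (root to focal), `creators` (distinct,
#'   in order of first appearance), and `session_sequence` (ordered distinct
#'   session ids along the path).
#' @export
provenance_path <- function(log, event_id, sessions = NULL) {
  ev <- log$events
  idx <- match(event_id, ev$event_id)
  if (is.na(idx)) stop("event not found: ", event_id)
  pidx <- match(ev$parent_event_id, ev$event_id)
  chain <- integer(0)
  seen <- logical(nrow(ev))
  i <- idx
  while (!is.na(i)) {
    if (seen[i]) stop("cycle detected in parent pointers (corrupt log)")
    seen[i] <- TRUE
    chain <- c(i, chain)
    i <- pidx[i]
  }
  if (is.null(sessions)) sessions <- assign_sessions(log)
  sess <- sessions$session_id[match(ev$event_id[chain], sessions$event_id)]
  list(
    event_ids = ev$event_id[chain],
    creators = unique(ev$participant_id[chain]),
    session_sequence = unique(sess)
  )
}
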