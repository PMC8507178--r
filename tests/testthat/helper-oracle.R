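# Independent brute-force re-implementations of the experiment metrics.
# Written deliberately without incremental state or shared code with the
# package's metric functions: every quantity is recomputed from first
# principles on the ordered event table.

oracle_max_score <- function(log) {
  best <- -Inf
  for (s in log$events$score) if (s > best) best <- s
  as.integer(best)
}

oracle_scoring_calls <- function(log) nrow(log$events)

oracle_time_played <- function(log, threshold = 60) {
  ev <- log$events
  total <- 0
  per <- c()
  for (p in unique(ev$participant_id)) {
    tt <- sort(as.numeric(ev$timestamp[ev$participant_id == p]))
    acc <- 0
    if (length(tt) > 1) {
      for (i in 2:length(tt)) {
        gap <- tt[i] - tt[i - 1]
        if (gap <= threshold) acc <- acc + gap
      }
    }
    per[p] <- acc
    total <- total + acc
  }
  list(per = per, total = total)
}

# leader changes: strict running-maximum improvements; a change whenever the
# improver differs from the previous improver
oracle_leader_changes <- function(log) {
  ev <- log$events
  imp <- c()
  for (i in seq_len(nrow(ev))) {
    prev_max <- if (i == 1) -Inf else max(ev$score[1:(i - 1)])
    if (ev$score[i] > prev_max || i == 1) imp <- c(imp, i)
  }
  creators <- ev$participant_id[imp]
  changes <- 0L
  if (length(creators) > 1) {
    for (j in 2:length(creators)) {
      if (creators[j] != creators[j - 1]) changes <- changes + 1L
    }
  }
  list(changes = changes, forefront = unique(creators))
}

# second implementation of the session-opening predicate
oracle_sessions <- function(log) {
  ev <- log$events
  n <- nrow(ev)
  opens <- logical(n)
  for (i in seq_len(n)) {
    p <- ev$parent_event_id[i]
    if (is.na(p)) { opens[i] <- TRUE; next }
    j <- which(ev$event_id == p)
    if (ev$participant_id[j] != ev$participant_id[i]) {
      opens[i] <- TRUE; next
    }
    own_before <- which(ev$participant_id == ev$participant_id[i] &
                          seq_len(n) < i)
    opens[i] <- length(own_before) == 0 || max(own_before) != j
  }
  # session id per event: nearest opening event reachable by parent pointers
  sess <- integer(n)
  open_idx <- cumsum(opens)
  for (i in seq_len(n)) {
    j <- i
    while (!opens[j]) j <- which(ev$event_id == ev$parent_event_id[j])
    sess[i] <- open_idx[j]
  }
  list(opens = opens, n_sessions = sum(opens), session = sess)
}

oracle_path <- function(log, event_id) {
  ev <- log$events
  chain <- c()
  i <- which(ev$event_id == event_id)
  repeat {
    chain <- c(i, chain)
    p <- ev$parent_event_id[i]
    if (is.na(p)) break
    i <- which(ev$event_id == p)
  }
  chain
}

oracle_evolution_steps <- function(log, event_id) {
  sess <- oracle_sessions(log)$session
  length(unique(sess[oracle_path(log, event_id)]))
}

oracle_collaboration <- function(log, event_id) {
  ev <- log$events
  creators <- unique(ev$participant_id[oracle_path(log, event_id)])
  100 * length(creators) / length(unique(ev$participant_id))
}

# pairwise-comparison uniqueness count (quadratic, no hashing/grouping)
oracle_unique_count <- function(keys) {
  classes <- 0L
  for (i in seq_along(keys)) {
    dup <- FALSE
    if (i > 1) for (j in 1:(i - 1)) if (keys[j] == keys[i]) dup <- TRUE
    if (!dup) classes <- classes + 1L
  }
  classes
}

oracle_scaffold_ratio <- function(log) {
  rec <- canonicalize(log$events$smiles)
  keys <- rec$inchikey[rec$valid]
  smis <- rec$smiles_canonical[rec$valid]
  uniq_smis <- c(); seen <- c()
  for (i in seq_along(keys)) {
    if (!(keys[i] %in% seen)) { seen <- c(seen, keys[i]); uniq_smis <- c(uniq_smis, smis[i]) }
  }
  scafs <- c()
  for (s in uniq_smis) scafs <- c(scafs, murcko_scaffold(s))
  oracle_unique_count(scafs) / length(uniq_smis)
}
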