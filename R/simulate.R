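# Score-guided agent-based search simulator.
#
# The simulator emulates the structure of the human experiments, not human
# cognition: agents take turns editing molecules at the atom/bond level,
# guided only by the normalized similarity score to a hidden target. Each
# move either restarts from scratch (a single carbon) or picks a parent
# from the visible pool - the agent's own saved molecules in individual
# mode, everyone's in collective mode - by a softmax over scores, then
# applies a few random valence-valid edits. Every event records creator,
# timestamp, parent pointer and score, so simulated logs have exactly the
# provenance and session structure the metric suite assumes.
#
# Reproducibility: one master seed spawns one L'Ecuyer-CMRG substream per
# agent, so a run is bit-identical for a given (config, seed) and adding an
# agent does not perturb the others' private randomness.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: seven engaged participants per
#' experiment (the reported mean engagement), score-guided incremental
#' editing with occasional scratch restarts, and inter-event gaps drawn
#' from a two-component mixture (short in-session gaps up to a minute,
#' occasional longer idle gaps) so the idle filter of time-played is
#' exercised.
#'
#' @param n_agents number of agents (default 7).
#' @param mode `"individual"` or `"collective"` visibility.
#' @param target_smiles the hidden target molecule.
#' @param max_events stop after this many events if the target is not found.
#' @param seed master seed.
#' @param restart_probability per-move probability of starting from scratch.
#' @param selection_greediness inverse softmax temperature on score/1000.
#' @param edits_per_move integer range of edits applied per move.
#' @param element_alphabet elements available to the edit operations.
#' @param max_heavy_atoms molecule size cap.
#' @param gap_short_range,gap_long_range,gap_long_prob inter-event gap
#'   mixture (seconds).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_agents = 7L,
                              mode = c("collective", "individual"),
                              target_smiles = "CCOC(=O)c1ccccc1",
                              max_events = 2000L,
                              seed = 1L,
                              restart_probability = 0.05,
                              selection_greediness = 20,
                              edits_per_move = 1L,
                              element_alphabet = c("C", "N", "O", "S",
                                                   "F", "Cl"),
                              max_heavy_atoms = 60L,
                              gap_short_range = c(5, 45),
                              gap_long_range = c(90, 600),
                              gap_long_prob = 0.1) {
  mode <- match.arg(mode)
  stopifnot(n_agents >= 1, max_events >= n_agents,
            restart_probability >= 0, restart_probability <= 1,
            selection_greediness >= 0)
  structure(
    list(n_agents = as.integer(n_agents), mode = mode,
         target_smiles = target_smiles, max_events = as.integer(max_events),
         seed = as.integer(seed),
         restart_probability = restart_probability,
         selection_greediness = selection_greediness,
         edits_per_move = as.integer(edits_per_move),
         element_alphabet = element_alphabet,
         max_heavy_atoms = as.integer(max_heavy_atoms),
         gap_short_range = gap_short_range,
         gap_long_range = gap_long_range,
         gap_long_prob = gap_long_prob),
    class = "simulation_config"
  )
}

#' An easy packaged target for desk-scale simulations
#'
#' Ethyl glycolate: eight heavy atoms, no ring, reachable by short edit
#' sequences from a single carbon.
#'
#' @return a SMILES string.
#' @export
easy_target <- function() "CCOC(=O)CO"

# --- edit operations -------------------------------------------------------

# free valence of each atom (implicit hydrogens that could become bonds)
.free_valence <- function(g) g$nH

# Apply one randomly chosen edit operation to a raw graph copy.
# Returns the raw (unfinalized) edited graph or NULL when the sampled
# operation is not applicable at the sampled site.
.apply_random_edit <- function(g, alphabet, max_heavy) {
  n <- length(g$elem)
  kinds <- c("add_atom", "remove_terminal_atom", "change_bond_order",
             "form_ring_bond", "break_ring_bond", "substitute_element")
  kind <- sample(kinds, 1)
  raw <- list(elem = g$elem, charge = g$charge, bonds = g$bonds,
              extraH = integer(n))
  free <- .free_valence(g)
  switch(kind,
    add_atom = {
      if (n >= max_heavy) return(NULL)
      sites <- which(free >= 1)
      if (length(sites) == 0) return(NULL)
      a <- sites[sample.int(length(sites), 1)]
      raw$elem <- c(raw$elem, sample(alphabet, 1))
      raw$charge <- c(raw$charge, 0L)
      raw$extraH <- c(raw$extraH, 0L)
      raw$bonds <- rbind(raw$bonds, c(n + 1L, a, 1L))
      raw
    },
    remove_terminal_atom = {
      if (n <= 1) return(NULL)
      term <- which(g$degree == 1)
      if (length(term) == 0) return(NULL)
      a <- term[sample.int(length(term), 1)]
      keep <- setdiff(seq_len(n), a)
      .subgraph(g, keep)
    },
    change_bond_order = {
      if (nrow(g$bonds) == 0) return(NULL)
      b <- sample.int(nrow(g$bonds), 1)
      delta <- sample(c(-1L, 1L), 1)
      new_order <- g$bonds[b, 3] + delta
      if (new_order < 1 || new_order > 3) return(NULL)
      raw$bonds[b, 3] <- new_order
      raw
    },
    form_ring_bond = {
      if (n < 3) return(NULL)
      sites <- which(free >= 1)
      if (length(sites) < 2) return(NULL)
      a <- sites[sample.int(length(sites), 1)]
      partners <- setdiff(sites, c(a, g$adj[[a]]))
      if (length(partners) == 0) return(NULL)
      b <- partners[sample.int(length(partners), 1)]
      raw$bonds <- rbind(raw$bonds, c(a, b, 1L))
      raw
    },
    break_ring_bond = {
      rb <- which(g$ring_bond)
      if (length(rb) == 0) return(NULL)
      b <- rb[sample.int(length(rb), 1)]
      raw$bonds <- raw$bonds[-b, , drop = FALSE]
      raw
    },
    substitute_element = {
      a <- sample.int(n, 1)
      choices <- setdiff(alphabet, g$elem[a])
      if (length(choices) == 0) return(NULL)
      raw$elem[a] <- sample(choices, 1)
      raw
    }
  )
}

#' Apply one random valence-valid edit to a molecule
#'
#' Samples an edit operation (atom addition/removal, bond-order change,
#' ring closure/opening, element substitution), applies it and sanitizes
#' the result; inapplicable or valence-breaking edits are resampled up to
#' `max_retries` times. Draws from the current RNG state, so seeded runs
#' are reproducible.
#'
#' @param mol a `molgraph` or SMILES string.
#' @param config a [simulation_config()].
#' @param max_retries resampling budget.
#' @return a valid `molgraph`; if the retry budget is exhausted the input
#'   is returned unchanged with attribute `exhausted = TRUE`.
#' @export
mutate_molecule <- function(mol, config = simulation_config(),
                            max_retries = 20L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molgraph"))
  for (i in seq_len(max_retries)) {
    raw <- .apply_random_edit(mol, config$element_alphabet,
                              config$max_heavy_atoms)
    if (is.null(raw)) next
    cand <- finalize_molgraph(raw)
    if (!cand$valence_ok) next
    if (length(unique(.components(length(cand$elem), cand$adj))) != 1) next
    if (length(cand$elem) > config$max_heavy_atoms) next
    if (!any(cand$elem == "C")) next
    return(cand)
  }
  attr(mol, "exhausted") <- TRUE
  mol
}

.single_carbon <- function() {
  finalize_molgraph(list(elem = "C", charge = 0L,
                         bonds = matrix(integer(0), ncol = 3),
                         extraH = 0L))
}

# --- the simulator ---------------------------------------------------------

#' Simulate one design experiment
#'
#' Agents act in round-robin. Each move restarts from scratch with
#' probability `restart_probability` (parent `NA`, seed molecule a single
#' carbon) or selects a parent from the visible pool by softmax over
#' normalized scores, then applies 1-3 random edits. Each event is scored
#' against the target; the run stops when the drawn molecule's InChIKey
#' equals the target's, or at `max_events`.
#'
#' @param config a [simulation_config()].
#' @return an `experiment_log` whose events carry canonical SMILES; the
#'   config (including the seed) is attached as attribute `config`,
#'   and `target_found` records the stop reason.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  target <- parse_smiles(config$target_smiles)
  if (is.null(target)) stop("target SMILES does not parse")
  target_fp <- count_fingerprint(target)
  target_key <- .ob_inchikey(config$target_smiles)

  old_kind <- RNGkind("L'Ecuyer-CMRG")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    RNGkind(old_kind[1])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  streams <- vector("list", config$n_agents)
  s <- get(".Random.seed", globalenv())
  for (a in seq_len(config$n_agents)) {
    s <- parallel::nextRNGStream(s)
    streams[[a]] <- s
  }

  n_max <- config$max_events
  graphs <- vector("list", n_max)
  creator <- integer(n_max)
  parent <- rep(NA_integer_, n_max)
  score <- integer(n_max)
  tstamp <- numeric(n_max)
  clock <- 0                             # global clock, seconds
  n_ev <- 0L
  found <- FALSE
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")

  repeat {
    for (a in seq_len(config$n_agents)) {
      if (n_ev >= n_max || found) break
      assign(".Random.seed", streams[[a]], globalenv())

      visible <- if (config$mode == "collective") {
        seq_len(n_ev)
      } else {
        which(creator[seq_len(n_ev)] == a)
      }
      restart <- length(visible) == 0 ||
        stats::runif(1) < config$restart_probability
      if (restart) {
        par_idx <- NA_integer_
        base <- .single_carbon()
      } else {
        w <- exp(config$selection_greediness *
                   score[visible] / 1000)
        par_idx <- visible[sample.int(length(visible), 1, prob = w)]
        base <- graphs[[par_idx]]
      }
      k <- if (length(config$edits_per_move) == 1) {
        config$edits_per_move
      } else {
        sample(config$edits_per_move, 1)
      }
      mol <- base
      for (i in seq_len(k)) mol <- mutate_molecule(mol, config)

      sim <- tanimoto_count(count_fingerprint(mol), target_fp)
      sc <- .round_half_up(1000 * sim)
      gap <- if (stats::runif(1) < config$gap_long_prob) {
        stats::runif(1, config$gap_long_range[1], config$gap_long_range[2])
      } else {
        stats::runif(1, config$gap_short_range[1], config$gap_short_range[2])
      }
      clock <- clock + gap
      n_ev <- n_ev + 1L
      graphs[[n_ev]] <- mol
      creator[n_ev] <- a
      parent[n_ev] <- par_idx
      score[n_ev] <- sc
      tstamp[n_ev] <- clock
      streams[[a]] <- get(".Random.seed", globalenv())

      if (sc == 1000L) {
        key <- .ob_inchikey(molgraph_to_smiles(graphs[n_ev]))
        if (!is.na(key) && key == target_key) found <- TRUE
      }
    }
    if (n_ev >= n_max || found) break
  }

  idx <- seq_len(n_ev)
  smiles <- molgraph_to_smiles(graphs[idx])
  ids <- sprintf("e%05d", idx)
  ev <- tibble::tibble(
    event_id = ids,
    timestamp = t0 + tstamp[idx],
    participant_id = sprintf("agent%02d", creator[idx]),
    smiles = smiles,
    parent_event_id = ifelse(is.na(parent[idx]), NA_character_,
                             ids[parent[idx]]),
    score = score[idx]
  )
  log <- experiment_log(ev, mode = config$mode,
                        target = config$target_smiles,
                        experiment_id = sprintf("sim-%s-seed%d",
                                                config$mode, config$seed))
  attr(log, "config") <- config
  attr(log, "target_found") <- found
  log
}

#' The packaged hand-authored fixture log
#'
#' A 27-event collective experiment by three participants searching for
#' toluene, authored so that every metric has a documented hand-derived
#' value (shipped alongside as `fixture_log_expected.json`). It contains
#' duplicate molecules, cross-creator branches, session re-openings, an
#' idle pause per participant and a found target whose provenance crosses
#' three sessions and two creators.
#'
#' @return an `experiment_log`.
#' @export
fixture_log <- function() {
  path <- system.file("extdata", "fixture_log.csv", package = "molsearch")
  parse_log(path, mode = "collective", target = "Cc1ccccc1",
            experiment_id = "fixture")
}

#' Hand-derived expectations for the fixture log
#'
#' @return the parsed expectations list.
#' @export
fixture_expectations <- function() {
  path <- system.file("extdata", "fixture_log_expected.json",
                      package = "molsearch")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
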