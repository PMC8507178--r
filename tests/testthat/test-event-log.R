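test_that("a well-formed CSV parses with no warnings", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "event_id,timestamp,participant_id,smiles,parent_event_id,score",
    "a1,2021-03-01T10:00:00,u1,CCO,,100",
    "a2,2021-03-01T10:00:30,u1,CCN,a1,200",
    "a3,2021-03-01T10:01:00,u2,CCC,,150"
  ), path)
  log <- parse_log(path, mode = "collective")
  expect_s3_class(log, "experiment_log")
  expect_equal(nrow(log$events), 3L)
  expect_equal(log$validation$n_dangling_parents, 0L)
  expect_equal(log$participants, c("u1", "u2"))
})

test_that("dangling parents warn and become scratch starts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "event_id,timestamp,participant_id,smiles,parent_event_id,score",
    "a1,2021-03-01T10:00:00,u1,CCO,,100",
    "a2,2021-03-01T10:00:30,u1,CCN,zz,200"
  ), path)
  expect_warning(log <- parse_log(path), "dangling")
  expect_true(is.na(log$events$parent_event_id[2]))
  expect_equal(log$validation$n_dangling_parents, 1L)
})

test_that("a missing mandatory column is named in the error", {
  bad <- tibble::tibble(event_id = "a", timestamp = "2021-01-01T00:00:00",
                        participant_id = "u", smiles = "C")
  expect_error(experiment_log(bad), "parent_event_id")
})

test_that("mapping config adapts foreign column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,when,who,structure,from,points",
    "a1,2021-03-01T10:00:00,u1,CCO,,100",
    "a2,2021-03-01T10:00:30,u1,CCN,a1,200"
  ), path)
  mapping <- c(event_id = "id", timestamp = "when", participant_id = "who",
               smiles = "structure", parent_event_id = "from",
               score = "points")
  log <- parse_log(path, mapping = mapping)
  expect_equal(log$events$smiles, c("CCO", "CCN"))
  # the same mapping from a flat key=value file
  mpath <- withr::local_tempfile(fileext = ".cfg")
  writeLines(paste0(names(mapping), "=", mapping), mpath)
  log2 <- parse_log(path, mapping = mpath)
  expect_equal(log2$events, log$events)
  expect_error(parse_log(path, mapping = c(score = "absent_column")),
               "absent_column")
})

test_that("write/parse round-trips are lossless in CSV and JSONL", {
  log <- fixture_log()
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_log(log, path, format = fmt)
    back <- parse_log(path, mode = log$mode, target = "Cc1ccccc1")
    expect_equal(back$events, log$events)
  }
})

test_that("timestamp ties are broken deterministically by event id", {
  ev <- tibble::tibble(
    event_id = c("b", "a", "c"),
    timestamp = rep("2021-03-01T10:00:00", 3),
    participant_id = c("u1", "u1", "u2"),
    smiles = c("CC", "C", "CCC"),
    parent_event_id = c("a", NA, NA),
    score = c(2L, 1L, 3L)
  )
  log1 <- experiment_log(ev)
  log2 <- experiment_log(ev[c(3, 1, 2), ])
  expect_equal(log1$events$event_id, c("a", "b", "c"))
  expect_equal(log1$events, log2$events)
})

test_that("session segmentation follows the session-opening rule", {
  # one participant chaining on their latest molecule: one session
  chain <- make_log(rep("u1", 3), c("C", "CC", "CCC"), c(1, 2, 3),
                    parent = c(NA, 1, 2))
  s <- assign_sessions(chain)
  expect_equal(length(unique(s$session_id)), 1L)
  # re-opening an older own molecule starts a new session
  reopen <- make_log(rep("u1", 3), c("C", "CC", "CC(C)C"), c(1, 2, 3),
                     parent = c(NA, 1, 1))
  expect_equal(length(unique(assign_sessions(reopen)$session_id)), 2L)
  # branching from another participant's molecule starts a new session
  cross <- make_log(c("u1", "u2"), c("C", "CC"), c(1, 2), parent = c(NA, 1))
  expect_equal(length(unique(assign_sessions(cross)$session_id)), 2L)
})

test_that("fixture sessions equal the hand-derived assignment", {
  log <- fixture_log()
  exp <- fixture_expectations()
  s <- assign_sessions(log)
  expect_equal(s$session_id, unname(unlist(exp$sessions)[s$event_id]))
})

test_that("provenance paths track creators and sessions", {
  root <- make_log("u1", "C", 1)
  p <- provenance_path(root, "e001")
  expect_equal(p$event_ids, "e001")
  expect_equal(p$creators, "u1")
  # a chain of five events by two alternating creators
  alt <- make_log(c("u1", "u2", "u1", "u2", "u1"),
                  c("C", "CC", "CCC", "CCCC", "CCCCC"),
                  1:5, parent = c(NA, 1, 2, 3, 4))
  p5 <- provenance_path(alt, "e005")
  expect_equal(length(p5$event_ids), 5L)
  expect_equal(sort(p5$creators), c("u1", "u2"))
  expect_error(provenance_path(alt, "nope"), "not found")
})

test_that("fixture target provenance matches its documented path", {
  log <- fixture_log()
  exp <- fixture_expectations()
  p <- provenance_path(log, exp$target_event_id)
  expect_equal(p$event_ids, exp$target_path_event_ids)
  expect_equal(p$creators, exp$target_path_creators)
  expect_equal(length(p$session_sequence), exp$target_evolution_steps)
})

test_that("cycles in parent pointers are detected as corrupt", {
  ev <- tibble::tibble(
    event_id = c("a", "b"),
    timestamp = c("2021-03-01T10:00:00", "2021-03-01T10:00:30"),
    participant_id = "u1",
    smiles = c("C", "CC"),
    parent_event_id = c("b", "a"),
    score = c(1L, 2L)
  )
  log <- suppressWarnings(experiment_log(ev))
  expect_error(provenance_path(log, "b"), "cycle")
})

test_that("individual-mode provenance paths have a single creator", {
  cfg <- simulation_config(n_agents = 3, mode = "individual",
                           target_smiles = easy_target(),
                           max_events = 60, seed = 5)
  sim <- simulate_experiment(cfg)
  sessions <- assign_sessions(sim)
  for (id in sample(sim$events$event_id, 10)) {
    expect_length(provenance_path(sim, id, sessions)$creators, 1)
  }
})
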