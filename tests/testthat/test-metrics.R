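test_that("max score and scoring calls count events as played", {
  log <- make_log(c("u1", "u2", "u1"), c("C", "CC", "CCC"),
                  c(10, 500, 430))
  expect_equal(max_score(log), 500L)
  expect_equal(scoring_calls(log), 3L)
  single <- make_log("u1", "CCO", 77)
  expect_equal(max_score(single), 77L)
  # the same structure redrawn five times contributes five calls
  dup <- make_log(rep("u1", 5), rep("CCO", 5), rep(10, 5),
                  parent = c(NA, 1, 2, 3, 4))
  expect_equal(scoring_calls(dup), 5L)
  expect_equal(as.integer(unique_molecule_count(dup$events$smiles)), 1L)
  empty <- experiment_log(tibble::tibble(
    event_id = character(0), timestamp = character(0),
    participant_id = character(0), smiles = character(0),
    parent_event_id = character(0), score = integer(0)))
  expect_equal(scoring_calls(empty), 0L)
  expect_error(max_score(empty), "empty")
  expect_error(metrics_report(empty), "empty")
})

test_that("time played keeps sub-minute gaps and drops idle frames", {
  log <- make_log(rep("u1", 3), c("C", "CC", "CCC"), c(1, 2, 3),
                  offset = c(0, 30, 120))
  tp <- time_played(log)
  expect_equal(tp$total_seconds, 30)
  expect_equal(time_played(make_log("u1", "C", 1))$total_seconds, 0)
  # two participants, one 45 s gap each, summed over participants
  two <- make_log(c("u1", "u1", "u2", "u2"), c("C", "CC", "CCC", "CCCC"),
                  1:4, offset = c(0, 45, 10, 55))
  expect_equal(time_played(two)$total_seconds, 90)
  # a gap of exactly the threshold is kept; strictly greater is dropped
  edge <- make_log(rep("u1", 3), c("C", "CC", "CCC"), 1:3,
                   offset = c(0, 60, 121))
  expect_equal(time_played(edge)$total_seconds, 60)
})

test_that("scaffold/molecule ratio counts framework classes per molecule", {
  pair <- make_log(c("u1", "u1"), c("Cc1ccccc1", "CCc1ccccc1"), c(1, 2))
  expect_equal(scaffold_molecule_ratio(pair), 0.5)
  expect_equal(scaffold_molecule_ratio(pair, invert = TRUE), 2)
  distinct <- make_log(rep("u1", 3),
                       c("c1ccccc1", "c1ccncc1", "C1CCCCC1"), 1:3)
  expect_equal(scaffold_molecule_ratio(distinct), 1.0)
  # all-acyclic logs share the single sentinel scaffold class
  acyclic <- make_log(rep("u1", 4), c("C", "CC", "CCO", "CCN"), 1:4)
  expect_equal(scaffold_molecule_ratio(acyclic), 0.25)
})

test_that("leader changes follow the strict running-maximum scan", {
  log <- make_log(c("A", "B", "A", "A", "C"),
                  c("C", "CC", "CCC", "CCCC", "CCCCC"),
                  c(10, 20, 30, 40, 50))
  lead <- leader_changes(log)
  expect_equal(lead$changes, 3L)
  expect_equal(sort(lead$forefront_creators), c("A", "B", "C"))
  expect_equal(lead$forefront_participation_pct, 100)
  solo <- make_log(rep("u1", 4), c("C", "CC", "CCC", "CCCC"),
                   c(5, 10, 7, 20))
  expect_equal(leader_changes(solo)$changes, 0L)
  # ties do not overtake: strict improvement is required
  tie <- make_log(c("A", "B"), c("C", "CC"), c(10, 10))
  expect_equal(leader_changes(tie)$changes, 0L)
})

test_that("evolution steps count distinct sessions along the path", {
  scratch <- make_log(rep("u1", 2), c("C", "CC"), c(1, 2),
                      parent = c(NA, 1))
  expect_equal(evolution_steps(scratch, "e002"), 1L)
  log <- fixture_log()
  exp <- fixture_expectations()
  expect_equal(evolution_steps(log, exp$target_event_id),
               exp$target_evolution_steps)
})

test_that("collaboration degree is the path-creator share of participants", {
  # one creator's path among five engaged participants: 20 %
  log <- make_log(c("A", "B", "C", "D", "E", "A"),
                  c("C", "CC", "CCC", "CCCC", "CCCCC", "CCO"),
                  1:6, parent = c(NA, NA, NA, NA, NA, 1))
  expect_equal(collaboration_degree(log, "e006"), 20)
  fix <- fixture_log()
  exp <- fixture_expectations()
  expect_equal(collaboration_degree(fix, exp$target_event_id),
               exp$target_collaboration_pct)
})

test_that("the fixture metrics report equals its expectations field for field", {
  rep <- metrics_report(fixture_log())
  exp <- fixture_expectations()
  expect_equal(rep$max_score, exp$max_score)
  expect_equal(rep$unique_molecules, exp$unique_molecules)
  expect_equal(rep$scoring_calls, exp$scoring_calls)
  expect_equal(rep$invalid_events, exp$invalid_events)
  expect_equal(rep$n_participants, exp$n_participants)
  expect_equal(rep$time_played_seconds, exp$time_played_seconds)
  expect_equal(rep$scaffold_molecule_ratio, exp$scaffold_molecule_ratio)
  expect_equal(rep$leader_changes, exp$leader_changes)
  expect_equal(rep$forefront_participation_pct,
               exp$forefront_participation_pct)
  expect_equal(rep$target_found, exp$target_found)
  expect_equal(rep$target_event_id, exp$target_event_id)
  expect_equal(rep$target_evolution_steps, exp$target_evolution_steps)
  expect_equal(rep$target_collaboration_pct, exp$target_collaboration_pct)
  tp <- time_played(fixture_log())$per_participant
  expect_equal(as.list(tp), exp$time_played_by_participant)
})

test_that("target detection requires the target's InChIKey, not just 1000", {
  # a 1000-scoring event that is not the target molecule must not count
  log <- make_log(c("u1", "u2"), c("CCO", "CCN"), c(1000, 900),
                  target = "Cc1ccccc1")
  rep <- metrics_report(log)
  expect_false(rep$target_found)
  expect_null(rep$target_evolution_steps)
  expect_null(rep$target_collaboration_pct)
  # spelled differently, the target still matches by InChIKey
  found <- make_log("u1", "c1ccccc1C", 1000, target = "Cc1ccccc1")
  expect_true(metrics_report(found)$target_found)
})

test_that("metrics are invariant under same-timestamp input permutations", {
  ev <- tibble::tibble(
    event_id = sprintf("e%02d", 1:6),
    timestamp = rep("2021-03-01T10:00:00", 6),
    participant_id = c("A", "B", "A", "C", "B", "A"),
    smiles = c("C", "CC", "CCC", "c1ccccc1", "CCO", "OCC"),
    parent_event_id = c(NA, NA, "e01", NA, "e02", "e03"),
    score = c(10L, 40L, 30L, 80L, 20L, 50L)
  )
  set.seed(13)
  base <- metrics_report(experiment_log(ev, target = "c1ccccc1"))
  for (i in 1:3) {
    perm <- metrics_report(experiment_log(ev[sample(6), ],
                                          target = "c1ccccc1"))
    expect_equal(perm[names(perm) != "config"],
                 base[names(base) != "config"])
  }
})

test_that("leader and forefront bounds hold on simulated logs", {
  for (seed in 1:3) {
    cfg <- simulation_config(n_agents = 3, mode = "collective",
                             target_smiles = easy_target(),
                             max_events = 50, seed = seed)
    sim <- simulate_experiment(cfg)
    lead <- leader_changes(sim)
    expect_lte(lead$changes, scoring_calls(sim) - 1L)
    expect_gte(lead$forefront_participation_pct,
               100 / length(sim$participants))
    expect_lte(lead$forefront_participation_pct, 100)
  }
})
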