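test_that("canonicalization collapses SMILES spellings of one molecule", {
  rec <- canonicalize(c("OCC", "CCO"))
  expect_true(all(rec$valid))
  expect_equal(rec$smiles_canonical[1], rec$smiles_canonical[2])
  expect_equal(rec$inchikey[1], rec$inchikey[2])
  expect_match(rec$inchikey[1], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("canonicalization is idempotent on its own output", {
  rec <- canonicalize(five_drugs())
  rec2 <- canonicalize(rec$smiles_canonical)
  expect_equal(rec2$smiles_canonical, rec$smiles_canonical)
  expect_equal(rec2$inchikey, rec$inchikey)
  expect_equal(rec2$heavy_atom_count, rec$heavy_atom_count)
})

test_that("malformed or non-single-organic inputs yield invalid records", {
  bad <- c("C(", "C1CC", "", "not-a-smiles", "CCO.CCN", "[Na+]", "C)C")
  rec <- canonicalize(bad)
  expect_false(any(rec$valid))
  expect_true(all(is.na(rec$smiles_canonical)))
  expect_true(all(is.na(rec$inchikey)))
  expect_true(all(is.na(rec$heavy_atom_count)))
})

test_that("albuterol has 17 heavy atoms", {
  rec <- canonicalize(five_drugs()[["albuterol"]])
  expect_true(rec$valid)
  expect_equal(rec$heavy_atom_count, 17L)
})

test_that("unique molecule counting follows InChIKey equivalence", {
  expect_equal(as.integer(unique_molecule_count(c("CCO", "OCC"))), 1L)
  expect_equal(as.integer(unique_molecule_count(character(0))), 0L)
  expect_equal(as.integer(unique_molecule_count(c("CCO", "CCN", "CCO"))), 2L)
  mixed <- unique_molecule_count(c("CCO", "C(", "OCC"))
  expect_equal(as.integer(mixed), 1L)
  expect_equal(attr(mixed, "n_invalid"), 1L)
})

test_that("unique count equals brute-force pairwise InChIKey classes", {
  set.seed(11)
  for (rep in 1:3) {
    smis <- sample(small_pool(), 30, replace = TRUE)
    rec <- canonicalize(smis)
    expect_equal(as.integer(unique_molecule_count(smis)),
                 oracle_unique_count(rec$inchikey[rec$valid]))
  }
})

test_that("Murcko scaffolds strip side chains and share frameworks", {
  benzene <- murcko_scaffold("c1ccccc1")
  expect_equal(murcko_scaffold("Cc1ccccc1"), benzene)
  expect_equal(murcko_scaffold("CCc1ccccc1"), benzene)
  expect_equal(murcko_scaffold("CCO"), "")
  # side chains attached by a single bond vanish entirely
  expect_equal(murcko_scaffold("CC(=O)c1ccccc1"), benzene)
  # double bonds directly on the framework are retained
  expect_equal(murcko_scaffold("O=C(c1ccccc1)c1ccccc1"),
               canonicalize("O=C(c1ccccc1)c1ccccc1")$smiles_canonical)
})

test_that("scaffold is invariant under acyclic terminal decoration", {
  benzene <- murcko_scaffold("c1ccccc1")
  subs <- c("C", "CC", "CCC", "NC", "OC", "ClC", "CC(C)C", "OCC")
  set.seed(7)
  for (s in sample(subs, 6)) {
    expect_equal(murcko_scaffold(paste0(s, "c1ccccc1")), benzene)
  }
  # decorated pyridine keeps the pyridine framework
  pyr <- murcko_scaffold("c1ccncc1")
  expect_equal(murcko_scaffold("CCc1ccncc1"), pyr)
})

test_that("ring classification separates aromatic and aliphatic rings", {
  benz <- complexity_profile("c1ccccc1")
  expect_equal(benz$heavy_atoms, 6L)
  expect_equal(benz$aromatic_rings, 1L)
  expect_equal(benz$aliphatic_rings, 0L)
  hex <- complexity_profile("C1CCCCC1")
  expect_equal(hex$aromatic_rings, 0L)
  expect_equal(hex$aliphatic_rings, 1L)
})

test_that("complexity equivalence is strict equality on all five features", {
  drugs <- five_drugs()
  a <- complexity_profile(drugs[["albuterol"]])
  expect_true(complexity_equivalent(a, a))
  expect_false(complexity_equivalent(a, complexity_profile(drugs[["celecoxib"]])))
  tweaked <- a
  tweaked$total_fingerprints <- tweaked$total_fingerprints + 1L
  expect_false(complexity_equivalent(a, tweaked))
})

test_that("equivalent-target selection keeps matches in input order", {
  ref <- five_drugs()[["albuterol"]]
  expect_equal(select_equivalent_targets(ref, ref), ref)
  # benzene differs in heavy atoms, so it is excluded
  expect_length(select_equivalent_targets(ref, "c1ccccc1"), 0)
  # five candidates with exactly two profile matches (two spellings of the
  # reference molecule); brute-force comparison fixes the expectation
  spelling <- "OC(CNC(C)(C)C)c1ccc(O)c(CO)c1"
  cands <- c("c1ccccc1", spelling, "CCO", ref, "Cc1ccncc1")
  ref_prof <- complexity_profile(ref)
  brute <- cands[vapply(cands, function(s) {
    complexity_equivalent(complexity_profile(s), ref_prof)
  }, logical(1))]
  got <- select_equivalent_targets(ref, cands)
  expect_equal(got, brute)
  expect_equal(got, c(spelling, ref))
})
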