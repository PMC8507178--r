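# Shared molecule constants and a quick event-table builder.

five_drugs <- function() {
  c(albuterol = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
    celecoxib = "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1",
    thiothixene = "CN(C)S(=O)(=O)c1ccc2c(c1)C(=CCCN1CCN(C)CC1)c1ccccc1S2",
    aripiprazole = "O=C1CCc2ccc(OCCCCN3CCN(c4cccc(Cl)c4Cl)CC3)cc2N1",
    troglitazone = "Cc1c(C)c2c(c(C)c1O)CCC(C)(COc1ccc(CC3SC(=O)NC3=O)cc1)O2")
}

# Build an experiment log from compact vectors; offsets in seconds.
make_log <- function(participant, smiles, score,
                     parent = rep(NA_character_, length(smiles)),
                     offset = seq(0, by = 30, length.out = length(smiles)),
                     mode = "collective", target = NULL) {
  n <- length(smiles)
  ids <- sprintf("e%03d", seq_len(n))
  parent_ids <- ifelse(is.na(parent), NA_character_,
                       ids[match(parent, seq_len(n))])
  ev <- tibble::tibble(
    event_id = ids,
    timestamp = as.POSIXct("2021-03-01 09:00:00", tz = "UTC") + offset,
    participant_id = participant,
    smiles = smiles,
    parent_event_id = parent_ids,
    score = as.integer(score)
  )
  experiment_log(ev, mode = mode, target = target)
}

# A reusable pool of small valid molecules for randomized log construction.
small_pool <- function() {
  c("C", "CC", "CCC", "CCO", "OCC", "CCN", "CO", "CN", "CCCC", "CC(C)O",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "Cc1ccncc1",
    "C1CCCCC1", "c1ccsc1", "CC(=O)O", "CC(=O)C", "c1ccc2ccccc2c1")
}
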