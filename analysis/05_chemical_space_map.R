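#!/usr/bin/env Rscript
# Chemical-space map of an explored log.
#
# Embeds the unique molecules of one simulated collective log (fingerprint
# space, fixed-seed t-SNE) and writes the coordinates with participant and
# creation-order annotations - the two colourings used to compare how
# individual and collective searches spread over chemical space.

suppressMessages(library(molsearch))
dir.create("results", showWarnings = FALSE)

path <- "results/logs/sim_collective_seed01.csv"
if (!file.exists(path)) {
  cat("no simulated log found; run analysis/02_simulate_experiments.R first\n")
  quit(status = 0)
}
log <- parse_log(path, mode = "collective", target = easy_target())
emb <- embed_chemical_space(log, seed = 42, perplexity = 15)
print(utils::head(emb))
utils::write.csv(emb, "results/chemical_space_map.csv", row.names = FALSE)
cat("wrote", nrow(emb), "coordinates to results/chemical_space_map.csv\n")
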