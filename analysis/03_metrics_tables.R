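#!/usr/bin/env Rscript
# Experiment-level metric tables.
#
# Analyses the packaged fixture log plus the simulated logs from
# 02_simulate_experiments.R and renders the per-experiment metric rows
# (time played, unique molecules, scaffold/molecule ratio, leader
# changes, max score, evolution steps and collaboration degree for found
# targets) as JSON and markdown under results/.

suppressMessages(library(molsearch))
dir.create("results/reports", showWarnings = FALSE, recursive = TRUE)

reports <- list(metrics_report(fixture_log()))
analyze_log(fixture_log(), out_dir = "results/reports")

logs <- list.files("results/logs", pattern = "^sim_.*\\.csv$",
                   full.names = TRUE)
if (length(logs) == 0) {
  cat("no simulated logs found; run analysis/02_simulate_experiments.R first\n")
} else {
  for (path in logs[1:min(6, length(logs))]) {
    mode <- if (grepl("individual", path)) "individual" else "collective"
    rep <- analyze_log(path, target = easy_target(), mode = mode,
                       out_dir = "results/reports")
    reports[[length(reports) + 1]] <- rep
  }
}
md <- report_markdown(reports)
writeLines(md)
writeLines(md, "results/metrics_table.md")
cat("\nwrote results/metrics_table.md and per-experiment reports under results/reports/\n")
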