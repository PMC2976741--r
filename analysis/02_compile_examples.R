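#!/usr/bin/env Rscript

# Step 2: compile labeled examples from the strong cohort under all four
# window geometries and both compilation modes, mirroring the structure of
# the study's data-compilation stage: sparse hypotensive windows against a
# large control majority in multiple mode, and one example per record
# (hypotensive-first) in single mode.

suppressPackageStartupMessages(library(mapcast))

out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

recs <- simulate_cohort(fixture_cohort_config("strong", 120, seed = 20100))

rows <- list()
for (obs in c(30, 60)) {
  for (gap in c(60, 120)) {
    spec <- window_spec(obs, gap)
    for (mode in c("multiple", "single")) {
      tab <- compile_cohort(recs, spec, mode = mode, seed = 7)$table
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode, obs_min = obs, gap_min = gap,
        n_examples = nrow(tab),
        n_control = sum(tab$label == "control"),
        n_hypotensive = sum(tab$label == "hypotensive"),
        prevalence_pct = 100 * mean(tab$label == "hypotensive"))
    }
  }
}
counts <- do.call(rbind, rows)
write.csv(counts, file.path(out_dir, "example_counts.csv"), row.names = FALSE)
print(counts, row.names = FALSE)
cat("\nMultiple compilation keeps the natural class imbalance;",
    "single compilation (hypotensive-first) concentrates episode records.\n")
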