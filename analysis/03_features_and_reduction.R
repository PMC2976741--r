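#!/usr/bin/env Rscript

# Step 3: extract the 102-dimensional feature vectors for the default
# geometry and examine the PCA reduction: how many components carry ~90% of
# the variance, and which raw features load heaviest on the first
# components.

suppressPackageStartupMessages(library(mapcast))

out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

recs <- simulate_cohort(fixture_cohort_config("strong", 120, seed = 20100))
comp <- compile_cohort(recs, window_spec(30, 60), "multiple")
feats <- feature_matrix(comp$examples, recs)
cat(sprintf("feature matrix: %d examples x %d features\n",
            nrow(feats), ncol(feats)))

red <- suppressWarnings(fit_reducer(feats))
cat(sprintf("PCA on the full example set: %d components capture %.1f%%\n",
            red$k, 100 * red$cum_var_ratio))

# top loadings of the first three components
top <- do.call(rbind, lapply(1:3, function(j) {
  v <- red$loadings[, j]
  ord <- order(abs(v), decreasing = TRUE)[1:8]
  data.frame(component = j, feature = feature_names()[ord],
             loading = round(v[ord], 3))
}))
write.csv(top, file.path(out_dir, "pca_top_loadings.csv"), row.names = FALSE)
print(head(top, 16), row.names = FALSE)

# per-class separation of a few interpretable features
sel <- c("map_mean", "map_slope", "pp_mean", "map_sd", "wav_map_a5")
lab <- comp$table$label
sep <- data.frame(
  feature = sel,
  control_mean = round(colMeans(feats[lab == "control", sel]), 3),
  hypotensive_mean = round(colMeans(feats[lab == "hypotensive", sel]), 3))
write.csv(sep, file.path(out_dir, "feature_separation.csv"),
          row.names = FALSE)
print(sep, row.names = FALSE)
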