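#!/usr/bin/env Rscript

# Step 6: minute-by-minute continuous monitoring of held-out records with a
# trained classifier/regressor pair: one record containing hypotensive
# episodes and one without. Full traces go to scratch/ (bulky); a summary
# lands in results/analysis/.

suppressPackageStartupMessages(library(mapcast))

out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)

recs <- simulate_cohort(fixture_cohort_config("strong", 40, seed = 20100))
log <- attr(recs, "episode_log")

# train on the first 30 records, monitor held-out ones
train_ids <- names(recs)[1:30]
spec <- window_spec(30, 60)
comp <- compile_cohort(recs[train_ids], spec, "multiple")
feats <- feature_matrix(comp$examples, recs)
y <- as.numeric(comp$table$label == "hypotensive")
bal <- balance_by_subsampling(y, seed = 17)
red <- suppressWarnings(fit_reducer(feats[bal, ]))
clf <- train_classifier(apply_reducer(red, feats[bal, ]), y[bal], seed = 17)
reg <- train_regressor(apply_reducer(red, feats),
                       comp$table$target_median_map, seed = 17)

held <- setdiff(names(recs), train_ids)
with_ep <- intersect(held, unique(log$record_id))
without_ep <- setdiff(held, unique(log$record_id))
picks <- c(episodes = with_ep[1], quiet = without_ep[1])

summ <- list()
for (nm in names(picks)) {
  id <- picks[[nm]]
  if (is.na(id)) next
  rec <- recs[[id]]
  tr <- continuous_predict(rec, clf, reg, red, spec)
  write.csv(tr, sprintf("scratch/trace_%s_%s.csv", nm, id),
            row.names = FALSE)
  made <- !is.na(tr$probability)
  summ[[nm]] <- data.frame(
    record = id, kind = nm, minutes = nrow(tr),
    predictions = sum(made),
    no_prediction_pct = round(100 * mean(!made), 1),
    median_probability = round(median(tr$probability[made]), 3),
    max_probability = round(max(tr$probability[made]), 3),
    median_predicted_map = round(median(tr$predicted_map[made]), 1))
  cat(sprintf("%s record %s: %d/%d minutes predicted, median p=%.3f, max p=%.3f\n",
              nm, id, sum(made), nrow(tr),
              summ[[nm]]$median_probability, summ[[nm]]$max_probability))
  if (nm == "episodes") {
    o <- log$onset[log$record_id == id][1]
    pre <- tr$probability[(o - 60 + 1):o]
    cat(sprintf("  hour before first onset (min %d): max p=%.3f\n",
                o, max(pre, na.rm = TRUE)))
  }
}
write.csv(do.call(rbind, summ),
          file.path(out_dir, "monitoring_summary.csv"), row.names = FALSE)
cat("full traces (minute, probability, predicted_map, reason) under scratch/\n")
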