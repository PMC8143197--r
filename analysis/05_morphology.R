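#!/usr/bin/env Rscript
# Aggregate-morphology classification of all aggregate-bearing tracked
# neurons and the per-line statistics: class frequencies, between-line
# proportion tests, and Ordered-vs-Disordered comparisons of lifespan,
# onset time and aggregate lifespan.

suppressPackageStartupMessages({library(tauseedr); library(dplyr)})
dir.create("results", showWarnings = FALSE)

events <- read.csv("results/cell_events.csv")
measures <- readRDS("scratch/track_measures.rds")
if (!nrow(events)) stop("run analysis/03_single_cell_tracking.R first")

calls <- classify_cells(events, measures)
write.csv(calls, "results/morphology_calls.csv", row.names = FALSE)
cat("morphology calls:\n")
print(table(calls$label, calls$line))

st <- tryCatch(morphology_statistics(calls, events), error = function(e) {
  cat("statistics skipped:", conditionMessage(e), "\n"); NULL
})
if (!is.null(st)) {
  write.csv(st$proportions, "results/morphology_proportions.csv",
            row.names = FALSE)
  write.csv(st$comparisons, "results/morphology_comparisons.csv",
            row.names = FALSE)
  cat("per-line proportions (Unclassifiable excluded):\n")
  print(as.data.frame(st$proportions))
  cat("Ordered vs Disordered comparisons:\n")
  print(as.data.frame(st$comparisons))
}
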