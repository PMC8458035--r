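#!/usr/bin/env Rscript

# Ambient-RNA stress test: redistribute the reads of 10/20/40% of final
# barcodes as debris (after 20% doublet creation) and track mean recall
# of the matched-bulk genotype-aware demultiplexer across seeds.

library(demuxbench)

seeds <- 1:5
dir.create("results", showWarnings = FALSE)

rows <- list()
for (s in seeds) {
  for (f in c(0, 0.10, 0.20, 0.40)) {
    run <- run_scenario(scenario_config(doublet_fraction = 0.20,
                                        debris_fraction = f, seed = s))
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, debris_fraction = f,
      mean_recall = mean(run$metrics$recall),
      mean_precision = mean(run$metrics$precision, na.rm = TRUE))
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/debris_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summ <- aggregate(cbind(mean_recall, mean_precision) ~ debris_fraction,
                  tab, mean)
message("mean recall by debris level (", length(seeds), " seeds):")
print(summ, row.names = FALSE, digits = 4)
message("recall declines as ambient contamination grows: ",
        paste(round(summ$mean_recall, 3), collapse = " -> "))
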