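#!/usr/bin/env Rscript
# Disease-state dynamics: per-treatment state sequences over the eight
# time points, summary counts, and the compound-supported transition
# network.

library(toxds)

ds <- readRDS("results/states/assignment.rds")
cfg <- readRDS("results/cohort/config.rds")

sched <- expand.grid(compound = unique(sub("\\|.*", "",
                                           ds$assignment$condition)),
                     dose = cfg$doses, stringsAsFactors = FALSE)
seqs <- build_sequences(ds, sched, time_points = cfg$time_points)
summ <- sequence_summary(seqs)
graph <- transition_graph(seqs)

dir.create("results/dynamics", showWarnings = FALSE, recursive = TRUE)
utils::write.table(
  data.frame(treatment = rownames(seqs), seqs, check.names = FALSE),
  "results/dynamics/sequences.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(graph$edges, "results/dynamics/transitions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
igraph::write_graph(graph$graph, "results/dynamics/transitions.graphml",
                    format = "graphml")
jsonlite::write_json(summ, "results/dynamics/summary.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("%d treatments: %d (%d%%) reach a state, %d (%d%%) more than one\n",
            summ$n, summ$n_any_ds, summ$pct_any_ds, summ$n_multi_ds,
            summ$pct_multi_ds))
cat("transition edges surviving the 2-compound rule:", nrow(graph$edges), "\n")
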