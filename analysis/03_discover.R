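#!/usr/bin/env Rscript
# Call disease states: Pearson distance over normalized physiology, 25
# seeded t-SNE runs, severity smoothing on each map, DBSCAN over the
# severity-selected conditions, co-association consensus, and the
# size/compound filter. Scores recovery against the planted truth.

library(toxds)

norm <- readRDS("results/normalized/normalized.rds")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)$state_of_condition
truth <- unlist(truth)

ds <- discover_states(norm$phys, norm$calls, n_runs = 25, seed = 1)

dir.create("results/states", showWarnings = FALSE, recursive = TRUE)
utils::write.table(ds$assignment, "results/states/assignment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ds$runs, "results/states/runs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(condition = rownames(ds$coassoc), ds$coassoc,
             check.names = FALSE),
  "results/states/coassociation.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
saveRDS(ds, "results/states/assignment.rds")

ari <- label_ari(ds$assignment$label, truth[ds$assignment$condition])
sizes <- table(ds$assignment$label[ds$assignment$label > 0])
cat("recovered", length(sizes), "states with sizes",
    paste(sizes, collapse = ", "), "\n")
cat(sprintf("adjusted Rand index vs planted truth: %.3f\n", ari))
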