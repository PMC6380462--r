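#!/usr/bin/env Rscript
# Characterize each called disease state: physiology deviation (signed log
# q), histopathology enrichment, compound-class overrepresentation, and
# transcriptome separability by prevalidated elastic-net classification.

library(toxds)

norm <- readRDS("results/normalized/normalized.rds")
ds <- readRDS("results/states/assignment.rds")
classes <- utils::read.delim("results/cohort/compound_classes.tsv")
ed <- readRDS("results/normalized/expression_delta_liver.rds")

dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

phys_dev <- physiology_deviation(norm$phys, ds)
utils::write.table(phys_dev, "results/profiles/physiology_deviation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("physiology: ", sum(phys_dev$significant),
    "state/parameter pairs at q < 1e-10\n")

hist_enr <- histopath_enrichment(norm$calls, ds)
utils::write.table(hist_enr, "results/profiles/histopath_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("histopathology:", sum(hist_enr$significant),
    "state/phenotype pairs at q < 5e-3\n")

cls <- class_overrepresentation(classes, ds)
utils::write.table(cls, "results/profiles/class_overrepresentation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("classes:", sum(cls$significant), "state/class pairs at q < 1e-2\n")

states <- sort(setdiff(unique(ds$assignment$label), 0L))
clf <- lapply(states, function(s) {
  fit <- prevalidated_classifier(ed, ds, s, seed = s)
  data.frame(ds = s, auroc = fit$auroc, n_members = sum(fit$y))
})
clf <- do.call(rbind, clf)
base <- classifier_baseline(ed, ds, states[1], n_draws = 5, seed = 99)
utils::write.table(clf, "results/profiles/classifier_auroc.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(auroc = clf, baseline = base),
                     "results/profiles/classifier_report.json",
                     auto_unbox = TRUE, digits = NA)
cat("liver transcriptome AUROC per state:",
    paste(sprintf("DS%d=%.3f", clf$ds, clf$auroc), collapse = ", "), "\n")
cat(sprintf("random-baseline AUROC median %.3f\n", stats::median(base)))
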