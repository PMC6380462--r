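#!/usr/bin/env Rscript
# Normalize the raw cohort: average animal replicates, express physiology
# in IQR units, curate histopathology against the vehicle background with
# the project-level ratio, call condition phenotypes, and vehicle-subtract
# the expression matrices.

library(toxds)

physiology <- utils::read.delim("results/cohort/physiology.tsv",
                                check.names = FALSE)
findings <- utils::read.delim("results/cohort/findings.tsv")

cond <- average_replicates(physiology)
phys <- normalize_physiology(cond)
r0 <- curation_threshold(sum(physiology$dose == "control"),
                         sum(physiology$dose != "control"))
retained <- curate_histopathology(findings, r0)
calls <- call_condition_phenotypes(retained)

dir.create("results/normalized", showWarnings = FALSE, recursive = TRUE)
utils::write.table(data.frame(condition = rownames(phys$matrix),
                              phys$matrix, check.names = FALSE),
                   "results/normalized/physiology_iqr.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(condition = rownames(calls), calls,
                              check.names = FALSE),
                   "results/normalized/phenotype_calls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(mode = phys$mode, center = as.list(phys$center),
       iqr = as.list(phys$iqr), curation_ratio = r0,
       n_tuples_kept = sum(attr(retained, "tuples")$kept),
       n_tuples_total = nrow(attr(retained, "tuples"))),
  "results/normalized/manifest.json", auto_unbox = TRUE, digits = NA)
saveRDS(list(phys = phys, calls = calls),
        "results/normalized/normalized.rds")

for (tis in c("liver", "kidney")) {
  mat <- as.matrix(utils::read.delim(
    sprintf("results/cohort/expression_%s.tsv", tis), row.names = 1,
    check.names = FALSE))
  samples <- utils::read.delim(sprintf("results/cohort/samples_%s.tsv", tis))
  ed <- normalize_expression(mat, samples, tis)
  saveRDS(ed, sprintf("results/normalized/expression_delta_%s.rds", tis))
  cat(tis, "delta:", nrow(ed$delta), "genes x", ncol(ed$delta),
      "conditions\n")
}

cat(sprintf("curation ratio %.3f kept %d of %d finding tuples\n", r0,
            sum(attr(retained, "tuples")$kept),
            nrow(attr(retained, "tuples"))))
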