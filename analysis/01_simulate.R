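#!/usr/bin/env Rscript
# Build the synthetic toxicogenomic cohort that stands in for the raw
# study data: per-animal physiology and histopathology for a 25-compound x
# 3-dose x 8-time-point grid with four planted disease states, matched
# vehicle arms, a compound-class table, and the planted ground truth.
# Writes the TSV/JSON bundle every later step consumes.

library(toxds)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")
saveRDS(cfg, "results/cohort/config.rds")

gene_sets <- make_gene_sets(cfg, n_sets = 50, set_size = 30)
write_gmt(gene_sets, "results/cohort/gene_sets.gmt")
expr <- simulate_expression(cfg, cohort$truth, gene_sets)
for (tis in names(expr)) {
  utils::write.table(
    data.frame(gene = rownames(expr[[tis]]$matrix), expr[[tis]]$matrix,
               check.names = FALSE),
    sprintf("results/cohort/expression_%s.tsv", tis),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr[[tis]]$samples,
                     sprintf("results/cohort/samples_%s.tsv", tis),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

n_state <- sum(cohort$truth$state_of_condition > 0)
cat("cohort:", length(cohort$truth$state_of_condition), "conditions,",
    n_state, "bearing a planted state across",
    cfg$n_states, "states\n")
cat("findings:", nrow(cohort$findings), "per-animal observations\n")
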