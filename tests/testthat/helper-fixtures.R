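# Small shared fixtures, built in code at test time.

# Reduced cohort: 8 compounds, 2 planted states, 192 treated conditions.
small_config <- function(seed = 3, ...) {
  args <- list(n_compounds = 8, n_states = 2, compounds_per_state = 2,
               n_genes = 400, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

small_cohort <- function(seed = 3, ...) {
  cfg <- small_config(seed = seed, ...)
  cohort <- simulate_cohort(cfg)
  list(config = cfg, cohort = cohort)
}

normalized_small <- function(seed = 3, ...) {
  sc <- small_cohort(seed = seed, ...)
  cond <- average_replicates(sc$cohort$physiology)
  phys <- normalize_physiology(cond)
  calls <- call_condition_phenotypes(
    curate_histopathology(sc$cohort$findings, 1 / 3))
  c(sc, list(phys = phys, calls = calls))
}

igf1_indicator_columns <- function() {
  c(paste0("liver_", c("igf1", "igfals", "igfbp1", "igfbp2")),
    paste0("kidney_", c("igf1", "igfals", "igfbp1", "igfbp2")))
}

# Hand-written planted schedule over the full grid of a config: compound 1
# (high dose) passes through state 1 then state 2; compound 2 (high dose)
# holds state 2 from day 8; everything else stays non-state.
default_schedule_for_tests <- function(cfg) {
  grid <- expand.grid(
    compound = paste0("cmpd_", sprintf("%02d", seq_len(cfg$n_compounds))),
    dose = cfg$doses, time_point = cfg$time_points,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- 0L
  tp <- cfg$time_points
  pick <- function(cmp, dose, tps) grid$compound == cmp & grid$dose == dose &
    grid$time_point %in% tps
  grid$state[pick("cmpd_01", "high", tp[4:5])] <- 1L
  grid$state[pick("cmpd_01", "high", tp[7:8])] <- 2L
  grid$state[pick("cmpd_02", "high", tp[6:8])] <- 2L
  grid$condition_id <- condition_id(grid$compound, grid$dose, grid$time_point)
  grid
}

# Exact two-sided rank-sum p by full enumeration of group allocations
# (no ties). Independent of stats::wilcox.test.
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))
  w_obs <- sum(r[seq_len(n1)])
  allo <- utils::combn(n, n1)
  ws <- colSums(matrix(seq_len(n)[allo], nrow = n1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# One-sided enrichment p for a 2x2 table by explicit hypergeometric sums.
enum_fisher_p <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Brute-force running-sum walk for the enrichment score.
walk_es <- function(gene_stats, set) {
  ord <- order(-gene_stats, names(gene_stats), method = "radix")
  hit <- names(gene_stats)[ord] %in% set
  N <- length(gene_stats); m <- sum(hit)
  rs <- cumsum(ifelse(hit, 1 / m, -1 / (N - m)))
  rs[which(abs(rs) >= max(abs(rs)) - 1e-12)[1]]
}

tree_leaf_sets_for_tests <- function(hc) toxds:::tree_leaf_sets(hc)
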