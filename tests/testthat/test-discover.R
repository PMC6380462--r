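test_that("Pearson distance matches a hand-computed correlation oracle", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 4), d = c(1, 3, 5))
  D <- pearson_distance(x)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D, t(D))
  expect_equal(unname(D["a", "b"]), 2)
  r_oracle <- function(u, v) {
    du <- u - mean(u); dv <- v - mean(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  expect_equal(unname(D["c", "d"]), 1 - r_oracle(c(1, 2, 4), c(1, 3, 5)),
               tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 2))
  expect_error(pearson_distance(rbind(x, e = c(2, 2, 2))), "e")
})

test_that("embedding is seed-deterministic and preserves planted neighborhoods", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(40 * 5, 0), ncol = 5),
               matrix(rnorm(40 * 5, 12), ncol = 5))
  rownames(pts) <- paste0("p", 1:80)
  D <- as.matrix(dist(pts))
  e1 <- embed_conditions(D, seed = 7, perplexity = 10)
  e2 <- embed_conditions(D, seed = 7, perplexity = 10)
  expect_identical(e1$coords, e2$coords)

  # 10-NN label purity between the two planted groups
  lab <- rep(1:2, each = 40)
  d2 <- as.matrix(dist(e1$coords))
  purity <- mean(vapply(seq_len(80), function(i) {
    nn <- order(d2[i, ])[2:11]
    mean(lab[nn] == lab[i])
  }, numeric(1)))
  expect_gte(purity, 0.9)

  expect_warning(embed_conditions(D[1:20, 1:20], seed = 1, perplexity = 30),
                 "perplexity")
  D_bad <- D; D_bad[1, 2] <- NA
  expect_error(embed_conditions(D_bad, seed = 1), "non-finite")
})

test_that("severity scores count distinct called phenotypes per tissue", {
  calls <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
                  dimnames = list(c("c1", "c2"),
                                  c("liver:necrosis", "liver:swelling",
                                    "kidney:edema")))
  expect_equal(severity_score(calls, "liver"), c(c1 = 2L, c2 = 1L))
  expect_equal(severity_score(calls, "kidney"), c(c1 = 0L, c2 = 1L))
})

test_that("severity smoothing matches a direct kernel-regression oracle", {
  set.seed(8)
  coords <- matrix(runif(40, 0, 10), ncol = 2)
  sev <- rpois(20, 2)
  bw <- 1.2
  sm <- impute_severity(coords, sev, bandwidth = bw, grid_size = 201)
  nw_oracle <- vapply(seq_len(20), function(i) {
    w <- dnorm(coords[, 1], coords[i, 1], bw) *
      dnorm(coords[, 2], coords[i, 2], bw)
    sum(w * sev) / sum(w)
  }, numeric(1))
  expect_lt(max(abs(sm - nw_oracle) / pmax(nw_oracle, 1e-9)), 0.05)

  # constancy: equal severities smooth to the same constant
  smc <- impute_severity(coords, rep(3, 20), bandwidth = bw)
  expect_lt(max(abs(smc - 3)), 1e-6)

  # local limit: an isolated point keeps its own severity
  far <- rbind(coords, c(500, 500))
  smf <- impute_severity(far, c(sev, 7), bandwidth = bw)
  expect_equal(unname(smf[21]), 7, tolerance = 1e-6)

  expect_error(impute_severity(coords, sev, bandwidth = 0), "positive")
})

test_that("density clustering follows DBSCAN reachability semantics", {
  lonely <- cbind(seq(0, 50, by = 10), 0)
  expect_equal(density_cluster(lonely, eps = 1, min_pts = 2),
               rep(0L, 6))

  blob <- function(cx) cbind(rnorm(20, cx, 0.3), rnorm(20, 0, 0.3))
  set.seed(2)
  two <- rbind(blob(0), blob(20))
  lab <- density_cluster(two, eps = 1.5, min_pts = 5)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
  expect_equal(length(unique(lab[1:20])), 1)

  chain <- cbind(seq(0, 9, by = 0.5), 0)
  expect_equal(unique(density_cluster(chain, eps = 0.6, min_pts = 3)), 1L)

  expect_error(density_cluster(two, eps = -1), "positive")
})

test_that("consensus clustering aggregates runs and scores likelihoods", {
  lab <- c(1L, 1L, 1L, 2L, 2L, 0L)
  cons <- consensus_cluster(list(lab, lab, lab))
  expect_equal(cons$assignment$label[1:5], c(1L, 1L, 1L, 2L, 2L))
  expect_equal(cons$assignment$likelihood[1:5], rep(1, 5))
  expect_equal(cons$assignment$label[6], 0L)

  # co-clustered in half the runs -> likelihood 0.5 (not below it)
  runs <- c(rep(list(c(1L, 1L, 1L, 1L)), 5), rep(list(c(1L, 1L, 1L, 0L)), 5))
  cons2 <- consensus_cluster(runs)
  expect_equal(cons2$assignment$likelihood[4], 0.5)
  expect_equal(cons2$assignment$label[4], cons2$assignment$label[1])

  expect_error(consensus_cluster(list()), "no labelings")
})

test_that("consensus agrees with the exhaustive-partition oracle on small cases", {
  # 2 of 3 runs agree; majority grouping must win
  l1 <- c(1L, 1L, 2L, 2L, 3L, 3L)
  l2 <- c(1L, 1L, 2L, 2L, 3L, 3L)
  l3 <- c(1L, 2L, 2L, 2L, 3L, 3L)
  cons <- consensus_cluster(list(l1, l2, l3))
  oracle <- consensus_partition_oracle(cons$coassoc)
  expect_equal(label_ari(cons$assignment$label, oracle), 1)

  # three clean groups, three runs with permuted cluster ids
  g <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L)
  perm <- function(l, p) p[l]
  cons2 <- consensus_cluster(list(g, perm(g, c(2L, 3L, 1L)),
                                  perm(g, c(3L, 1L, 2L))))
  oracle2 <- consensus_partition_oracle(cons2$coassoc)
  expect_equal(label_ari(cons2$assignment$label, oracle2), 1)
  expect_equal(label_ari(cons2$assignment$label, g), 1)
})

test_that("state filtering enforces size and compound support, then renumbers", {
  n <- c(19, 25, 37, 50)
  labels <- rep(1:4, times = n)
  compounds <- c(paste0("x", seq_len(19)),               # big enough? no: 19
                 rep("only_one", 25),                     # single compound
                 rep(paste0("c", 1:10), length.out = 37),
                 rep(paste0("d", 1:12), length.out = 50))
  cons <- list(assignment = data.frame(
    condition = paste0("k", seq_along(labels)),
    label = labels, likelihood = 1),
    coassoc = outer(labels, labels, "=="), n_runs = 1L)
  class(cons) <- "ds_assignment"
  out <- filter_disease_states(cons, compounds, min_size = 20,
                               min_compounds = 2)
  kept <- table(out$assignment$label[out$assignment$label > 0])
  # 19-strong cluster out (fewer than 20), 25-strong out (one compound);
  # survivors renumbered by descending size
  expect_equal(as.vector(kept[c("1", "2")]), c(50L, 37L))
  expect_equal(length(kept), 2L)

  n_before <- length(setdiff(unique(labels), 0L))
  n_after <- length(kept)
  expect_lte(n_after, n_before)
})

test_that("full discovery recovers planted states on a reduced cohort", {
  ns <- normalized_small(seed = 3)
  ds <- discover_states(ns$phys, ns$calls, n_runs = 6, seed = 42,
                        min_size = 10)
  truth <- ns$cohort$truth$state_of_condition[ds$assignment$condition]
  expect_gte(label_ari(ds$assignment$label, truth), 0.7)
  expect_true(all(ds$assignment$likelihood >= 0 &
                    ds$assignment$likelihood <= 1))
})

test_that("recovery quality does not degrade as the planted effect grows", {
  ari_at <- function(effect, seed) {
    ns <- normalized_small(seed = seed, phys_effect_size = effect)
    ds <- discover_states(ns$phys, ns$calls, n_runs = 4, seed = seed + 100,
                          min_size = 10)
    truth <- ns$cohort$truth$state_of_condition[ds$assignment$condition]
    label_ari(ds$assignment$label, truth)
  }
  seeds <- c(51, 52, 53)
  weak <- vapply(seeds, function(s) ari_at(0.5, s), numeric(1))
  strong <- vapply(seeds, function(s) ari_at(3, s), numeric(1))
  expect_gte(stats::median(strong), stats::median(weak))
})

test_that("consensus labels are stable when the number of runs doubles", {
  cfg <- sim_config(n_compounds = 12, compounds_per_state = 3, seed = 19)
  co <- simulate_cohort(cfg)
  phys <- normalize_physiology(average_replicates(co$physiology))
  calls <- call_condition_phenotypes(
    curate_histopathology(co$findings, 1 / 3))
  ds1 <- discover_states(phys, calls, n_runs = 12, seed = 77)
  ds2 <- discover_states(phys, calls, n_runs = 24, seed = 77)
  a1 <- ds1$assignment$label
  a2 <- ds2$assignment$label
  # match cluster ids by maximal overlap before counting changed labels
  relabel <- function(from, to) {
    out <- integer(length(from))
    for (cl in setdiff(unique(from), 0L)) {
      hit <- table(to[from == cl])
      out[from == cl] <- as.integer(names(hit)[which.max(hit)])
    }
    out
  }
  expect_gt(length(setdiff(unique(a2), 0L)), 0)  # states actually exist
  changed <- mean(relabel(a1, a2) != a2)
  expect_lt(changed, 0.05)
})
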