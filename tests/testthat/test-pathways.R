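test_that("GMT round trip preserves sets and matches an independent reader", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    expect_identical(fgsea::gmtPathways(path), sets)
  }
})

test_that("enrichment score hits its extremes and the brute-force walk", {
  stats_vec <- stats::setNames(10:1, paste0("g", 1:10))
  expect_equal(enrichment_score(stats_vec, paste0("g", 1:3)), 1)
  expect_equal(enrichment_score(stats_vec, paste0("g", 8:10)), -1)

  # N = 5, |S| = 2, members at ranks 2 and 5
  v5 <- stats::setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  expect_equal(enrichment_score(v5, c("g2", "g5")),
               walk_es(v5, c("g2", "g5")))

  expect_error(enrichment_score(v5, names(v5)), "whole universe")
  expect_error(enrichment_score(v5, "absent"), "no members")
})

test_that("fast matrix scoring equals the walk oracle on random profiles", {
  set.seed(3)
  genes <- paste0("g", sprintf("%02d", 1:40))
  mat <- matrix(rnorm(40 * 6), 40, dimnames = list(genes, paste0("c", 1:6)))
  sets <- list(s1 = sample(genes, 12), s2 = sample(genes, 15),
               s3 = sample(genes, 10))
  es <- enrichment_score_matrix(mat, sets, min_size = 5)
  for (s in names(sets)) {
    for (j in 1:6) {
      expect_equal(es[s, j], walk_es(mat[, j], sets[[s]]), tolerance = 1e-12)
    }
  }
  # measured-size filter
  sets$tiny <- genes[1:3]
  expect_false("tiny" %in%
                 rownames(enrichment_score_matrix(mat, sets, min_size = 5)))
})

test_that("activity scores are signed log10 Wilcoxon p-values", {
  set.seed(6)
  es <- stats::setNames(c(rnorm(20, 2), rnorm(60, 0)), paste0("c", 1:80))
  a <- data.frame(condition = names(es), label = rep(c(1L, 0L), c(20, 60)))
  sc <- activity_score(es, a, 1)
  p <- stats::wilcox.test(es[1:20], es[21:80])$p.value
  expect_equal(sc, -log10(p) * 1)
  expect_gt(sc, 5)
  expect_lt(activity_score(-es, a, 1), 0)
  expect_equal(activity_score(stats::setNames(rep(1, 80), names(es)), a, 1), 0)
})

test_that("state dendrogram uses rank correlation and complete linkage", {
  set.seed(9)
  base <- rnorm(30)
  scores <- cbind(DS1 = base, DS2 = exp(base), DS3 = rnorm(30),
                  DS4 = -base + rnorm(30, sd = 3))
  rownames(scores) <- paste0("pw", 1:30)
  hc <- cluster_ds_by_activity(scores)
  m12 <- which(apply(hc$merge, 1, function(r) setequal(r, c(-1, -2))))
  expect_equal(hc$height[m12], 0, tolerance = 1e-12)  # Spearman invariance

  # exhaustive complete-linkage check on the 4-column toy
  D <- 1 - stats::cor(scores, method = "spearman")
  ref <- stats::hclust(stats::as.dist(D), method = "complete")
  expect_equal(hc$merge, ref$merge)
  expect_equal(hc$height, ref$height)

  bad <- scores; bad[, 2] <- 1
  expect_error(cluster_ds_by_activity(bad), "constant")
})

test_that("pathways map to the unique node matching their direction pattern", {
  states <- paste0("DS", 1:4)
  # build a fixed dendrogram: ((DS1,DS2),(DS3,DS4))
  act <- cbind(c(10, 10, 0, 0), c(9, 10, 0.5, 0), c(0, 0.5, 10, 9),
               c(0, 0, 9, 10))
  colnames(act) <- states
  rownames(act) <- paste0("seed", 1:4)
  hc <- cluster_ds_by_activity(act)

  scores <- rbind(
    only_ds1   = c(8, 0, 0, 0),
    pair_up    = c(8, 7, 0, 0),
    everywhere = c(8, 7, 9, 6),
    not_clade  = c(8, 0, 9, 0),
    both_ways  = c(8, -7, 0, 0),
    nothing    = c(1, 2, 0, 1),
    pair_down  = c(0, 0, -8, -9))
  colnames(scores) <- states
  m <- map_pathways_to_nodes(scores, hc)
  lookup <- function(pw) m[m$pathway == pw, ]
  expect_equal(lookup("only_ds1")$node, "leaf:DS1")
  expect_equal(lookup("pair_up")$direction, "up")
  sets <- tree_leaf_sets_for_tests(hc)
  expect_equal(sort(sets[[lookup("pair_up")$node]]), c("DS1", "DS2"))
  expect_equal(sort(sets[[lookup("everywhere")$node]]), sort(states))
  expect_true(is.na(lookup("not_clade")$node))
  expect_equal(lookup("both_ways")$direction, "mixed")
  expect_equal(lookup("nothing")$direction, "flat")
  expect_equal(lookup("pair_down")$direction, "down")

  # every significant pathway lands on at most one node; the rest are NA
  expect_equal(sum(!is.na(m$node)), 4)
})

test_that("cofactor stratification groups enzymes and sees a planted shift", {
  map <- ec_cofactor_map()
  expect_equal(map$cofactor[map$ec == "EC2.5.1.18"], "glutathione")
  expect_gte(sum(map$cofactor == "NAD(P)H"), 10)

  set.seed(10)
  genes <- paste0("g", 1:40)
  nadph_ec <- map$ec[map$cofactor == "NAD(P)H"][1:15]
  atp_ec <- map$ec[map$cofactor == "ATP"][1:6]
  gene_ec <- data.frame(gene = genes[1:21], ec = c(nadph_ec, atp_ec))
  X <- matrix(rnorm(40 * 30, 0, 0.5), 40,
              dimnames = list(genes, paste0("c", 1:30)))
  X[1:15, 1:12] <- X[1:15, 1:12] + 2       # NADPH genes up in the group
  out <- stratify_by_cofactor(X, paste0("c", 1:12), gene_ec)
  s <- out$summary
  expect_gt(s$median_signed_log_p[s$cofactor == "NAD(P)H"],
            s$median_signed_log_p[s$cofactor == "ATP"])
  expect_gt(s$median_signed_log_p[s$cofactor == "NAD(P)H"], 0)
  expect_true(s$displayed[s$cofactor == "NAD(P)H"])
  expect_false(s$displayed[s$cofactor == "ATP"])

  # a group identical to its vehicle baseline scores ~0
  X0 <- matrix(0, 40, 30, dimnames = dimnames(X))
  out0 <- stratify_by_cofactor(X0, paste0("c", 1:12), gene_ec)
  expect_equal(max(abs(out0$genes$signed_log_p)), 0)
})

test_that("signature derivation splits the correlation ranking symmetrically", {
  v <- stats::setNames(c(3, 2, 1, 0.5, -0.4, -1, -2, -2.5, 0.1, -0.1),
                       paste0("g", 1:10))
  sig <- derive_signatures(v, size = 2)
  expect_equal(sig$res, c("g1", "g2"))
  expect_equal(sig$sen, c("g8", "g7"))
  expect_length(intersect(sig$res, sig$sen), 0)

  exact <- stats::setNames(c(rep(1, 200), rep(-1, 200)), paste0("g", 1:400))
  sig2 <- derive_signatures(exact, size = 200)
  expect_setequal(sig2$res, paste0("g", 1:200))
  expect_setequal(sig2$sen, paste0("g", 201:400))

  orth <- data.frame(gene = paste0("g", 1:10),
                     ortholog = c(paste0("r", 1:8), NA, NA))
  sig3 <- derive_signatures(v, size = 2, orthologs = orth)
  expect_equal(sig3$res, c("r1", "r2"))

  expect_error(derive_signatures(stats::setNames(rep(0, 10),
                                                 paste0("g", 1:10)), 2),
               "all-zero")
  expect_error(derive_signatures(v, size = 6), "2 \\* size")
})

test_that("score-profile correlation is tie-corrected Spearman", {
  prof <- stats::setNames(c(1, 2, 2, 3, 5, 4), paste0("c", 1:6))
  mat <- rbind(self = prof, neg = -prof,
               other = c(2, 1, 4, 4, 3, 6))
  colnames(mat) <- names(prof)
  rho <- correlate_score_profiles(prof, mat)
  expect_equal(unname(rho["self"]), 1)
  expect_equal(unname(rho["neg"]), -1)
  # independent oracle: rank then Pearson
  expect_equal(unname(rho["other"]),
               stats::cor(rank(prof), rank(mat["other", ])),
               tolerance = 1e-12)
  expect_error(correlate_score_profiles(stats::setNames(rep(1, 6),
                                                        names(prof)), mat),
               "constant")
})
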