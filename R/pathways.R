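#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: id, description, members).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of gene-id vectors.
#' @param path output file.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(id)
    paste(c(id, id, gene_sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Running-sum (KS) enrichment score of one gene set
#'
#' Genes are ranked by the per-condition statistic in descending order
#' (ties broken by stable gene-id order); the running sum gains
#' `1/|S|` on set members and loses `1/(N - |S|)` otherwise. The score is
#' the running-sum value of maximal absolute deviation from zero, in
#' \[-1, 1\]: +1 when the whole set sits at the top of the ranking, -1 at
#' the bottom.
#'
#' @param gene_stats named numeric vector (one condition's per-gene
#'   statistic over the measured universe).
#' @param set gene ids of the set; members absent from the universe are
#'   ignored.
#' @param exponent rank-statistic weighting exponent; 0 (default) is the
#'   classic unweighted form.
#' @return enrichment score.
#' @export
enrichment_score <- function(gene_stats, set, exponent = 0) {
  stopifnot(!is.null(names(gene_stats)))
  N <- length(gene_stats)
  hit <- names(gene_stats) %in% set
  m <- sum(hit)
  if (m == 0) stop("gene set has no members in the universe")
  if (m == N) stop("gene set covers the whole universe")
  ord <- order(-gene_stats, names(gene_stats), method = "radix")
  hit <- hit[ord]
  if (exponent == 0) {
    up <- rep(1 / m, N)
  } else {
    w <- abs(gene_stats[ord])^exponent
    w[!hit] <- 0
    up <- w / sum(w[hit])
  }
  steps <- ifelse(hit, up, -1 / (N - m))
  rs <- cumsum(steps)
  rs[arg_max_abs(rs)]
}

# earliest index attaining the maximal |value| up to float tolerance, so
# the direct walk and the hit-position shortcut always agree
arg_max_abs <- function(x, tol = 1e-12) {
  which(abs(x) >= max(abs(x)) - tol)[1]
}

#' Enrichment scores of many sets across many conditions
#'
#' Applies [enrichment_score()] (unweighted form) to every column of a
#' per-gene statistic matrix, using a rank-walk shortcut that only visits
#' set-member positions. Sets with fewer than `min_size` measured members
#' are dropped, mirroring the measured-gene requirement for scoring.
#'
#' @param stats_matrix genes x conditions matrix (e.g. an
#'   `expression_delta$delta`).
#' @param gene_sets named list of gene sets.
#' @param min_size minimum measured members per set (default 10).
#' @return sets x conditions matrix of enrichment scores.
#' @export
enrichment_score_matrix <- function(stats_matrix, gene_sets, min_size = 10) {
  genes <- rownames(stats_matrix)
  N <- length(genes)
  keep <- vapply(gene_sets, function(s) sum(genes %in% s) >= min_size, TRUE)
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) stop("no gene set passes the measured-size filter")
  member_idx <- lapply(gene_sets, function(s) which(genes %in% s))

  out <- matrix(NA_real_, length(gene_sets), ncol(stats_matrix),
                dimnames = list(names(gene_sets), colnames(stats_matrix)))
  for (j in seq_len(ncol(stats_matrix))) {
    v <- stats_matrix[, j]
    ord <- order(-v, genes, method = "radix")
    pos_of <- integer(N)
    pos_of[ord] <- seq_len(N)
    for (s in seq_along(member_idx)) {
      p <- sort(pos_of[member_idx[[s]]])
      m <- length(p)
      i <- seq_len(m)
      after <- i / m - (p - i) / (N - m)          # walk right after hit i
      before <- (i - 1) / m - (p - i) / (N - m)   # walk just before hit i
      cand <- c(after, before)
      o <- order(c(p, p - 1L))  # |max| ties resolve to the earliest walk step
      cand <- cand[o]
      out[s, j] <- cand[arg_max_abs(cand)]
    }
  }
  out
}

#' Activity score of one pathway in one disease state
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-condition enrichment
#' scores of state members against the non-state pool;
#' `score = sign(median difference) * -log10(p)`, deliberately unadjusted
#' (significance is called at the strict `|score| >= 5`, i.e.
#' p <= 1e-5).
#'
#' @param es named numeric vector of per-condition enrichment scores for
#'   one pathway.
#' @param assignment `ds_assignment` or condition/label data frame.
#' @param ds state id.
#' @return signed log10 p activity score (0 when all values are tied).
#' @export
activity_score <- function(es, assignment, ds) {
  a <- assignment_frame(assignment)
  a <- a[a$condition %in% names(es), , drop = FALSE]
  x <- es[a$condition[a$label == ds]]
  y <- es[a$condition[a$label == 0L]]
  if (!length(x) || !length(y)) stop("state and non-state pools must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(0)
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  signed_log10(p, sign(stats::median(x) - stats::median(y)))
}

#' Pathway x disease-state activity matrix
#'
#' @param es_matrix sets x conditions enrichment-score matrix.
#' @param assignment `ds_assignment` or condition/label data frame.
#' @param threshold significance threshold on |score| (default 5).
#' @return list: `scores` (pathway x state matrix), `significant` (logical
#'   mask |score| >= threshold).
#' @export
activity_matrix <- function(es_matrix, assignment, threshold = 5) {
  a <- assignment_frame(assignment)
  states <- sort(setdiff(unique(a$label), 0L))
  scores <- sapply(states, function(ds)
    apply(es_matrix, 1, activity_score, assignment = a, ds = ds))
  scores <- matrix(scores, nrow = nrow(es_matrix),
                   dimnames = list(rownames(es_matrix), paste0("DS", states)))
  list(scores = scores, significant = abs(scores) >= threshold,
       threshold = threshold)
}

#' Dendrogram of disease states from pathway activity
#'
#' Complete-linkage hierarchical clustering of the state columns using
#' 1 - Spearman correlation as the distance.
#'
#' @param scores pathway x state activity matrix, usually restricted to
#'   pathways significant in at least one state.
#' @return an `hclust` tree over the states.
#' @export
cluster_ds_by_activity <- function(scores) {
  stopifnot(ncol(scores) >= 2, nrow(scores) >= 2)
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0))
    stop("constant activity column(s): ",
         paste(colnames(scores)[sds == 0], collapse = ", "))
  D <- 1 - stats::cor(scores, method = "spearman")
  stats::hclust(stats::as.dist(D), method = "complete")
}

# Leaf sets of every node of an hclust tree: leaves first (singletons),
# then internal nodes in merge order; the last internal node is the root.
tree_leaf_sets <- function(hc) {
  k <- length(hc$labels)
  nodes <- as.list(hc$labels)
  names(nodes) <- paste0("leaf:", hc$labels)
  internal <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(j) if (j < 0) hc$labels[-j] else internal[[j]]
    internal[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  names(internal) <- paste0("node:", seq_len(nrow(hc$merge)))
  c(nodes, internal)
}

#' Map pathways onto dendrogram nodes by their direction pattern
#'
#' Each pathway is binarized per state (up when score >= threshold, down
#' when <= -threshold). A pathway changed in exactly one direction maps to
#' the unique tree node whose leaf set equals the set of states sharing
#' that direction: a leaf for an exclusive pathway, an internal node for a
#' shared one, the root when all states change. Patterns matching no node,
#' and pathways significant in both directions, are unassigned.
#'
#' @param scores pathway x state activity matrix.
#' @param hc state dendrogram ([cluster_ds_by_activity()]).
#' @param threshold activity significance threshold (default 5).
#' @return data frame: pathway, node (`leaf:DSx`, `node:i`, or NA),
#'   direction (`up`/`down`/`mixed`/`flat`), states (comma-joined).
#' @export
map_pathways_to_nodes <- function(scores, hc, threshold = 5) {
  stopifnot(setequal(hc$labels, colnames(scores)))
  leafsets <- tree_leaf_sets(hc)
  keys <- vapply(leafsets, paste, "", collapse = ",")
  res <- lapply(rownames(scores), function(pw) {
    v <- scores[pw, ]
    up <- sort(colnames(scores)[v >= threshold])
    dn <- sort(colnames(scores)[v <= -threshold])
    if (length(up) && length(dn))
      return(data.frame(pathway = pw, node = NA_character_,
                        direction = "mixed", states = ""))
    if (!length(up) && !length(dn))
      return(data.frame(pathway = pw, node = NA_character_,
                        direction = "flat", states = ""))
    ss <- if (length(up)) up else dn
    hitnode <- names(keys)[match(paste(ss, collapse = ","), keys)]
    data.frame(pathway = pw,
               node = if (is.na(hitnode)) NA_character_ else hitnode,
               direction = if (length(up)) "up" else "down",
               states = paste(ss, collapse = ","))
  })
  do.call(rbind, res)
}

#' Packaged EC-number to cofactor map
#'
#' Oxidoreductase (EC1) and transferase (EC2) classes regrouped by the
#' cofactor their reactions consume (NAD(P)H, glutathione, and so on);
#' hydrolases are excluded since water is not limiting.
#'
#' @return data frame with columns ec, cofactor.
#' @export
ec_cofactor_map <- function() {
  utils::read.delim(system.file("extdata", "ec_cofactors.tsv",
                                package = "toxds"),
                    stringsAsFactors = FALSE)
}

#' Stratify enzyme expression changes by cofactor
#'
#' For each enzyme-encoding gene, the vehicle-subtracted log2 changes
#' across the group's conditions are tested against zero (signed-rank),
#' giving a per-gene signed log10 p; genes are grouped by the cofactor of
#' their EC class. Cofactors with at least `min_enzymes` measured genes
#' are flagged for display.
#'
#' @param delta `expression_delta` or genes x conditions matrix.
#' @param conditions condition ids of the group (e.g. one state's members).
#' @param gene_ec data frame gene -> ec.
#' @param cofactors data frame ec -> cofactor (default the packaged map).
#' @param min_enzymes display threshold (default 10).
#' @return list: `genes` (gene, ec, cofactor, p, signed_log_p), `summary`
#'   (per cofactor: n_genes, median signed log p, displayed flag).
#' @export
stratify_by_cofactor <- function(delta, conditions, gene_ec,
                                 cofactors = ec_cofactor_map(),
                                 min_enzymes = 10) {
  X <- if (inherits(delta, "expression_delta")) delta$delta else delta
  stopifnot(all(conditions %in% colnames(X)))
  gene_ec$cofactor <- cofactors$cofactor[match(gene_ec$ec, cofactors$ec)]
  gene_ec <- gene_ec[!is.na(gene_ec$cofactor) & gene_ec$gene %in% rownames(X), ]
  if (!nrow(gene_ec)) stop("no measured genes map to any cofactor")

  res <- lapply(seq_len(nrow(gene_ec)), function(i) {
    x <- X[gene_ec$gene[i], conditions]
    p <- if (all(x == 0)) 1 else
      suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)
    data.frame(gene = gene_ec$gene[i], ec = gene_ec$ec[i],
               cofactor = gene_ec$cofactor[i], p = p,
               signed_log_p = signed_log10(p, sign(stats::median(x))))
  })
  genes <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(genes, genes$cofactor), function(g)
    data.frame(cofactor = g$cofactor[1], n_genes = nrow(g),
               median_signed_log_p = stats::median(g$signed_log_p))))
  summ$displayed <- summ$n_genes >= min_enzymes
  rownames(summ) <- NULL
  list(genes = genes, summary = summ)
}

#' Sensitivity/resistance signatures from a correlation profile
#'
#' The `size` most positively correlated genes form the resistance set and
#' the `size` most negative the sensitivity set (positive correlation with
#' a growth-inhibition profile marks genes high in resistant lines). Ties
#' spanning the cutoff are resolved by stable gene-id order. An ortholog
#' map, when given, is applied afterward and genes without orthologs are
#' dropped.
#'
#' @param correlation named numeric vector, gene -> correlation with the
#'   mechanism's sensitivity profile.
#' @param size signature size per side (default 200).
#' @param orthologs optional data frame gene -> ortholog.
#' @return list with `res` and `sen` gene vectors (disjoint).
#' @export
derive_signatures <- function(correlation, size = 200, orthologs = NULL) {
  stopifnot(!is.null(names(correlation)))
  if (length(correlation) < 2 * size)
    stop("need at least 2 * size genes to split signatures")
  if (all(correlation == 0)) stop("all-zero correlation vector: nothing to rank")
  ord_res <- order(-correlation, names(correlation), method = "radix")
  ord_sen <- order(correlation, names(correlation), method = "radix")
  res <- names(correlation)[ord_res[seq_len(size)]]
  sen <- names(correlation)[ord_sen[seq_len(size)]]
  if (!is.null(orthologs)) {
    res <- stats::na.omit(orthologs$ortholog[match(res, orthologs$gene)])
    sen <- stats::na.omit(orthologs$ortholog[match(sen, orthologs$gene)])
    res <- as.character(res); sen <- as.character(sen)
  }
  list(res = res, sen = sen)
}

#' Spearman correlation of one score profile against many
#'
#' @param profile named per-condition enrichment scores of the query set.
#' @param profiles sets x conditions matrix of scores to correlate with.
#' @return named vector of tie-corrected Spearman rho values.
#' @export
correlate_score_profiles <- function(profile, profiles) {
  stopifnot(all(colnames(profiles) %in% names(profile)))
  if (stats::sd(profile) == 0) stop("constant query profile")
  v <- profile[colnames(profiles)]
  apply(profiles, 1, function(row) stats::cor(v, row, method = "spearman"))
}
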