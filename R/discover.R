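#' Pearson distance between condition profiles
#'
#' `D_ij = 1 - cor(row_i, row_j)`; symmetric, zero diagonal, in \[0, 2\].
#'
#' @param x conditions x parameters numeric matrix, or a
#'   `normalized_physiology` object.
#' @return condition x condition distance matrix.
#' @export
pearson_distance <- function(x) {
  if (inherits(x, "normalized_physiology")) x <- x$matrix
  stopifnot(is.matrix(x), ncol(x) >= 2)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance condition profile(s): ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
  }
  D <- 1 - stats::cor(t(x))
  D[D < 0] <- 0           # clip numerical noise below exact zero
  diag(D) <- 0
  D
}

#' Stochastic 2-D embedding of a distance matrix
#'
#' Runs t-SNE on a precomputed distance matrix. Deterministic for a fixed
#' seed. When the point count is too small for the requested perplexity
#' (`n <= 3 * perplexity + 1`), the perplexity is shrunk with a warning.
#'
#' @param D condition x condition distance matrix.
#' @param seed RNG seed for this run.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter gradient-descent iterations.
#' @return list of class `embedding_run`: `coords` (n x 2, rownames from
#'   `D`), `seed`, `perplexity`.
#' @export
embed_conditions <- function(D, seed, perplexity = 30, max_iter = 500) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!all(is.finite(D))) stop("distance matrix has non-finite entries")
  n <- nrow(D)
  if (n - 1 < 3 * perplexity) {
    perplexity <- max(1, floor((n - 1) / 3))
    warning("perplexity too large for ", n, " points; reduced to ", perplexity)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(D, is_distance = TRUE, dims = 2,
                      perplexity = perplexity, theta = 0.5,
                      max_iter = max_iter, verbose = FALSE,
                      check_duplicates = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(D)
  structure(list(coords = coords, seed = seed, perplexity = perplexity),
            class = "embedding_run")
}

#' Raw histopathology severity per condition
#'
#' The number of distinct called phenotypes of one tissue for each
#' condition (topography and grade already collapsed at the call stage).
#'
#' @param calls binary call matrix ([call_condition_phenotypes()]).
#' @param tissue `"liver"` or `"kidney"`.
#' @return named integer vector over the conditions of `calls`.
#' @export
severity_score <- function(calls, tissue = c("liver", "kidney")) {
  tissue <- match.arg(tissue)
  cols <- grep(paste0("^", tissue, ":"), colnames(calls))
  out <- if (length(cols)) rowSums(calls[, cols, drop = FALSE]) else
    rep(0, nrow(calls))
  stats::setNames(as.integer(out), rownames(calls))
}

#' Smooth severity over the embedding (Nadaraya-Watson on a grid)
#'
#' Builds a severity-weighted binned Gaussian kernel surface and divides it
#' by the unweighted density surface on a regular grid, then reads the
#' smoothed value back at each condition's coordinates by bilinear
#' interpolation. Conditions in empty neighborhoods get 0.
#'
#' @param run an `embedding_run` (or an n x 2 coordinate matrix).
#' @param severity numeric severity per condition, aligned with the rows of
#'   the coordinates.
#' @param bandwidth Gaussian kernel sd per axis; default a normal-reference
#'   rule per axis.
#' @param grid_size grid nodes per axis.
#' @return numeric vector of smoothed severities (>= 0).
#' @export
impute_severity <- function(run, severity, bandwidth = NULL, grid_size = 101) {
  coords <- if (inherits(run, "embedding_run")) run$coords else run
  stopifnot(nrow(coords) == length(severity))
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::bw.nrd(coords[, 1]), stats::bw.nrd(coords[, 2]))
  }
  bandwidth <- rep(bandwidth, length.out = 2)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")

  pad <- 3 * bandwidth
  gx <- seq(min(coords[, 1]) - pad[1], max(coords[, 1]) + pad[1],
            length.out = grid_size)
  gy <- seq(min(coords[, 2]) - pad[2], max(coords[, 2]) + pad[2],
            length.out = grid_size)

  # Nearest-node binning, then separable Gaussian blur of both surfaces.
  ix <- pmin(pmax(round(stats::approx(gx, seq_along(gx), coords[, 1],
                                      rule = 2)$y), 1), grid_size)
  iy <- pmin(pmax(round(stats::approx(gy, seq_along(gy), coords[, 2],
                                      rule = 2)$y), 1), grid_size)
  Bw <- matrix(0, grid_size, grid_size)  # severity mass
  Bn <- matrix(0, grid_size, grid_size)  # point mass
  for (i in seq_len(nrow(coords))) {
    Bw[ix[i], iy[i]] <- Bw[ix[i], iy[i]] + severity[i]
    Bn[ix[i], iy[i]] <- Bn[ix[i], iy[i]] + 1
  }
  Kx <- stats::dnorm(outer(gx, gx, "-") / bandwidth[1])
  Ky <- stats::dnorm(outer(gy, gy, "-") / bandwidth[2])
  num <- Kx %*% Bw %*% Ky
  den <- Kx %*% Bn %*% Ky

  sm_num <- bilinear_interp(gx, gy, num, coords[, 1], coords[, 2])
  sm_den <- bilinear_interp(gx, gy, den, coords[, 1], coords[, 2])
  out <- ifelse(sm_den > 1e-12, sm_num / sm_den, 0)
  pmax(out, 0)
}

#' Density-based clustering (DBSCAN semantics)
#'
#' Core points have at least `min_pts` neighbors (themselves included)
#' within `eps`; clusters grow by density reachability; unreachable points
#' are labeled noise (0).
#'
#' @param coords n x 2 coordinate matrix.
#' @param eps neighborhood radius (> 0).
#' @param min_pts core-point threshold.
#' @return integer labels, 0 for noise.
#' @export
density_cluster <- function(coords, eps, min_pts = 5) {
  if (eps <= 0) stop("eps must be positive")
  n <- nrow(coords)
  if (n < min_pts) stop("need at least min_pts points")
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Per-run DBSCAN radius from the knee of the k-NN distance curve
#'
#' Sorts the distances to each point's k-th nearest neighbor and returns
#' the value at the point of maximum deviation from the chord joining the
#' curve's endpoints (the usual elbow heuristic).
#'
#' @param coords n x 2 coordinates.
#' @param k neighbor rank (default = `min_pts`).
#' @return eps estimate (> 0).
#' @export
knee_eps <- function(coords, k = 5) {
  D <- as.matrix(stats::dist(coords))
  kd <- sort(apply(D, 1, function(d) sort(d)[k + 1]))
  n <- length(kd)
  t <- (seq_len(n) - 1) / (n - 1)
  chord <- kd[1] + t * (kd[n] - kd[1])
  eps <- kd[which.max(chord - kd)]  # curve runs below the chord; elbow = max gap
  if (eps <= 0) eps <- max(kd[kd > 0][1], 1e-8)
  eps
}

#' Consensus over many stochastic clusterings
#'
#' Builds the co-association matrix `M_ij` = fraction of runs in which i
#' and j share a non-noise cluster, clusters `1 - M` by average-linkage
#' hierarchical clustering cut at 0.5, and scores each condition's
#' membership likelihood as its mean co-association with the other members
#' of its consensus cluster. Conditions with likelihood below 0.5 are
#' relabeled non-state (0).
#'
#' @param labelings list of integer label vectors (0 = noise), all over the
#'   same conditions.
#' @param condition_ids optional condition names.
#' @param cut consensus dissimilarity cut height (default 0.5).
#' @return list of class `ds_assignment`: `assignment` data frame
#'   (condition, label, likelihood), `coassoc` matrix, `n_runs`.
#' @export
consensus_cluster <- function(labelings, condition_ids = NULL, cut = 0.5) {
  R <- length(labelings)
  if (R == 0) stop("no labelings supplied")
  n <- length(labelings[[1]])
  stopifnot(all(vapply(labelings, length, 1L) == n))
  if (is.null(condition_ids)) condition_ids <- paste0("c", seq_len(n))

  M <- matrix(0, n, n)
  for (lab in labelings) {
    for (cl in setdiff(unique(lab), 0L)) {
      m <- which(lab == cl)
      M[m, m] <- M[m, m] + 1
    }
  }
  M <- M / R
  diag(M) <- 1

  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  # average linkage is monotone; clamp float-level height inversions
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  raw <- stats::cutree(hc, h = cut)
  lik <- membership_likelihood(M, raw)
  label <- raw
  label[lik < 0.5] <- 0L
  # renumber surviving groups compactly (size-descending happens at filter)
  kept <- setdiff(unique(label), 0L)
  label <- match(label, kept, nomatch = 0L)

  assignment <- data.frame(condition = condition_ids, label = as.integer(label),
                           likelihood = lik, stringsAsFactors = FALSE)
  dimnames(M) <- list(condition_ids, condition_ids)
  structure(list(assignment = assignment, coassoc = M, n_runs = R),
            class = "ds_assignment")
}

# Mean co-association of each point with the other members of its group;
# singletons score 0 (no supporting co-membership evidence).
membership_likelihood <- function(M, labels) {
  vapply(seq_along(labels), function(i) {
    m <- setdiff(which(labels == labels[i] & labels != 0L), i)
    if (labels[i] == 0L) return(0)
    if (!length(m)) return(0)
    mean(M[i, m])
  }, numeric(1))
}

#' Filter disease states by size and compound support
#'
#' Clusters with fewer than `min_size` conditions or fewer than
#' `min_compounds` distinct compounds are relabeled non-state; survivors
#' are renumbered by descending size (ties by first appearance), and
#' membership likelihoods are recomputed against the final clusters.
#'
#' @param consensus a `ds_assignment` ([consensus_cluster()]).
#' @param compound_of character vector: compound of each condition, aligned
#'   with the assignment rows.
#' @param min_size minimum conditions per state (default 20).
#' @param min_compounds minimum distinct compounds per state (default 2).
#' @return a filtered `ds_assignment` (labels `DS1..DSk` as integers 1..k).
#' @export
filter_disease_states <- function(consensus, compound_of,
                                  min_size = 20, min_compounds = 2) {
  a <- consensus$assignment
  stopifnot(length(compound_of) == nrow(a))
  keep <- c()
  for (cl in setdiff(unique(a$label), 0L)) {
    m <- a$label == cl
    if (sum(m) >= min_size &&
        length(unique(compound_of[m])) >= min_compounds) keep <- c(keep, cl)
  }
  sizes <- vapply(keep, function(cl) sum(a$label == cl), 1L)
  keep <- keep[order(-sizes, match(keep, a$label[a$label %in% keep]))]
  new <- match(a$label, keep, nomatch = 0L)
  a$label <- as.integer(new)
  a$likelihood <- membership_likelihood(consensus$coassoc, a$label)
  structure(list(assignment = a, coassoc = consensus$coassoc,
                 n_runs = consensus$n_runs),
            class = "ds_assignment")
}

#' End-to-end disease-state discovery
#'
#' Pearson distance over normalized physiology, `n_runs` stochastic t-SNE
#' embeddings, severity smoothing on each map, DBSCAN over the
#' severity-selected conditions of each run, co-association consensus, and
#' the size/compound filter.
#'
#' @param phys a `normalized_physiology` object.
#' @param calls phenotype call matrix over the same conditions
#'   ([call_condition_phenotypes()]); conditions absent from `calls` count
#'   as severity 0.
#' @param n_runs number of embed-smooth-cluster runs (default 100).
#' @param perplexity,min_pts,eps t-SNE / DBSCAN parameters; `eps = NULL`
#'   takes the per-run knee of the sorted `min_pts`-NN distance curve.
#' @param severity_threshold smoothed total severity above which a
#'   condition enters the clustering (default 0.5 phenotype-equivalents).
#' @param min_size,min_compounds disease-state filters.
#' @param seed master seed; run seeds are derived deterministically.
#' @return `ds_assignment` with extra fields `runs` (per-run seeds and
#'   cluster counts) and `smoothed_severity` (mean over runs).
#' @export
discover_states <- function(phys, calls, n_runs = 100, perplexity = 30,
                            min_pts = 5, eps = NULL,
                            severity_threshold = 0.5,
                            min_size = 20, min_compounds = 2, seed = 1L) {
  X <- phys$matrix
  treated <- phys$conditions$dose != "control"
  X <- X[treated, , drop = FALSE]
  compound_of <- phys$conditions$compound[treated]
  ids <- rownames(X)

  sev <- numeric(length(ids))
  for (tis in c("liver", "kidney")) {
    s <- severity_score(calls, tis)
    hit <- match(ids, names(s))
    sev <- sev + ifelse(is.na(hit), 0, s[hit])
  }

  D <- pearson_distance(X)
  seeds <- derive_seeds(seed, n_runs)
  labelings <- vector("list", n_runs)
  runs <- data.frame(seed = seeds, n_clusters = NA_integer_,
                     eps = NA_real_, n_selected = NA_integer_)
  sm_acc <- numeric(length(ids))
  for (r in seq_len(n_runs)) {
    emb <- embed_conditions(D, seed = seeds[r], perplexity = perplexity)
    sm <- impute_severity(emb, sev)
    sm_acc <- sm_acc + sm
    sel <- which(sm > severity_threshold)
    lab <- integer(length(ids))
    if (length(sel) >= min_pts) {
      e <- if (is.null(eps)) knee_eps(emb$coords[sel, , drop = FALSE],
                                      k = min_pts) else eps
      lab_sel <- density_cluster(emb$coords[sel, , drop = FALSE],
                                 eps = e, min_pts = min_pts)
      lab[sel] <- lab_sel
      runs$eps[r] <- e
    }
    runs$n_clusters[r] <- length(setdiff(unique(lab), 0L))
    runs$n_selected[r] <- length(sel)
    labelings[[r]] <- lab
  }

  cons <- consensus_cluster(labelings, condition_ids = ids)
  out <- filter_disease_states(cons, compound_of,
                               min_size = min_size,
                               min_compounds = min_compounds)
  out$runs <- runs
  out$smoothed_severity <- stats::setNames(sm_acc / n_runs, ids)
  out
}

#' Exhaustive consensus-partition oracle (small n)
#'
#' Enumerates every partition of `n <= 10` items and returns one that
#' minimizes the summed disagreement with the co-association matrix,
#' `sum_ij |M_ij - [same cluster]|`. Used only as an independent check of
#' [consensus_cluster()] on tiny fixtures.
#'
#' @param M co-association matrix.
#' @return integer labels of a minimizing partition.
#' @export
consensus_partition_oracle <- function(M) {
  n <- nrow(M)
  stopifnot(n <= 10)
  parts <- set_partitions(n)
  cost <- vapply(parts, function(lab) {
    same <- outer(lab, lab, "==")
    sum(abs(M - same)[upper.tri(M)])
  }, numeric(1))
  parts[[which.min(cost)]]
}

# All set partitions of n items as label vectors (restricted growth strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, maxlab) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(maxlab + 1L)) {
      rec(c(labels, l), max(maxlab, l))
    }
  }
  rec(integer(0), 0L)
  out
}
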