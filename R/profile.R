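#' Physiology deviation of each disease state
#'
#' Unpaired two-sided Wilcoxon rank-sum test of each parameter between the
#' conditions of each state and the non-state pool, Benjamini-Hochberg
#' adjusted across the whole state x parameter grid. The sign is the sign
#' of the median difference (state minus non-state).
#'
#' @param phys `normalized_physiology` (or a conditions x parameters
#'   matrix).
#' @param assignment `ds_assignment`, or a data frame with columns
#'   condition and label.
#' @param q_threshold reporting threshold recorded in the output's
#'   `significant` column (default 1e-10).
#' @return long data frame: ds, parameter, p, sign, q, signed_log_q,
#'   significant.
#' @export
physiology_deviation <- function(phys, assignment, q_threshold = 1e-10) {
  X <- if (inherits(phys, "normalized_physiology")) phys$matrix else phys
  a <- assignment_frame(assignment)
  a <- a[a$condition %in% rownames(X), , drop = FALSE]
  states <- sort(setdiff(unique(a$label), 0L))
  if (!length(states)) stop("no disease states in the assignment")
  non <- a$condition[a$label == 0L]
  if (!length(non)) stop("non-state pool is empty")

  res <- list()
  for (ds in states) {
    mem <- a$condition[a$label == ds]
    if (length(mem) < 2) stop("state ", ds, " has fewer than 2 members")
    for (p in colnames(X)) {
      x <- X[mem, p]; y <- X[non, p]
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
      res[[length(res) + 1L]] <- data.frame(
        ds = ds, parameter = p, p = ht$p.value,
        sign = sign(stats::median(x) - stats::median(y)),
        n_ds = length(x), n_non = length(y))
    }
  }
  out <- add_signed_log_q(do.call(rbind, res))
  out$significant <- out$q < q_threshold
  out
}

#' Histopathology enrichment of each disease state
#'
#' One-sided Fisher (hypergeometric) enrichment of each called phenotype in
#' each state, restricted to conditions with at least one histopathology
#' call, BH-adjusted across the grid. Enrichment only: the sign is +1.
#'
#' @param calls phenotype call matrix.
#' @param assignment `ds_assignment` or condition/label data frame.
#' @param q_threshold reporting threshold (default 5e-3).
#' @return long data frame: ds, phenotype, p, sign, q, signed_log_q,
#'   significant.
#' @export
histopath_enrichment <- function(calls, assignment, q_threshold = 5e-3) {
  a <- assignment_frame(assignment)
  a <- a[a$condition %in% rownames(calls), , drop = FALSE]
  calls <- calls[a$condition, , drop = FALSE]
  with_obs <- rowSums(calls) >= 1
  if (!any(with_obs)) stop("no conditions with histopathology observations")
  a <- a[with_obs, , drop = FALSE]
  calls <- calls[with_obs, , drop = FALSE]

  N <- nrow(calls)
  states <- sort(setdiff(unique(a$label), 0L))
  res <- list()
  for (ds in states) {
    in_ds <- a$label == ds
    n_ds <- sum(in_ds)
    for (ph in colnames(calls)) {
      K <- sum(calls[, ph])
      k <- sum(calls[in_ds, ph])
      p <- stats::phyper(k - 1, K, N - K, n_ds, lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        ds = ds, phenotype = ph, p = p, sign = 1,
        n_in_ds = k, n_total = K)
    }
  }
  out <- add_signed_log_q(do.call(rbind, res))
  out$significant <- out$q < q_threshold
  out
}

#' Compound-class overrepresentation in disease states
#'
#' One-sided Fisher enrichment of each compound class within each state,
#' counted per condition (default) or per compound, BH-adjusted.
#'
#' @param classes data frame compound -> class.
#' @param assignment `ds_assignment` or condition/label data frame
#'   (condition ids `compound|dose|time`).
#' @param unit `"condition"` or `"compound"` counting.
#' @param q_threshold reporting threshold (default 1e-2).
#' @return long data frame: ds, class, p, q, signed_log_q, significant.
#' @export
class_overrepresentation <- function(classes, assignment,
                                     unit = c("condition", "compound"),
                                     q_threshold = 1e-2) {
  unit <- match.arg(unit)
  a <- assignment_frame(assignment)
  a$compound <- vapply(strsplit(a$condition, "|", fixed = TRUE), `[`, "", 1)
  unknown <- setdiff(a$compound, classes$compound)
  if (length(unknown))
    stop("compounds without class annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  a$class <- classes$class[match(a$compound, classes$compound)]

  states <- sort(setdiff(unique(a$label), 0L))
  res <- list()
  for (ds in states) {
    if (unit == "condition") {
      in_ds <- a$label == ds
      cls <- a$class
    } else {
      by_cmp <- tapply(a$label == ds, a$compound, any)
      in_ds <- as.vector(by_cmp)
      cls <- classes$class[match(names(by_cmp), classes$compound)]
    }
    if (!any(in_ds)) {
      warning("state ", ds, " is empty under unit=", unit, "; skipped")
      next
    }
    N <- length(in_ds); n_ds <- sum(in_ds)
    for (cc in sort(unique(cls))) {
      K <- sum(cls == cc)
      k <- sum(cls == cc & in_ds)
      p <- stats::phyper(k - 1, K, N - K, n_ds, lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        ds = ds, class = cc, p = p, sign = 1, n_in_ds = k, n_class = K)
    }
  }
  out <- add_signed_log_q(do.call(rbind, res))
  out$significant <- out$q < q_threshold
  out
}

#' Prevalidated elastic-net classification of one disease state
#'
#' Binary elastic-net (L1/L2) logistic classifier separating one state's
#' conditions from the rest, with sample weights reciprocal to class sizes,
#' stratified fold construction (members and non-members binned
#' separately), inner cross-validated regularization selection maximizing
#' AUROC, and out-of-fold (prevalidated) probabilities averaged over
#' repeated fold splits. The pooled AUROC is computed on those
#' prevalidated probabilities, so every condition is scored by models that
#' never saw it.
#'
#' @param delta `expression_delta` or a genes x conditions matrix.
#' @param assignment `ds_assignment` or condition/label data frame.
#' @param ds state id to classify.
#' @param folds,repeats cross-validation design (default 10 x 10).
#' @param alpha elastic-net mixing (default 0.5).
#' @param nlambda regularization path length.
#' @param seed seed for the fold splits.
#' @param foldid optional repeats x n integer matrix of fold assignments
#'   (overrides the internal stratified splits; used by leakage tests).
#' @return list: `probability` (named, prevalidated), `auroc`, `y`,
#'   `folds`, `repeats`.
#' @export
prevalidated_classifier <- function(delta, assignment, ds, folds = 10,
                                    repeats = 10, alpha = 0.5, nlambda = 30,
                                    seed = 1L, foldid = NULL,
                                    inner_nfolds = 3) {
  X <- if (inherits(delta, "expression_delta")) delta$delta else delta
  a <- assignment_frame(assignment)
  a <- a[a$condition %in% colnames(X), , drop = FALSE]
  x <- t(X[, a$condition, drop = FALSE])
  y <- as.integer(a$label == ds)
  if (all(y == 1L) || all(y == 0L)) stop("classification needs both classes")
  if (sum(y) < folds || sum(1 - y) < folds)
    stop("each class needs at least `folds` members")
  n <- length(y)

  if (is.null(foldid)) {
    set.seed(seed)
    foldid <- t(vapply(seq_len(repeats), function(r) {
      f <- integer(n)
      f[y == 1L] <- sample(rep_len(seq_len(folds), sum(y)))
      f[y == 0L] <- sample(rep_len(seq_len(folds), sum(1 - y)))
      f
    }, integer(n)))
  }
  stopifnot(nrow(foldid) == repeats, ncol(foldid) == n)

  prob <- matrix(NA_real_, repeats, n)
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      hold <- foldid[r, ] == f
      ytr <- y[!hold]
      # class weights reciprocal to the training-set class sizes, so a
      # held-out condition can never influence its own model
      wtr <- ifelse(ytr == 1L, 1 / sum(ytr), 1 / sum(1 - ytr))
      set.seed(seed * 1000L + r * 100L + f)
      fit <- train_elastic_net(x[!hold, , drop = FALSE], ytr, wtr,
                               alpha = alpha, nlambda = nlambda,
                               nfolds = inner_nfolds)
      prob[r, hold] <- as.numeric(stats::predict(
        fit$model, x[hold, , drop = FALSE], s = fit$lambda,
        type = "response"))
    }
  }
  p_bar <- colMeans(prob)
  auroc <- as.numeric(pROC::auc(pROC::roc(y, p_bar, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
  list(probability = stats::setNames(p_bar, a$condition), auroc = auroc,
       y = y, folds = folds, repeats = repeats)
}

#' Random-baseline AUROC distribution for the state classifier
#'
#' Repeats the full prevalidated classification on pseudo-states of the
#' same size drawn at random, giving the chance-level AUROC distribution.
#'
#' @inheritParams prevalidated_classifier
#' @param n_draws number of random pseudo-states.
#' @return numeric vector of AUROC values.
#' @export
classifier_baseline <- function(delta, assignment, ds, n_draws = 20,
                                folds = 10, repeats = 10, alpha = 0.5,
                                nlambda = 30, seed = 1L) {
  X <- if (inherits(delta, "expression_delta")) delta$delta else delta
  a <- assignment_frame(assignment)
  a <- a[a$condition %in% colnames(X), , drop = FALSE]
  size <- sum(a$label == ds)
  vapply(seq_len(n_draws), function(i) {
    set.seed(seed + 31L * i)
    pseudo <- a
    pseudo$label <- 0L
    pseudo$label[sample(nrow(a), size)] <- ds
    prevalidated_classifier(X, pseudo, ds, folds = folds, repeats = repeats,
                            alpha = alpha, nlambda = nlambda,
                            seed = seed + 31L * i)$auroc
  }, numeric(1))
}

# Rank-based AUROC of a score vector against binary labels (ties averaged).
rank_auc <- function(y, score) {
  r <- rank(score)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Elastic-net training with inner cross-validated lambda selection
# maximizing AUROC on a shared regularization path. The model engine is
# glmnet; only the fold bookkeeping is local (kept lean because the outer
# prevalidation loop calls this hundreds of times).
train_elastic_net <- function(x, y, w, alpha = 0.5, nlambda = 30,
                              nfolds = 3) {
  master <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                           weights = w, nlambda = nlambda,
                           lambda.min.ratio = 0.02)
  path <- master$lambda
  n <- length(y)
  fold <- integer(n)
  fold[y == 1L] <- sample(rep_len(seq_len(nfolds), sum(y == 1L)))
  fold[y == 0L] <- sample(rep_len(seq_len(nfolds), sum(y == 0L)))
  aucs <- matrix(NA_real_, nfolds, length(path))
  for (f in seq_len(nfolds)) {
    ho <- fold == f
    fit <- glmnet::glmnet(x[!ho, , drop = FALSE], y[!ho],
                          family = "binomial", alpha = alpha,
                          weights = w[!ho], lambda = path)
    pred <- stats::predict(fit, x[ho, , drop = FALSE], type = "link")
    aucs[f, seq_len(ncol(pred))] <-
      apply(pred, 2, function(s) rank_auc(y[ho], s))
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  # one-standard-error parsimony rule: strongest regularization whose mean
  # inner AUROC is within one SE of the best, guarding against selection
  # noise on null-like folds
  se_auc <- apply(aucs, 2, stats::sd) / sqrt(nfolds)
  best <- which.max(mean_auc)
  ok <- which(mean_auc >= mean_auc[best] - se_auc[best])
  list(model = master, lambda = path[min(ok)])
}

# Accept either a ds_assignment or a bare condition/label data frame.
assignment_frame <- function(assignment) {
  a <- if (inherits(assignment, "ds_assignment")) assignment$assignment
  else assignment
  stopifnot(all(c("condition", "label") %in% names(a)))
  a
}
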