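#' Cumulative (area-under-curve) expression over the repeated-dose window
#'
#' Trapezoidal integral of each gene's expression trajectory over the
#' available time points, in (log2-delta x days) units.
#'
#' @param mat genes x time-points matrix for one treatment (columns in
#'   time order; columns that are all-`NA` are dropped).
#' @param times numeric times (days) matching the columns.
#' @return named numeric vector of per-gene AUCs.
#' @export
cumulative_expression <- function(mat, times) {
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1)
  stopifnot(ncol(mat) == length(times))
  keep <- colSums(!is.na(mat)) > 0
  mat <- mat[, keep, drop = FALSE]
  times <- times[keep]
  if (length(times) < 2) stop("need at least 2 time points for an AUC")
  stopifnot(!is.unsorted(times, strictly = TRUE))
  dt <- diff(times)
  mid <- (mat[, -ncol(mat), drop = FALSE] + mat[, -1, drop = FALSE]) / 2
  drop(mid %*% dt)
}

#' Correlate per-gene features with a whole-body outcome
#'
#' Tie-corrected Spearman correlation of each gene's feature (cumulative
#' or per-time-point expression) with the outcome (day-29 body weight or
#' per-day food consumption), with plasma-protein flags.
#'
#' @param features genes x samples matrix.
#' @param outcome numeric outcome aligned with the columns.
#' @param plasma_genes optional character vector of plasma-protein-encoding
#'   gene ids to flag.
#' @return data frame: gene, rho, plasma (logical), ranked by rho.
#' @export
correlate_with_outcome <- function(features, outcome, plasma_genes = NULL) {
  stopifnot(ncol(features) == length(outcome))
  if (stats::sd(outcome, na.rm = TRUE) == 0) stop("constant outcome")
  rho <- apply(features, 1, function(x)
    stats::cor(x, outcome, method = "spearman", use = "complete.obs"))
  out <- data.frame(gene = rownames(features), rho = rho,
                    plasma = if (is.null(plasma_genes)) NA else
                      rownames(features) %in% plasma_genes)
  rownames(out) <- NULL
  out[order(-out$rho), ]
}

# Implied covariance of (8 indicators, body weight) for the two-factor
# structural model. theta layout:
#  1:3  free liver loadings (first fixed at 1)
#  4:6  free kidney loadings (first fixed at 1)
#  7:8  structural l, k
#  9:11 Cholesky of the latent covariance: log c11, c21, log c22
# 12:19 log residual sd of the 8 indicators
#  20   log residual sd of body weight
implied_sigma <- function(theta) {
  Lam <- matrix(0, 8, 2)
  Lam[1:4, 1] <- c(1, theta[1:3])
  Lam[5:8, 2] <- c(1, theta[4:6])
  beta <- theta[7:8]
  C <- matrix(c(exp(theta[9]), theta[10], 0, exp(theta[11])), 2, 2)
  Psi <- C %*% t(C)
  Theta <- diag(exp(theta[12:19])^2, 8)
  sig_b <- exp(theta[20])^2
  Sxx <- Lam %*% Psi %*% t(Lam) + Theta
  Sxb <- Lam %*% Psi %*% beta
  Sbb <- drop(t(beta) %*% Psi %*% beta) + sig_b
  rbind(cbind(Sxx, Sxb), c(Sxb, Sbb))
}

sem_discrepancy <- function(theta, S) {
  Sig <- implied_sigma(theta)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  val <- logdet + sum(diag(chol2inv(ch) %*% S))
  if (!is.finite(val)) 1e10 else val
}

#' Latent Igf1-activity regression of day-29 body weight
#'
#' Two-factor measurement model: four liver indicators load on a liver
#' latent activity and four kidney indicators on a kidney latent (first
#' loading of each tissue fixed at 1, latents freely correlated); body
#' weight is structurally regressed on both latents
#' (`bw = l * L_liver + k * L_kidney + residual`). Parameters maximize
#' the multivariate-normal likelihood of the sample covariance
#' (quasi-Newton); standard errors come from the inverse observed
#' information, with Wald z and p per parameter.
#'
#' @param indicators data frame or matrix with 8 columns: the four liver
#'   indicator genes then the four kidney ones (cumulative expression).
#' @param body_weight day-29 body-weight change, aligned with the rows.
#' @param exclude optional logical/index vector of rows to drop (e.g. a
#'   designated compound class refit).
#' @return list of class `igf1_fit`: `estimates` (data frame with
#'   estimate, se, z, p for l, k and the free loadings), `l`, `k`,
#'   `converged`, `n`, `objective`.
#' @export
fit_igf1_latent_model <- function(indicators, body_weight, exclude = NULL) {
  X <- as.matrix(indicators)
  stopifnot(ncol(X) == 8, nrow(X) == length(body_weight))
  dat <- cbind(X, bw = body_weight)
  if (!is.null(exclude)) dat <- dat[!seq_len(nrow(dat)) %in% which(exclude | FALSE), , drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 30) stop("need at least 30 complete cases; have ", n)
  S <- stats::cov(dat) * (n - 1) / n
  if (any(diag(S) <= 0))
    stop("zero-variance indicator(s): ",
         paste(colnames(dat)[diag(S) <= 0], collapse = ", "))
  # S may be singular in the zero-measurement-noise limit; the ML
  # discrepancy only inverts the implied covariance, so that is fine.

  # Method-of-moments starting values. Triad estimate of each latent
  # variance (exact when measurement error vanishes, since the reference
  # loading is 1): psi = S21 * S31 / S32; loadings and residuals follow,
  # and the structural coefficients solve the 2x2 normal equations of the
  # reference indicators against body weight.
  triad <- function(i1, i2, i3) {
    v <- S[i2, i1] * S[i3, i1] / S[i3, i2]
    if (!is.finite(v) || v <= 0) v <- S[i1, i1] / 2
    min(v, S[i1, i1])
  }
  psi_l <- triad(1, 2, 3)
  psi_k <- triad(5, 6, 7)
  psi_lk <- S[1, 5]
  # keep the start inside the positive-definite cone
  psi_lk <- sign(psi_lk) * min(abs(psi_lk), 0.95 * sqrt(psi_l * psi_k))
  lam_l <- S[2:4, 1] / psi_l
  lam_k <- S[6:8, 5] / psi_k
  Psi0 <- matrix(c(psi_l, psi_lk, psi_lk, psi_k), 2)
  beta0 <- tryCatch(solve(Psi0, c(S[1, 9], S[5, 9])),
                    error = function(e) c(0, 0))
  th_ind <- pmax(diag(S)[1:8] - c(1, lam_l, 1, lam_k)^2 *
                   rep(c(psi_l, psi_k), each = 4), 1e-8)
  th_bw <- max(S[9, 9] - drop(t(beta0) %*% Psi0 %*% beta0), 1e-8)
  C0 <- t(chol(Psi0))
  start <- c(lam_l, lam_k, beta0,
             log(C0[1, 1]), C0[2, 1], log(C0[2, 2]),
             log(sqrt(th_ind)), log(sqrt(th_bw)))

  lower <- rep(-Inf, 20)
  lower[c(12:19, 20)] <- log(1e-5)  # residual-sd floor
  opt <- stats::optim(start, sem_discrepancy, S = S, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = 500, factr = 1e7))
  opt <- stats::optim(opt$par, sem_discrepancy, S = S, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = 500, factr = 1e7))
  conv <- opt$convergence == 0
  opt$par <- unname(opt$par)
  H <- stats::optimHess(opt$par, sem_discrepancy, S = S)
  info <- (n / 2) * H       # observed information of the log-likelihood
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    conv <- FALSE
    se <- rep(NA_real_, 20)
  } else {
    se <- sqrt(diag(vc))
  }

  free <- c(paste0("lambda_liver_", 2:4), paste0("lambda_kidney_", 2:4),
            "l", "k")
  est <- opt$par[1:8]
  ses <- se[1:8]
  z <- est / ses
  estimates <- data.frame(parameter = free, estimate = est, se = ses, z = z,
                          p = 2 * stats::pnorm(-abs(z)))
  structure(list(estimates = estimates, l = opt$par[7], k = opt$par[8],
                 se_l = ses[7], se_k = ses[8],
                 converged = conv, n = n, objective = opt$value,
                 theta = opt$par),
            class = "igf1_fit")
}

#' @export
print.igf1_fit <- function(x, ...) {
  cat("Latent Igf1-activity regression of body weight (n =", x$n, ")\n")
  cat(sprintf("  liver  l = %.4f (se %.4f)\n", x$l, x$se_l))
  cat(sprintf("  kidney k = %.4f (se %.4f)\n", x$k, x$se_k))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Regression of food consumption on Gdf15 expression
#'
#' Ordinary least squares of daily food consumption on liver and kidney
#' Gdf15 expression, pooled and (when strata are given) with a
#' stratum-by-expression categorical interaction; strata with fewer than
#' three samples are excluded with a warning.
#'
#' @param food numeric outcome (food consumption per day).
#' @param gdf15_liver,gdf15_kidney expression covariates.
#' @param strata optional stratum labels (e.g. day-29 disease-state
#'   groups).
#' @param min_stratum minimum samples per included stratum (default 3).
#' @return list: `pooled` (lm), `stratified` (lm or NULL), `slopes`
#'   (per-stratum liver/kidney slope, se, p), `excluded_strata`.
#' @export
gdf15_food_regression <- function(food, gdf15_liver, gdf15_kidney,
                                  strata = NULL, min_stratum = 3) {
  df <- data.frame(food = food, liver = gdf15_liver, kidney = gdf15_kidney)
  mm <- cbind(1, df$liver, df$kidney)
  if (kappa(crossprod(mm)) > 1e12) stop("collinear Gdf15 covariates")
  pooled <- stats::lm(food ~ liver + kidney, data = df)

  stratified <- NULL
  slopes <- NULL
  excluded <- character()
  if (!is.null(strata)) {
    df$stratum <- factor(strata)
    sizes <- table(df$stratum)
    excluded <- names(sizes)[sizes < min_stratum]
    if (length(excluded)) {
      warning("excluding strata with < ", min_stratum, " samples: ",
              paste(excluded, collapse = ", "))
      df <- droplevels(df[!df$stratum %in% excluded, , drop = FALSE])
    }
    stratified <- if (nlevels(df$stratum) > 1) {
      stats::lm(food ~ stratum + stratum:liver + stratum:kidney, data = df)
    } else {
      stats::lm(food ~ liver + kidney, data = df)
    }
    cf <- summary(stratified)$coefficients
    rows <- grep("(^|:)(liver|kidney)$", rownames(cf))
    slopes <- data.frame(
      term = rownames(cf)[rows],
      stratum = ifelse(grepl(":", rownames(cf)[rows]),
                       sub("^stratum(.*):(liver|kidney)$", "\\1",
                           rownames(cf)[rows]),
                       levels(df$stratum)[1]),
      tissue = sub("^.*:", "", rownames(cf)[rows]),
      estimate = cf[rows, 1], se = cf[rows, 2], p = cf[rows, 4])
    rownames(slopes) <- NULL
  }
  list(pooled = pooled, stratified = stratified, slopes = slopes,
       excluded_strata = excluded)
}
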