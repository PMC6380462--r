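#' @keywords internal
"_PACKAGE"

#' Build the canonical condition identifier
#'
#' A condition is one (compound, dose level, time point) cell of the
#' experimental grid; this string is the key used to align every matrix in
#' the pipeline.
#'
#' @param compound,dose,time_point character vectors of equal length.
#' @return character vector of condition ids.
#' @export
condition_id <- function(compound, dose, time_point) {
  paste(compound, dose, time_point, sep = "|")
}

#' The eight scheduled time-point labels, in order
#'
#' Single-dose animals are sacrificed at 3-24 h; repeated-dose animals at
#' 4-29 days.
#' @return character vector of length 8.
#' @export
time_grid <- function() {
  c("3 hr", "6 hr", "9 hr", "24 hr", "4 day", "8 day", "15 day", "29 day")
}

#' Repeated-dose time points in days
#' @return named numeric vector (days) for the repeated-dose arm.
#' @export
repeat_dose_days <- function() {
  c("4 day" = 4, "8 day" = 8, "15 day" = 15, "29 day" = 29)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper used for recovery checks of planted states; the non-state
#' pool counts as one class.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
label_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(as.character(a), as.character(b))
}

#' Bilinear interpolation on a regular grid
#'
#' @param gx,gy increasing grid coordinates.
#' @param z matrix of surface values, `length(gx)` x `length(gy)`.
#' @param x,y query coordinates (clamped to the grid hull).
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_interp <- function(gx, gy, z, x, y) {
  stopifnot(nrow(z) == length(gx), ncol(z) == length(gy))
  x <- pmin(pmax(x, gx[1]), gx[length(gx)])
  y <- pmin(pmax(y, gy[1]), gy[length(gy)])
  ix <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
  tx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    z[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Signed log10 transform of a p-value
#'
#' @param p p-value(s) in (0, 1].
#' @param sign direction of the effect (-1, 0, +1).
#' @return `sign * -log10(p)`.
#' @keywords internal
signed_log10 <- function(p, sign) {
  sign * -log10(pmax(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg signed log q-values over a statistic grid
#'
#' Adjusts raw p-values across the whole grid and attaches the directional
#' summary `signed_log_q = sign * -log10(q)`.
#'
#' @param df data frame with columns `p` and `sign`.
#' @return `df` with columns `q` and `signed_log_q` appended.
#' @keywords internal
add_signed_log_q <- function(df) {
  df$q <- stats::p.adjust(df$p, method = "BH")
  df$signed_log_q <- signed_log10(df$q, df$sign)
  df
}

# Deterministic child seeds below 2^31, derived from one master seed.
derive_seeds <- function(master_seed, n, stream = 0L) {
  (as.integer(master_seed) %% 100000L) * 10000L + stream * 1000L + seq_len(n)
}
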