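#' Average animal replicates to condition level
#'
#' One row per (compound, dose, time_point); each value is the arithmetic
#' mean of the non-missing replicates. A condition with zero non-missing
#' replicates for a parameter keeps `NA` and is flagged, never silently
#' zeroed.
#'
#' @param per_animal data frame with key columns and numeric parameter
#'   columns.
#' @param key_columns columns identifying a condition.
#' @param value_columns numeric columns to average; default everything that
#'   is not a key and not `animal_id`.
#' @return condition-level data frame with an `n_replicates` column and a
#'   `flagged_missing` attribute (condition/parameter pairs with no data).
#' @export
average_replicates <- function(per_animal,
                               key_columns = c("compound", "dose", "time_point"),
                               value_columns = NULL) {
  stopifnot(all(key_columns %in% names(per_animal)))
  if (is.null(value_columns)) {
    value_columns <- setdiff(names(per_animal), c(key_columns, "animal_id"))
  }
  key <- interaction(per_animal[key_columns], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  out <- per_animal[first, key_columns, drop = FALSE]
  ord <- match(levels(key), key[first])  # level order -> row order
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$n_replicates <- as.integer(table(key))
  flagged <- NULL
  for (v in value_columns) {
    x <- per_animal[[v]]
    if (!is.numeric(x)) stop("value column not numeric: ", v)
    m <- tapply(x, key, function(z) mean(z, na.rm = TRUE))
    m[is.nan(m)] <- NA_real_
    if (anyNA(m)) {
      flagged <- rbind(flagged, data.frame(
        condition = names(m)[is.na(m)], parameter = v))
    }
    out[[v]] <- as.numeric(m)
  }
  attr(out, "flagged_missing") <- flagged
  out
}

#' Normalize condition-level physiology to IQR units
#'
#' Each parameter is centered (cohort mean by default, or the matched
#' vehicle value of the same compound and time point) and divided by its
#' interquartile range across all conditions, computed with linearly
#' interpolated quantiles. Constant parameters are rejected by name.
#'
#' @param cond condition-level table ([average_replicates()] output).
#' @param mode `"cohort"` (center on the cohort mean) or `"vehicle"`
#'   (center on the matched control condition).
#' @param parameters parameter columns; default all `param_*`-like numeric
#'   columns (anything numeric other than `n_replicates`).
#' @return list of class `normalized_physiology`: `matrix` (condition x
#'   parameter, rownames are condition ids), `center`, `iqr`, `mode`,
#'   `conditions` (the key columns).
#' @export
normalize_physiology <- function(cond, mode = c("cohort", "vehicle"),
                                 parameters = NULL) {
  mode <- match.arg(mode)
  if (is.null(parameters)) {
    parameters <- setdiff(names(cond)[vapply(cond, is.numeric, TRUE)],
                          "n_replicates")
  }
  if (nrow(cond) < 4) stop("need at least 4 conditions to normalize")
  X <- as.matrix(cond[, parameters, drop = FALSE])
  ids <- condition_id(cond$compound, cond$dose, cond$time_point)
  rownames(X) <- ids

  iqr <- apply(X, 2, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7)
    unname(q[2] - q[1])
  })
  if (any(iqr == 0)) {
    stop("constant parameter(s): ",
         paste(parameters[iqr == 0], collapse = ", "))
  }

  if (mode == "cohort") {
    center <- colMeans(X, na.rm = TRUE)
    Xc <- sweep(X, 2, center, "-")
  } else {
    veh_id <- condition_id(cond$compound, "control", cond$time_point)
    vrow <- match(veh_id, ids)
    if (anyNA(vrow[cond$dose != "control"])) {
      miss <- ids[cond$dose != "control" & is.na(vrow)]
      stop("no matched vehicle for: ", paste(utils::head(miss, 5), collapse = ", "))
    }
    center <- X[vrow, , drop = FALSE]
    Xc <- X - center
  }
  Xn <- sweep(Xc, 2, iqr, "/")
  structure(list(matrix = Xn, center = center, iqr = iqr, mode = mode,
                 conditions = cond[, c("compound", "dose", "time_point")]),
            class = "normalized_physiology")
}

#' Project-level curation ratio
#'
#' The vehicle-to-treated animal ratio used as the evidence threshold in
#' histopathology curation (0.336 for the full rat cohort: 5,950 vehicle
#' and 17,685 toxin-treated animals).
#'
#' @param n_vehicle_rats,n_toxin_rats positive animal counts.
#' @return `n_vehicle_rats / n_toxin_rats`.
#' @export
curation_threshold <- function(n_vehicle_rats, n_toxin_rats) {
  stopifnot(n_vehicle_rats > 0)
  if (n_toxin_rats <= 0) stop("toxin-treated animal count must be positive")
  n_vehicle_rats / n_toxin_rats
}

#' Curate histopathology findings against the vehicle background
#'
#' Findings are stratified into (tissue, phenotype, topography, grade)
#' tuples. For each tuple the number of distinct vehicle animals and
#' compound-treated animals showing it is counted; the tuple is kept iff it
#' is enriched under compound treatment, i.e. `n_veh / n_cmp < r0` under
#' the default comparator. Tuples seen only in vehicles are dropped and
#' logged. All findings of retained tuples pass through.
#'
#' @param findings per-animal findings with columns animal_id, compound,
#'   dose, time_point, tissue, phenotype, topography, grade; vehicle arms
#'   have dose `"control"`.
#' @param r0 curation ratio ([curation_threshold()]).
#' @param keep_if `"lt"` keeps tuples with ratio strictly below `r0`
#'   (compound-enrichment reading, default); `"gt"` keeps the complement.
#' @return retained findings, with attributes `tuples` (per-tuple counts
#'   and decision) and `vehicle_only` (tuples dropped for lack of treated
#'   support).
#' @export
curate_histopathology <- function(findings, r0, keep_if = c("lt", "gt")) {
  keep_if <- match.arg(keep_if)
  stopifnot(r0 > 0)
  need <- c("animal_id", "dose", "tissue", "phenotype", "topography", "grade")
  stopifnot(all(need %in% names(findings)))
  if (!nrow(findings)) return(findings)

  tuple <- paste(findings$tissue, findings$phenotype, findings$topography,
                 findings$grade, sep = "\r")
  is_veh <- findings$dose == "control"
  n_veh <- tapply(ifelse(is_veh, findings$animal_id, NA), tuple,
                  function(a) length(unique(stats::na.omit(a))))
  n_cmp <- tapply(ifelse(!is_veh, findings$animal_id, NA), tuple,
                  function(a) length(unique(stats::na.omit(a))))
  ratio <- ifelse(n_cmp > 0, n_veh / n_cmp, Inf)
  keep <- if (keep_if == "lt") ratio < r0 else ratio > r0
  keep[n_cmp == 0] <- FALSE  # vehicle-only artifact

  tuples <- data.frame(do.call(rbind, strsplit(names(n_veh), "\r", fixed = TRUE)),
                       n_vehicle = as.integer(n_veh),
                       n_compound = as.integer(n_cmp),
                       ratio = as.numeric(ratio), kept = unname(keep))
  names(tuples)[1:4] <- c("tissue", "phenotype", "topography", "grade")
  out <- findings[keep[tuple], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tuples") <- tuples
  attr(out, "vehicle_only") <- tuples[tuples$n_compound == 0, , drop = FALSE]
  out
}

#' Call condition-level phenotypes from curated findings
#'
#' A (condition, tissue, phenotype) cell is called 1 when at least one
#' animal of that condition has a retained finding of that phenotype;
#' topography and grade are collapsed. Supporting animal counts are kept.
#'
#' @param retained curated findings ([curate_histopathology()]).
#' @param conditions optional character vector of condition ids fixing the
#'   row universe (conditions without findings get all-zero rows).
#' @return binary matrix conditions x "tissue:phenotype" with a `support`
#'   attribute holding the per-cell animal counts.
#' @export
call_condition_phenotypes <- function(retained, conditions = NULL) {
  cid <- condition_id(retained$compound, retained$dose, retained$time_point)
  feat <- paste(retained$tissue, retained$phenotype, sep = ":")
  if (is.null(conditions)) conditions <- sort(unique(cid))
  feats <- sort(unique(feat))
  calls <- matrix(0L, length(conditions), max(length(feats), 1L),
                  dimnames = list(conditions,
                                  if (length(feats)) feats else "none"))
  support <- calls
  if (nrow(retained)) {
    key <- paste(cid, feat, sep = "\r")
    cnt <- tapply(retained$animal_id, key, function(a) length(unique(a)))
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    ci <- match(vapply(parts, `[`, "", 1), conditions)
    fi <- match(vapply(parts, `[`, "", 2), feats)
    ok <- !is.na(ci) & !is.na(fi)
    support[cbind(ci[ok], fi[ok])] <- as.integer(cnt[ok])
    calls[support > 0] <- 1L
  }
  attr(calls, "support") <- support
  calls
}

#' Vehicle-subtracted condition-level expression
#'
#' Averages replicates per condition gene-wise, then subtracts the matched
#' vehicle profile (same compound and time point, dose `"control"`).
#'
#' @param mat genes x samples log2 expression matrix.
#' @param samples sample map with sample_id, compound, dose, time_point.
#' @param tissue tissue tag carried through.
#' @return list of class `expression_delta`: `delta` (genes x treated
#'   conditions, log2 ratio vs matched vehicle), `conditions`, `tissue`.
#' @export
normalize_expression <- function(mat, samples, tissue = "liver") {
  stopifnot(all(samples$sample_id %in% colnames(mat)))
  cid <- condition_id(samples$compound, samples$dose, samples$time_point)
  conds <- unique(cid)
  prof <- sapply(conds, function(cc)
    rowMeans(mat[, samples$sample_id[cid == cc], drop = FALSE]))
  info <- samples[match(conds, cid), c("compound", "dose", "time_point")]
  treated <- which(info$dose != "control")
  veh_id <- condition_id(info$compound, "control", info$time_point)
  vcol <- match(veh_id, conds)
  if (anyNA(vcol[treated])) {
    miss <- conds[treated][is.na(vcol[treated])]
    stop("missing matched vehicle profile for: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  delta <- prof[, treated, drop = FALSE] - prof[, vcol[treated], drop = FALSE]
  colnames(delta) <- conds[treated]
  structure(list(delta = delta,
                 conditions = info[treated, , drop = FALSE],
                 tissue = tissue),
            class = "expression_delta")
}

#' Vehicle-subtracted food-consumption / body-weight series
#'
#' For each treated (compound, dose) the vehicle series of the same
#' compound is subtracted time point by time point:
#' `delta = treated - vehicle`, so negative means less intake (or weight)
#' than vehicle. Set `flip = TRUE` for the opposite convention. Missing
#' time points stay missing.
#'
#' @param series long data frame: compound, dose, time, value; vehicles
#'   have dose `"control"`.
#' @param flip flip the sign convention.
#' @return long data frame compound, dose, time, delta for treated rows.
#' @export
normalize_food_bodyweight <- function(series, flip = FALSE) {
  stopifnot(all(c("compound", "dose", "time", "value") %in% names(series)))
  veh <- series[series$dose == "control", , drop = FALSE]
  trt <- series[series$dose != "control", , drop = FALSE]
  vkey <- paste(veh$compound, veh$time, sep = "\r")
  if (anyDuplicated(vkey)) stop("duplicated vehicle series entries")
  vv <- veh$value[match(paste(trt$compound, trt$time, sep = "\r"), vkey)]
  if (anyNA(vv) && any(!is.na(trt$value[is.na(vv)])))
    stop("treated series has time points absent from the vehicle grid")
  delta <- trt$value - vv
  if (flip) delta <- -delta
  data.frame(compound = trt$compound, dose = trt$dose, time = trt$time,
             delta = delta, stringsAsFactors = FALSE)
}
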