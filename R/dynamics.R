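#' Per-treatment state sequences over the time grid
#'
#' One sequence per (compound, dose) scheduled at all time points: the
#' state label assigned at each time point, `0` for non-state, `"dead"`
#' from the recorded death time on.
#'
#' @param assignment `ds_assignment` or condition/label data frame with
#'   condition ids `compound|dose|time`.
#' @param schedule data frame of (compound, dose) pairs scheduled at all
#'   time points.
#' @param time_points ordered time labels (default the 8-point grid).
#' @param deaths optional data frame (compound, dose, time_point) giving
#'   the first time point at which animals died; that point and all later
#'   ones are marked dead.
#' @return character matrix, rows = `compound|dose`, columns = time
#'   points; entries `"0"`, `"1"`.. or `"dead"`.
#' @export
build_sequences <- function(assignment, schedule, time_points = time_grid(),
                            deaths = NULL) {
  a <- assignment_frame(assignment)
  if (anyDuplicated(a$condition))
    stop("duplicated (compound, dose, time_point) in assignment")
  key <- do.call(rbind, strsplit(a$condition, "|", fixed = TRUE))
  lab <- stats::setNames(as.character(a$label),
                         paste(key[, 1], key[, 2], key[, 3], sep = "|"))

  seqs <- matrix("0", nrow(schedule), length(time_points),
                 dimnames = list(paste(schedule$compound, schedule$dose,
                                       sep = "|"),
                                 time_points))
  for (i in seq_len(nrow(schedule))) {
    ids <- condition_id(schedule$compound[i], schedule$dose[i], time_points)
    hit <- lab[ids]
    seqs[i, !is.na(hit)] <- hit[!is.na(hit)]
  }
  if (!is.null(deaths)) {
    for (i in seq_len(nrow(deaths))) {
      row <- paste(deaths$compound[i], deaths$dose[i], sep = "|")
      from <- match(deaths$time_point[i], time_points)
      if (row %in% rownames(seqs) && !is.na(from))
        seqs[row, from:length(time_points)] <- "dead"
    }
  }
  seqs
}

#' Disease-state transition network
#'
#' Each sequence is reduced to its run of states: dead entries terminate
#' the sequence, non-state interludes are skipped, consecutive repeats are
#' collapsed (persisting in a state is not a transition, and re-entering
#' the same state after a non-state gap contributes no edge). Each
#' adjacent pair in the collapsed run is a directed transition; edges
#' supported by fewer than `min_compounds` distinct compounds are dropped.
#'
#' @param seqs sequence matrix ([build_sequences()]).
#' @param min_compounds edge support filter (default 2).
#' @return list: `edges` (from, to, n_transitions, n_compounds), `nodes`
#'   (state, n_treatments), `graph` (igraph object).
#' @export
transition_graph <- function(seqs, min_compounds = 2) {
  trans <- list()
  node_treat <- list()
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    dead <- which(s == "dead")
    if (length(dead)) s <- s[seq_len(min(dead) - 1L)]
    s <- s[s != "0"]
    if (length(s)) s <- s[c(TRUE, s[-1] != s[-length(s)])]  # collapse repeats
    compound <- sub("\\|.*$", "", rownames(seqs)[i])
    for (st in unique(s))
      node_treat[[st]] <- c(node_treat[[st]], rownames(seqs)[i])
    if (length(s) >= 2) {
      for (j in seq_len(length(s) - 1L)) {
        trans[[length(trans) + 1L]] <- data.frame(
          from = s[j], to = s[j + 1L], compound = compound)
      }
    }
  }
  nodes <- data.frame(
    state = names(node_treat),
    n_treatments = vapply(node_treat, function(x) length(unique(x)), 1L))
  rownames(nodes) <- NULL

  if (length(trans)) {
    tr <- do.call(rbind, trans)
    key <- paste(tr$from, tr$to, sep = "->")
    uk <- sort(unique(key))
    edges <- data.frame(
      from = sub("->.*$", "", uk),
      to = sub("^.*->", "", uk),
      n_transitions = as.integer(table(key)[uk]),
      n_compounds = as.integer(tapply(tr$compound, key,
                                      function(x) length(unique(x)))[uk]))
    edges <- edges[edges$n_compounds >= min_compounds, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        n_transitions = integer(), n_compounds = integer())
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    vertices = if (nrow(nodes)) nodes else NULL, directed = TRUE)
  if (nrow(edges)) {
    igraph::E(g)$n_transitions <- edges$n_transitions
    igraph::E(g)$n_compounds <- edges$n_compounds
  }
  list(edges = edges, nodes = nodes, graph = g)
}

#' Summary counts over state sequences
#'
#' @param seqs sequence matrix ([build_sequences()]).
#' @return list: `n` sequences, `n_any_ds` (>= 1 state at some point),
#'   `n_multi_ds` (> 1 distinct state), `pct_any_ds` / `pct_multi_ds`
#'   (rounded to the nearest integer), `n_dead` (sequences hitting a dead
#'   entry), `n_complete` (sequences with no dead entry).
#' @export
sequence_summary <- function(seqs) {
  states_of <- apply(seqs, 1, function(s)
    unique(s[s != "0" & s != "dead"]))
  n_states <- vapply(states_of, length, 1L)
  n <- nrow(seqs)
  n_any <- sum(n_states >= 1L)
  n_multi <- sum(n_states > 1L)
  n_dead <- sum(apply(seqs, 1, function(s) any(s == "dead")))
  list(n = n, n_any_ds = n_any, n_multi_ds = n_multi,
       pct_any_ds = round(100 * n_any / n),
       pct_multi_ds = round(100 * n_multi / n),
       n_dead = n_dead, n_complete = n - n_dead)
}

#' Time-resolved pathway activity for day-29 outcome groups
#'
#' At each time point, the per-condition enrichment scores of each pathway
#' are compared between a group (fixed by the day-29 state, e.g. tolerance
#' vs tissue injury) and its complement with a two-sided Wilcoxon test,
#' reported as signed log10 p.
#'
#' @param es_by_time named list: time point -> sets x conditions
#'   enrichment-score matrix (conditions = treatments measured at that
#'   time).
#' @param groups named character vector: treatment -> group label.
#' @param group label of the foreground group.
#' @return matrix pathways x time points of signed log10 p scores.
#' @export
timecourse_activity <- function(es_by_time, groups, group) {
  stopifnot(length(es_by_time) >= 1)
  out <- sapply(names(es_by_time), function(tp) {
    es <- es_by_time[[tp]]
    g <- groups[colnames(es)]
    fg <- which(g == group)
    bg <- which(g != group)
    if (!length(fg) || !length(bg))
      stop("group '", group, "' empty (or exhaustive) at time point ", tp)
    apply(es, 1, function(v) {
      if (length(unique(v)) == 1L) return(0)
      p <- suppressWarnings(stats::wilcox.test(v[fg], v[bg])$p.value)
      signed_log10(p, sign(stats::median(v[fg]) - stats::median(v[bg])))
    })
  })
  matrix(out, nrow = nrow(es_by_time[[1]]),
         dimnames = list(rownames(es_by_time[[1]]), names(es_by_time)))
}
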