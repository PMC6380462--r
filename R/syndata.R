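#' Configuration for the synthetic toxicogenomic cohort
#'
#' Defines the study design the generator emulates: a compound x dose x
#' time-point grid with quintuplicate physiology/histopathology animals and
#' triplicate expression profiles, planted disease states with
#' state-defining physiology shifts (in eventual IQR units), state-enriched
#' histopathology phenotypes, planted pathway shifts, and a planted
#' latent-factor / regression structure for the whole-body analyses.
#'
#' @param n_compounds number of compounds on the grid.
#' @param doses treated dose levels (vehicles are generated separately as
#'   dose `"control"`).
#' @param time_points ordered sacrifice labels; default is the 8-point grid.
#' @param n_phys_params number of physiology parameters (default 37).
#' @param n_genes size of the measured gene universe.
#' @param n_states number K of planted disease states.
#' @param compounds_per_state compounds dedicated to each planted state.
#' @param params_per_state state-defining physiology parameters per state
#'   (disjoint across states).
#' @param phys_effect_size shift of state-defining parameters, in units of
#'   the cohort interquartile range of the condition-level values.
#' @param histo_baseline_rate per-animal, per-phenotype rate of background
#'   findings (vehicles and treated alike), confined to the
#'   background-prone phenotypes.
#' @param histo_background_phenotypes number of common phenotypes (taken
#'   from the end of the vocabulary, disjoint from planted ones) that occur
#'   spontaneously in all arms.
#' @param histo_state_rate per-animal rate of a state's phenotypes in
#'   conditions bearing that state.
#' @param phenotypes_per_state distinct phenotypes planted per state.
#' @param n_phenotypes size of the phenotype vocabulary.
#' @param pathway_effect mean log2 shift of planted pathway genes in
#'   state-bearing conditions.
#' @param expr_condition_sd sd of the per-condition biological expression
#'   effect (gene-wise, treated arms only); this is what makes different
#'   treatments transcriptionally distinct beyond the planted pathways.
#' @param pathways_per_state planted (up, down) gene-set pairs per state.
#' @param n_phys_replicates animals per condition for physiology/histology.
#' @param n_expr_replicates expression replicates per condition.
#' @param onset_index index into `time_points` from which high-dose
#'   conditions of state compounds carry the state; the middle dose joins at
#'   the last two time points.
#' @param schedule optional explicit transition schedule: data frame with
#'   columns compound, dose, time_point, state (`0` = no state). Overrides
#'   the default onset-based planting.
#' @param igf1 list of whole-body latent parameters: structural
#'   coefficients `l` (liver) and `k` (kidney), indicator `loadings` (first
#'   fixed at 1 per tissue), `latent_sd`, `indicator_sd`, `bw_sd`.
#' @param gdf15 list: `intercept`, per-stratum named lists of
#'   `slope_liver` / `slope_kidney`, and `noise_sd`.
#' @param seed master RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_compounds = 25,
                       doses = c("low", "middle", "high"),
                       time_points = time_grid(),
                       n_phys_params = 37,
                       n_genes = 1500,
                       n_states = 4,
                       compounds_per_state = 5,
                       params_per_state = 5,
                       phys_effect_size = 3,
                       histo_baseline_rate = 0.01,
                       histo_background_phenotypes = 3,
                       histo_state_rate = 0.6,
                       phenotypes_per_state = 2,
                       n_phenotypes = 12,
                       pathway_effect = 2,
                       pathways_per_state = 1,
                       expr_condition_sd = 1,
                       n_phys_replicates = 5,
                       n_expr_replicates = 3,
                       onset_index = 4,
                       schedule = NULL,
                       igf1 = list(l = 0.8, k = 0.2,
                                   loadings_liver = c(1, 0.9, -0.8, -0.7),
                                   loadings_kidney = c(1, 0.8, -0.9, -0.6),
                                   latent_sd = 1, indicator_sd = 0.3,
                                   bw_sd = 0.5),
                       gdf15 = list(intercept = 25,
                                    slopes = list(
                                      injury = c(liver = -0.3, kidney = -0.5),
                                      other  = c(liver = -0.1, kidney = -0.1)),
                                    noise_sd = 0.5),
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_compounds = n_compounds, n_phys_params = n_phys_params,
              n_genes = n_genes, n_states = n_states,
              n_phys_replicates = n_phys_replicates,
              n_expr_replicates = n_expr_replicates,
              n_phenotypes = n_phenotypes)
  if (any(counts <= 0)) {
    stop("all counts must be positive; offending: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  if (n_states * compounds_per_state > n_compounds)
    stop("not enough compounds to host ", n_states, " planted states")
  if (n_states * params_per_state > n_phys_params)
    stop("not enough physiology parameters for disjoint state definitions")
  if (n_states * phenotypes_per_state + histo_background_phenotypes > n_phenotypes)
    stop("not enough phenotypes for disjoint state and background sets")
  stopifnot(is.finite(phys_effect_size), is.finite(pathway_effect),
            expr_condition_sd >= 0,
            histo_baseline_rate >= 0, histo_baseline_rate <= 1,
            histo_state_rate >= 0, histo_state_rate <= 1,
            igf1$latent_sd > 0, igf1$indicator_sd >= 0, igf1$bw_sd >= 0,
            gdf15$noise_sd >= 0)
  if (!is.null(schedule)) {
    need <- c("compound", "dose", "time_point", "state")
    if (!all(need %in% names(schedule)))
      stop("schedule needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(setdiff(unique(schedule$state), 0L), seq_len(n_states))
    if (length(bad))
      stop("schedule references unknown states: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

phenotype_vocabulary <- function(n) {
  terms <- c("necrosis", "hypertrophy", "eosinophilic change", "degeneration",
             "bile duct proliferation", "single cell necrosis",
             "cell infiltration", "fibrosis", "extramedullary hematopoiesis",
             "vacuolization", "regeneration", "swelling", "atrophy",
             "congestion", "mineralization", "edema")
  if (n > length(terms)) terms <- c(terms, paste0("phenotype_", seq_len(n)))
  terms[seq_len(n)]
}

# Default planting: state s owns compounds ((s-1)*cps+1):(s*cps); its high
# dose carries the state from onset_index on, the middle dose at the last
# two time points.
default_schedule <- function(cfg) {
  cps <- cfg$compounds_per_state
  tp <- cfg$time_points
  grid <- expand.grid(compound = paste0("cmpd_", sprintf("%02d", seq_len(cfg$n_compounds))),
                      dose = cfg$doses, time_point = tp,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- 0L
  for (s in seq_len(cfg$n_states)) {
    cmp <- paste0("cmpd_", sprintf("%02d", ((s - 1) * cps + 1):(s * cps)))
    hi <- grid$compound %in% cmp & grid$dose == "high" &
      match(grid$time_point, tp) >= cfg$onset_index
    mid <- grid$compound %in% cmp & grid$dose == "middle" &
      match(grid$time_point, tp) >= length(tp) - 1L
    grid$state[hi | mid] <- s
  }
  grid
}

#' Simulate the per-animal physiology and histopathology cohort
#'
#' Generates quintuplicate per-animal physiology tables (treated arms plus a
#' vehicle arm for every compound/time point), per-animal histopathology
#' findings, a compound-class table, and the planted ground truth used by
#' recovery tests. State-bearing conditions have their state-defining
#' parameters shifted by `phys_effect_size` in eventual IQR units;
#' state phenotypes are drawn at `histo_state_rate` on top of a baseline
#' rate shared with vehicles.
#'
#' @param config a [sim_config()].
#' @return list with elements `physiology` (per-animal table), `findings`
#'   (per-animal histopathology), `classes` (compound -> class), and
#'   `truth` (planted labels, parameter signs, phenotypes, schedule).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  sched <- if (is.null(cfg$schedule)) default_schedule(cfg) else cfg$schedule
  sched$condition <- condition_id(sched$compound, sched$dose, sched$time_point)
  if (anyDuplicated(sched$condition))
    stop("schedule contains duplicated (compound, dose, time_point) cells")
  compounds <- sort(unique(sched$compound))

  # Disjoint state-defining parameter sets, with signs; disjointness rules
  # out ambiguous (opposite-sign, same-parameter) truth by construction.
  params <- sprintf("param_%02d", seq_len(cfg$n_phys_params))
  pool <- sample(params)
  affected <- lapply(seq_len(cfg$n_states), function(s) {
    idx <- ((s - 1) * cfg$params_per_state + 1):(s * cfg$params_per_state)
    data.frame(state = s, parameter = pool[idx],
               sign = sample(c(-1, 1), cfg$params_per_state, replace = TRUE))
  })
  affected <- do.call(rbind, affected)

  vocab <- phenotype_vocabulary(cfg$n_phenotypes)
  state_tissue <- rep(c("liver", "kidney"), length.out = cfg$n_states)
  planted_histo <- lapply(seq_len(cfg$n_states), function(s) {
    idx <- ((s - 1) * cfg$phenotypes_per_state + 1):(s * cfg$phenotypes_per_state)
    data.frame(state = s, tissue = state_tissue[s], phenotype = vocab[idx])
  })
  planted_histo <- do.call(rbind, planted_histo)

  # Per-parameter measurement scale/location; condition-level biological
  # spread sets the eventual IQR unit (IQR of a normal = 1.349 sd).
  scale_p <- 10^stats::runif(cfg$n_phys_params, -1, 2)
  mu_p <- stats::rnorm(cfg$n_phys_params, 50, 10) * scale_p
  cond_sd <- 1
  animal_sd <- 0.5
  iqr_unit <- 2 * stats::qnorm(0.75) * cond_sd

  all_rows <- rbind(
    sched[, c("compound", "dose", "time_point", "state")],
    data.frame(compound = rep(compounds, each = length(cfg$time_points)),
               dose = "control",
               time_point = rep(cfg$time_points, times = length(compounds)),
               state = 0L))
  n_cond <- nrow(all_rows)

  shift <- matrix(0, n_cond, cfg$n_phys_params,
                  dimnames = list(NULL, params))
  for (r in seq_len(nrow(affected))) {
    rows <- all_rows$state == affected$state[r]
    shift[rows, affected$parameter[r]] <-
      affected$sign[r] * cfg$phys_effect_size * iqr_unit
  }
  cond_dev <- matrix(stats::rnorm(n_cond * cfg$n_phys_params, 0, cond_sd),
                     n_cond, cfg$n_phys_params)

  nrep <- cfg$n_phys_replicates
  idx <- rep(seq_len(n_cond), each = nrep)
  animal <- matrix(stats::rnorm(length(idx) * cfg$n_phys_params, 0, animal_sd),
                   length(idx), cfg$n_phys_params)
  values <- sweep((cond_dev + shift)[idx, , drop = FALSE] + animal, 2,
                  scale_p, "*")
  values <- sweep(values, 2, mu_p, "+")
  colnames(values) <- params
  physiology <- data.frame(
    animal_id = paste0("an_", seq_along(idx)),
    compound = all_rows$compound[idx], dose = all_rows$dose[idx],
    time_point = all_rows$time_point[idx], values,
    stringsAsFactors = FALSE, check.names = FALSE)

  # Histopathology findings per animal: background everywhere, planted
  # phenotypes at the state rate in state-bearing conditions.
  background <- vocab[(cfg$n_phenotypes - cfg$histo_background_phenotypes + 1):
                        cfg$n_phenotypes]
  topos <- c("periportal", "centrilobular", "diffuse")
  grades <- c("minimal", "slight", "moderate", "severe")
  tissues <- c("liver", "kidney")
  n_an <- length(idx)
  find_list <- list()
  for (tis in tissues) {
    for (ph in vocab) {
      hit <- if (ph %in% background)
        stats::runif(n_an) < cfg$histo_baseline_rate else rep(FALSE, n_an)
      pl <- planted_histo[planted_histo$tissue == tis &
                            planted_histo$phenotype == ph, , drop = FALSE]
      if (nrow(pl)) {
        in_state <- all_rows$state[idx] %in% pl$state
        hit[in_state] <- stats::runif(sum(in_state)) < cfg$histo_state_rate
      }
      if (!any(hit)) next
      w <- which(hit)
      find_list[[length(find_list) + 1L]] <- data.frame(
        animal_id = physiology$animal_id[w],
        compound = physiology$compound[w], dose = physiology$dose[w],
        time_point = physiology$time_point[w],
        tissue = tis, phenotype = ph,
        topography = sample(topos, length(w), replace = TRUE),
        grade = sample(grades, length(w), replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)),
        stringsAsFactors = FALSE)
    }
  }
  findings <- if (length(find_list)) do.call(rbind, find_list) else
    data.frame(animal_id = character(), compound = character(),
               dose = character(), time_point = character(),
               tissue = character(), phenotype = character(),
               topography = character(), grade = character())
  rownames(findings) <- NULL

  classes <- data.frame(compound = compounds, class = "misc",
                        stringsAsFactors = FALSE)
  for (s in seq_len(cfg$n_states)) {
    cmp <- unique(sched$compound[sched$state == s])
    classes$class[classes$compound %in% cmp] <- paste0("class_", LETTERS[s])
  }

  truth <- list(
    state_of_condition = stats::setNames(all_rows$state,
                                         condition_id(all_rows$compound,
                                                      all_rows$dose,
                                                      all_rows$time_point)),
    affected_parameters = affected,
    planted_histo = planted_histo,
    schedule = sched,
    state_tissue = state_tissue)

  list(physiology = physiology, findings = findings, classes = classes,
       truth = truth)
}

#' Random gene-set collection over the simulated gene universe
#'
#' @param config a [sim_config()].
#' @param n_sets number of gene sets.
#' @param set_size members per set (sampled with replacement across sets,
#'   without within a set).
#' @return named list of gene-id vectors.
#' @export
make_gene_sets <- function(config, n_sets = 50, set_size = 30) {
  set.seed(config$seed + 7L)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  names(sets) <- sprintf("pathway_%03d", seq_len(n_sets))
  sets
}

#' Simulate replicate-level log2 expression per tissue
#'
#' Three replicates per condition and matched vehicle profiles; genes in a
#' state's planted pathways are shifted by `pathway_effect` (up set) or its
#' negative (down set) in conditions bearing that state, in the state's
#' tissue. All other entries are independent Gaussian noise on the log2
#' scale.
#'
#' @param config a [sim_config()].
#' @param truth truth component of [simulate_cohort()].
#' @param gene_sets named list of gene sets (e.g. [make_gene_sets()]).
#' @return list per tissue: `matrix` (genes x samples, log2),
#'   `samples` (sample map with compound/dose/time_point/replicate), and
#'   `planted` (state, tissue, pathway, direction).
#' @export
simulate_expression <- function(config, truth, gene_sets) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 13L)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  if (!length(gene_sets)) stop("gene_sets is empty")
  if (!all(unlist(gene_sets) %in% genes))
    stop("gene_sets contain genes outside the simulated universe")

  n_per_state <- cfg$pathways_per_state
  need <- cfg$n_states * n_per_state * 2
  if (length(gene_sets) < need)
    stop("need at least ", need, " gene sets to plant pathway shifts")
  ids <- names(gene_sets)
  planted <- do.call(rbind, lapply(seq_len(cfg$n_states), function(s) {
    base <- (s - 1) * 2 * n_per_state
    data.frame(state = s, tissue = truth$state_tissue[s],
               pathway = ids[base + seq_len(2 * n_per_state)],
               direction = rep(c(1, -1), each = n_per_state))
  }))

  cond <- data.frame(condition = names(truth$state_of_condition),
                     state = unname(truth$state_of_condition))
  key <- do.call(rbind, strsplit(cond$condition, "|", fixed = TRUE))
  cond$compound <- key[, 1]; cond$dose <- key[, 2]; cond$time_point <- key[, 3]

  out <- list()
  for (tis in c("liver", "kidney")) {
    shift_g <- matrix(0, cfg$n_genes, nrow(cond),
                      dimnames = list(genes, cond$condition))
    pl <- planted[planted$tissue == tis, , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      members <- gene_sets[[pl$pathway[r]]]
      in_state <- cond$state == pl$state[r]
      shift_g[members, in_state] <- pl$direction[r] * cfg$pathway_effect
    }
    # treated conditions carry their own biological expression state;
    # vehicle arms sit at the shared reference
    cond_eff <- matrix(stats::rnorm(cfg$n_genes * nrow(cond),
                                    0, cfg$expr_condition_sd),
                       cfg$n_genes)
    cond_eff[, cond$dose == "control"] <- 0
    nrep <- cfg$n_expr_replicates
    samples <- cond[rep(seq_len(nrow(cond)), each = nrep),
                    c("condition", "compound", "dose", "time_point")]
    samples$replicate <- rep(seq_len(nrep), times = nrow(cond))
    samples$sample_id <- paste0(tis, "_s", seq_len(nrow(samples)))
    rownames(samples) <- NULL
    mat <- (shift_g + cond_eff)[, rep(seq_len(nrow(cond)), each = nrep),
                                drop = FALSE] +
      matrix(stats::rnorm(cfg$n_genes * nrow(samples)), cfg$n_genes)
    colnames(mat) <- samples$sample_id
    out[[tis]] <- list(matrix = mat, samples = samples,
                       planted = planted[planted$tissue == tis, , drop = FALSE])
  }
  out
}

#' Simulate the whole-body layer: latents, indicators, weight and feeding
#'
#' Draws one liver and one kidney latent activity per condition; four
#' indicator genes per tissue load on their latent (first loading 1); day-29
#' body-weight change is `l * L_liver + k * L_kidney + noise`; daily food
#' consumption responds linearly to liver and kidney Gdf15 expression with
#' stratum-specific slopes.
#'
#' @param config a [sim_config()].
#' @param n_conditions number of (compound, dose) units to simulate.
#' @param strata optional character vector of stratum labels per condition;
#'   defaults to a random split over the names of `config$gdf15$slopes`.
#' @return list with `data` (one row per condition: indicators, body
#'   weight, Gdf15 levels, food consumption, stratum) and `truth`
#'   (structural coefficients, loadings, slopes).
#' @export
simulate_wholebody <- function(config, n_conditions = 300, strata = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ig <- cfg$igf1
  stopifnot(is.finite(ig$l), is.finite(ig$k))
  set.seed(cfg$seed + 29L)
  n <- n_conditions

  L_liv <- stats::rnorm(n, 0, ig$latent_sd)
  L_kid <- stats::rnorm(n, 0, ig$latent_sd)
  ind <- function(latent, loadings, prefix) {
    m <- sapply(loadings, function(lam)
      lam * latent + stats::rnorm(n, 0, ig$indicator_sd))
    colnames(m) <- paste0(prefix, c("igf1", "igfals", "igfbp1", "igfbp2"))
    m
  }
  liv <- ind(L_liv, ig$loadings_liver, "liver_")
  kid <- ind(L_kid, ig$loadings_kidney, "kidney_")
  bw <- ig$l * L_liv + ig$k * L_kid + stats::rnorm(n, 0, ig$bw_sd)

  gd <- cfg$gdf15
  if (is.null(strata)) {
    strata <- sample(names(gd$slopes), n, replace = TRUE)
  }
  stopifnot(length(strata) == n, all(strata %in% names(gd$slopes)))
  g_liv <- stats::rnorm(n)
  g_kid <- stats::rnorm(n)
  sl <- do.call(rbind, gd$slopes)[strata, , drop = FALSE]
  food <- gd$intercept + sl[, "liver"] * g_liv + sl[, "kidney"] * g_kid +
    stats::rnorm(n, 0, gd$noise_sd)

  data <- data.frame(condition = paste0("cond_", seq_len(n)),
                     liv, kid, body_weight_day29 = bw,
                     gdf15_liver = g_liv, gdf15_kidney = g_kid,
                     food_consumption = food, stratum = strata,
                     stringsAsFactors = FALSE)
  truth <- list(l = ig$l, k = ig$k, loadings_liver = ig$loadings_liver,
                loadings_kidney = ig$loadings_kidney,
                latents = data.frame(L_liver = L_liv, L_kidney = L_kid),
                gdf15_slopes = gd$slopes, intercept = gd$intercept)
  list(data = data, truth = truth)
}

#' Write the synthetic cohort to TSV files plus a truth sidecar
#'
#' Emits the dialects the preprocessing step consumes: per-animal
#' physiology, per-animal findings, the compound-class table, and the
#' planted truth as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(cohort$physiology, "physiology.tsv")
  wr(cohort$findings, "findings.tsv")
  wr(cohort$classes, "compound_classes.tsv")
  truth <- cohort$truth
  truth$state_of_condition <- as.list(truth$state_of_condition)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
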