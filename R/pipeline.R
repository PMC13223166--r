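# Pipeline orchestration: configuration, cohort summary tables, and the
# end-to-end driver that chains every analysis stage in order.

#' Pipeline run configuration
#'
#' Defaults follow the analysis conventions: bootstrap edge-strength
#' threshold `tau = 0.6`, co-occurrence quantile `q = 0.3` (the "top 30%"
#' rule), pure-MLE CPTs (`alpha = 0`), hub degree threshold 3, LN-positive
#' denominator for co-occurrence, 200 bootstrap iterations, NACT-treated
#' patients excluded before the mapping and network stages.
#'
#' @param seed Global seed; stage seeds derive from it via [stage_seed()].
#' @param bootstrap_B Bootstrap iterations.
#' @param tau Edge-strength threshold in (0, 1].
#' @param q Co-occurrence quantile in (0, 1].
#' @param alpha CPT pseudo-count.
#' @param hub_min Hub degree threshold.
#' @param denominator_mode `"lnm_patients"` or `"all_patients"`.
#' @param exclude_nact Drop NACT patients before mapping/network stages.
#' @param clinical_variables Covariates for the augmented network.
#' @param restarts Hill-climbing restarts.
#' @param max_indegree Parent limit for structure search.
#' @param augment Run the clinical-augmentation stage (default TRUE).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, bootstrap_B = 200L, tau = 0.6, q = 0.3,
                       alpha = 0, hub_min = 3L,
                       denominator_mode = "lnm_patients",
                       exclude_nact = TRUE,
                       clinical_variables = clinical_bn_spec()$variables,
                       restarts = 0L, max_indegree = Inf,
                       augment = TRUE) {
  stopifnot(tau > 0, tau <= 1, q > 0, q <= 1, alpha >= 0,
            bootstrap_B >= 1, hub_min >= 1,
            denominator_mode %in% c("lnm_patients", "all_patients"))
  structure(list(seed = as.integer(seed),
                 bootstrap_B = as.integer(bootstrap_B),
                 tau = tau, q = q, alpha = alpha,
                 hub_min = as.integer(hub_min),
                 denominator_mode = denominator_mode,
                 exclude_nact = exclude_nact,
                 clinical_variables = clinical_variables,
                 restarts = as.integer(restarts),
                 max_indegree = max_indegree,
                 augment = augment),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# short stable hash of a configuration for report provenance lines
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Cohort summary table by lymph node status
#'
#' One row per variable level with counts in the LN-negative and
#' LN-positive groups; categorical variables compared by chi-square,
#' continuous ones by Mann-Whitney (complete-case per variable).
#'
#' @param cohort Cohort data.frame.
#' @return Data.frame: `variable`, `level`, `n_negative`, `n_positive`,
#'   `p_value` (repeated across the variable's levels).
#' @export
cohort_summary_table <- function(cohort) {
  lnm <- as.integer(lnm_positive(cohort))
  disc <- discretize_clinical(cohort)
  cont <- list(age = cohort$age, ca125 = cohort$ca125, he4 = cohort$he4,
               ascites_ml = cohort$ascites_ml,
               tumor_size_mm = cohort$tumor_size_mm)
  rows <- list()
  for (v in names(disc)) {
    x <- disc[[v]]
    tab <- table(x, lnm)
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
    for (lev in levels(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev,
        n_negative = sum(x == lev & lnm == 0, na.rm = TRUE),
        n_positive = sum(x == lev & lnm == 1, na.rm = TRUE),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  for (v in names(cont)) {
    ok <- !is.na(cont[[v]])
    p <- tryCatch(
      mann_whitney_u(cont[[v]][ok & lnm == 0],
                     cont[[v]][ok & lnm == 1])$p_value,
      error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0(v, "_median"), level = "continuous",
      n_negative = sum(ok & lnm == 0), n_positive = sum(ok & lnm == 1),
      p_value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Univariate odds ratios for the standard binary risk factors
#'
#' Each dichotomized covariate against LN status, with Woolf intervals;
#' structural-zero tables (e.g. FIGO stage, where stage I-II is
#' node-negative by definition) are Haldane-Anscombe corrected and
#' flagged.
#'
#' @param cohort Cohort data.frame.
#' @return Data.frame: `variable`, `or`, `ci_low`, `ci_high`, `corrected`,
#'   `p_value`.
#' @export
univariate_or_table <- function(cohort) {
  lnm <- as.integer(lnm_positive(cohort))
  disc <- discretize_clinical(cohort)
  vars <- list(
    age = disc$age == "1",
    menopause = disc$menopause == "1",
    ca125 = disc$ca125 == "1",
    he4 = disc$he4 == "1",
    ascites = disc$ascites == "1",
    tumor_size = disc$tumor_size == "1",
    lateralization = disc$laterality == "bilateral",
    figo = disc$figo == "III-IV",
    histology = disc$histology == "non-serous",
    nact = disc$nact == "1"
  )
  rows <- lapply(names(vars), function(v) {
    x <- as.integer(vars[[v]])
    tab <- table2x2(sum(x == 0 & lnm == 0), sum(x == 0 & lnm == 1),
                    sum(x == 1 & lnm == 0), sum(x == 1 & lnm == 1))
    orr <- tryCatch(odds_ratio_2x2(tab),
                    error = function(e) odds_ratio_2x2(tab, correction = TRUE))
    p <- tryCatch(suppressWarnings(chi_square_2x2(tab)$p_value),
                  error = function(e) NA_real_)
    data.frame(variable = v, or = orr$or, ci_low = orr$ci_low,
               ci_high = orr$ci_high, corrected = orr$corrected,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# provenance-stamped TSV writer
write_stage_tsv <- function(df, path, stage, config, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s config=%s seed=%d", stage,
                     config_hash(config), seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort summary and univariate odds ratios; forward
#' stepwise logistic selection; NACT exclusion; laterality stratification;
#' regional mapping metrics; Bayesian-network structure learning on the
#' LN-positive subset; bootstrap edge confidence; co-occurrence analysis;
#' dual-criterion pathway extraction with chain report; and (optionally)
#' the clinical-variable-augmented network.  Identical configuration and
#' cohort yield an identical bundle.
#'
#' @param config A [run_config()].
#' @param cohort Cohort data.frame or path to a cohort CSV.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written as a provenance-stamped TSV and the pathway graph as DOT.
#' @return Named list (the report bundle) with one entry per stage.
#' @export
run_pipeline <- function(config, cohort, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name, stage) {
    if (!is.null(out_dir)) {
      write_stage_tsv(df, file.path(out_dir, paste0(name, ".tsv")),
                      stage, config, config$seed)
    }
  }
  bundle <- list(config = config)

  # cohort statistics on the full cohort
  bundle$summary <- cohort_summary_table(cohort)
  emit(bundle$summary, "cohort_summary", "cohort_statistics")
  bundle$univariate <- univariate_or_table(cohort)
  emit(bundle$univariate, "univariate_or", "cohort_statistics")
  disc <- discretize_clinical(cohort)
  sig <- bundle$univariate$variable[
    !is.na(bundle$univariate$p_value) & bundle$univariate$p_value < 0.05]
  cand_map <- list(
    age = as.integer(disc$age == "1"),
    menopause = as.integer(disc$menopause == "1"),
    ca125 = as.integer(disc$ca125 == "1"),
    he4 = as.integer(disc$he4 == "1"),
    ascites = as.integer(disc$ascites == "1"),
    tumor_size = as.integer(disc$tumor_size == "1"),
    lateralization = as.integer(disc$laterality == "bilateral"),
    figo = as.integer(disc$figo == "III-IV"),
    histology = as.integer(disc$histology == "non-serous"),
    nact = as.integer(disc$nact == "1")
  )
  cands <- as.data.frame(cand_map[intersect(sig, names(cand_map))])
  bundle$stepwise <- if (ncol(cands)) {
    forward_stepwise(cands, as.integer(lnm_positive(cohort)))
  } else {
    list(selected = character(0), fit = NULL, trace = NULL)
  }
  if (!is.null(bundle$stepwise$trace)) {
    emit(bundle$stepwise$trace, "stepwise_trace", "cohort_statistics")
  }

  # mapping cohort: optionally NACT-excluded, LN-positive subset for BN
  map_cohort <- if (config$exclude_nact) {
    cohort[cohort$nact == 0, , drop = FALSE]
  } else {
    cohort
  }
  if (!any(lnm_positive(map_cohort))) {
    stop("stage nodal_mapping: no LN-positive patients after filtering; ",
         "mapping and network stages cannot run")
  }
  bundle$node_distribution <- node_level_distribution(map_cohort)
  emit(bundle$node_distribution, "node_distribution", "nodal_mapping")
  bundle$patient_distribution <- patient_level_distribution(map_cohort)
  emit(bundle$patient_distribution, "patient_distribution", "nodal_mapping")
  bundle$positivity_rate <- overall_positivity_rate(map_cohort)
  bundle$resection <- resection_summary(map_cohort)
  emit(bundle$resection, "resection_summary", "nodal_mapping")
  strata <- stratify_by_laterality(map_cohort)
  bundle$strata_sizes <- vapply(strata, nrow, 1L)

  # network stages on the LN-positive subset
  lnm_cohort <- map_cohort[lnm_positive(map_cohort), , drop = FALSE]
  zones <- lnm_cohort[, zone_names()]
  bundle$dag <- hill_climb(zones, restarts = config$restarts,
                           seed = stage_seed(config$seed, "learn"),
                           max_indegree = config$max_indegree)
  bundle$cpts <- fit_cpts(bundle$dag, zones, alpha = config$alpha)
  bundle$edges <- bootstrap_edge_strength(
    zones, B = config$bootstrap_B,
    seed = stage_seed(config$seed, "bootstrap"),
    restarts = config$restarts, max_indegree = config$max_indegree)
  emit(edge_strength_table(bundle$edges), "edge_strength", "consensus")
  bundle$cooccurrence <- cooccurrence_matrix(
    lnm_cohort, denominator_mode = config$denominator_mode)
  bundle$top_pairs <- top_quantile_pairs(bundle$cooccurrence, q = config$q)
  emit(bundle$top_pairs, "top_pairs", "consensus")
  bundle$pathways <- extract_routes(bundle$edges, bundle$top_pairs,
                                    tau = config$tau)
  bundle$pathways$node_labels <- classify_nodes(bundle$pathways,
                                                hub_min = config$hub_min)
  emit(bundle$pathways$highlighted, "pathways", "pathway_extraction")
  bundle$chains <- chain_report(bundle$pathways)
  if (!is.null(out_dir)) {
    write_dot(bundle$pathways, file.path(out_dir, "pathways.dot"))
    write_edge_list(bundle$dag, file.path(out_dir, "network_edges.tsv"))
  }

  # clinical augmentation
  if (isTRUE(config$augment)) {
    bundle$augmented <- augment_with_clinical(
      lnm_cohort, clinical_bn_spec(config$clinical_variables),
      B = config$bootstrap_B, seed = stage_seed(config$seed, "augment"),
      alpha = config$alpha, max_indegree = config$max_indegree,
      restarts = config$restarts)
    emit(edge_strength_table(bundle$augmented$edges),
         "augmented_edge_strength", "pathway_extraction")
  }
  bundle
}
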