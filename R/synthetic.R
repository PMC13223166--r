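# Synthetic cohort generator: patient-level records with known ground
# truth.  Zone involvement is sampled ancestrally from a configurable truth
# DAG with conditional probability tables; clinical covariates are sampled
# marginally (independently) unless planted covariate -> zone effects are
# configured, in which case the named covariate state shifts the zone's
# conditional log-odds.  Planted pathways use a leaky noisy-OR
# parameterisation so several routes can share a child zone.

#' Default dichotomization cutoffs for clinical covariates
#'
#' Age 50 years, CA125 264.5 U/mL, HE4 148.5 (postmenopausal) / 122.2
#' (premenopausal), ascites 90 mL, tumor size 100 mm.
#'
#' @return Named list of cutoffs.
#' @export
clinical_cutoffs <- function() {
  list(age = 50, ca125 = 264.5, he4_post = 148.5, he4_pre = 122.2,
       ascites = 90, tumor_size = 100)
}

#' Simulation configuration for synthetic cohorts
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; the configuration plus seed fully determines
#'   the generated cohort.
#' @param truth_dag `bn_dag` over the 14 zone variables (`zone_01` ..
#'   `zone_14`); default empty graph.
#' @param zone_baseline Baseline involvement probability for zones with no
#'   planted structure (default 0.05).
#' @param root_marginals Optional named vector overriding `P(zone = 1)` for
#'   root zones, e.g. `c(zone_03 = 0.6)`.
#' @param laterality_probs Probabilities of (left, right, bilateral)
#'   primary tumors, summing to 1; default 38/50/122 out of 210.
#' @param effects Optional list of planted covariate -> zone effects, each
#'   `list(variable =, state =, zone =, log_odds =)`; `variable` refers to a
#'   column of the discretized clinical frame (see
#'   [discretize_clinical()]), `zone` is a zone id, and `log_odds` shifts
#'   that zone's conditional log-odds for patients in the named state.
#' @param resected_mean,resected_size Per-zone negative-binomial mean and
#'   dispersion (size) for resected-node counts; defaults follow the
#'   typical per-zone yields of systematic lymphadenectomy (para-aortic
#'   stations largest).
#' @param positive_rate Thinning probability for additional positive nodes
#'   beyond the first in an involved zone (default 0.3).
#' @param nact_prob Probability of neoadjuvant chemotherapy (default 0.19).
#' @param figo_adv_prob Probability that a node-negative patient is stage
#'   III-IV (default 0.36); node-positive patients are always III-IV, so
#'   stage I-II implies all zones negative (the structural zero).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       truth_dag = dag_new(zone_names()),
                       zone_baseline = 0.05,
                       root_marginals = NULL,
                       laterality_probs = c(left = 38, right = 50,
                                            bilateral = 122) / 210,
                       effects = list(),
                       resected_mean = c(2.0, 2.1, 2.1, 2.0, 2.0, 1.9,
                                         2.8, 3.1, 1.7, 1.8, 5.3, 4.6,
                                         1.9, 1.9),
                       resected_size = 1.2,
                       positive_rate = 0.3,
                       nact_prob = 0.19,
                       figo_adv_prob = 0.36) {
  cfg <- structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         truth_dag = truth_dag, zone_baseline = zone_baseline,
         root_marginals = root_marginals,
         laterality_probs = laterality_probs,
         effects = effects,
         edge_strengths = numeric(0),
         resected_mean = resected_mean, resected_size = resected_size,
         positive_rate = positive_rate, nact_prob = nact_prob,
         figo_adv_prob = figo_adv_prob),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config`.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 1L) stop("invalid config: n_patients must be >= 1")
  if (abs(sum(config$laterality_probs) - 1) > 1e-9) {
    stop("invalid config: laterality_probs must sum to 1")
  }
  if (!inherits(config$truth_dag, "bn_dag") ||
      !identical(sort(config$truth_dag$nodes), sort(zone_names()))) {
    stop("invalid config: truth_dag must cover the 14 zone variables")
  }
  # dag_new / dag_add_edge guarantee acyclicity; re-check defensively
  dag_topo_sort(config$truth_dag)
  p_ok <- function(p) all(p >= 0 & p <= 1)
  if (!p_ok(config$zone_baseline) || !p_ok(config$positive_rate) ||
      !p_ok(config$nact_prob) || !p_ok(config$figo_adv_prob)) {
    stop("invalid config: probabilities must lie in [0, 1]")
  }
  if (length(config$resected_mean) != 14L || any(config$resected_mean < 0)) {
    stop("invalid config: resected_mean must be 14 non-negative means")
  }
  tabs <- truth_cpts(config)
  for (ct in tabs) {
    if (any(abs(rowSums(ct$prob) - 1) > 1e-9)) {
      stop("invalid config: CPT rows for ", ct$node, " do not sum to 1")
    }
  }
  invisible(config)
}

#' Ground-truth CPTs implied by a simulation configuration
#'
#' Root zones take their override marginal (or the baseline); zones with
#' parents follow a leaky noisy-OR with the per-edge strengths recorded by
#' [plant_pathway()]: an involved parent on a planted edge of strength `s`
#' raises the child's probability so that with a single parent
#' `P(child = 1 | parent = 1) = s` and `P(child = 1 | parent = 0)` equals
#' the baseline.
#'
#' @param config A `sim_config`.
#' @return `bn_cpts` over the zone variables.
#' @export
truth_cpts <- function(config) {
  dag <- config$truth_dag
  base <- config$zone_baseline
  out <- lapply(dag$nodes, function(v) {
    pa <- dag$parents[[v]]
    if (!length(pa)) {
      p1 <- unname(config$root_marginals[v])
      if (length(p1) != 1L || is.na(p1)) p1 <- base
      return(binary_cpt(v, p1 = p1))
    }
    q <- 2^length(pa)
    cfg_states <- as.matrix(expand.grid(rep(list(0:1), length(pa))))
    # expand.grid varies the first factor fastest -- matches CPT row order
    theta <- vapply(pa, function(u) {
      s <- unname(config$edge_strengths[paste0(u, "->", v)])
      if (length(s) != 1L || is.na(s)) s <- base
      if (base >= 1) return(1)
      min(max(1 - (1 - s) / (1 - base), 0), 1)
    }, numeric(1))
    p1 <- vapply(seq_len(q), function(r) {
      1 - (1 - base) * prod((1 - theta)^cfg_states[r, ])
    }, numeric(1))
    binary_cpt(v, pa, p1)
  })
  names(out) <- dag$nodes
  structure(out, class = "bn_cpts", alpha = 0)
}

#' Plant a metastatic pathway into a simulation configuration
#'
#' Adds the consecutive edges of `route` to the truth DAG and records the
#' edge strength so that `P(child = 1 | parent = 1) = strength` and
#' `P(child = 1 | parent = 0) = baseline` (single-parent case; multiple
#' planted parents combine by noisy-OR).
#'
#' @param config A `sim_config`.
#' @param route Ordered vector of zone ids (length >= 2).
#' @param strength `P(child = 1 | parent = 1)` along the route.
#' @param root_p1 Optional marginal for the route head if it is a root
#'   zone (e.g. 0.6 for a frequently seeded entry station).
#' @return The updated `sim_config`.
#' @examples
#' cfg <- sim_config(100, seed = 1)
#' cfg <- plant_pathway(cfg, c(3, 5, 1), strength = 0.9, root_p1 = 0.5)
#' dag_edges(cfg$truth_dag)
#' @export
plant_pathway <- function(config, route, strength, root_p1 = NULL) {
  stopifnot(inherits(config, "sim_config"), length(route) >= 2,
            strength > 0, strength <= 1)
  if (!all(route %in% 1:14)) stop("route zone ids must be in 1..14")
  vs <- zone_names(route)
  for (i in seq_len(length(vs) - 1L)) {
    u <- vs[i]
    v <- vs[i + 1L]
    if (!u %in% config$truth_dag$parents[[v]]) {
      config$truth_dag <- tryCatch(
        dag_add_edge(config$truth_dag, u, v),
        error = function(e) {
          stop("route would close a cycle at edge ", u, " -> ", v)
        })
    }
    config$edge_strengths[[paste0(u, "->", v)]] <- strength
  }
  if (!is.null(root_p1)) {
    head <- vs[1L]
    if (!length(config$truth_dag$parents[[head]])) {
      rm_ <- config$root_marginals
      if (is.null(rm_)) rm_ <- numeric(0)
      rm_[[head]] <- root_p1
      config$root_marginals <- rm_
    }
  }
  validate_sim_config(config)
  config
}

#' Discretize clinical covariates with the standard cutoffs
#'
#' Age dichotomized at 50 years, CA125 at 264.5 U/mL, HE4 at 148.5 /
#' 122.2 U/mL for post-/premenopausal patients, ascites at 90 mL, tumor
#' size at 100 mm; grade, histology, FIGO stage, parity, laterality,
#' menopause and NACT by their observed categories.
#'
#' @param cohort Cohort data.frame (see [generate_cohort()]).
#' @param cutoffs Named list as from [clinical_cutoffs()].
#' @return Data.frame of factors, one row per patient.
#' @export
discretize_clinical <- function(cohort, cutoffs = clinical_cutoffs()) {
  he4_cut <- ifelse(cohort$menopause == 1, cutoffs$he4_post, cutoffs$he4_pre)
  bin <- function(x) factor(as.integer(x), levels = 0:1)
  data.frame(
    age = bin(cohort$age >= cutoffs$age),
    menopause = bin(cohort$menopause),
    parity = factor(cohort$parity, levels = c("0", "1-3", ">3")),
    ca125 = bin(cohort$ca125 >= cutoffs$ca125),
    he4 = bin(cohort$he4 >= he4_cut),
    ascites = bin(cohort$ascites_ml >= cutoffs$ascites),
    tumor_size = bin(cohort$tumor_size_mm >= cutoffs$tumor_size),
    grade = factor(cohort$grade, levels = c("G1", "G2", "G3")),
    histology = factor(cohort$histology, levels = c("serous", "non-serous")),
    figo = factor(cohort$figo, levels = c("I-II", "III-IV")),
    laterality = factor(cohort$laterality,
                        levels = c("left", "right", "bilateral")),
    nact = bin(cohort$nact)
  )
}

#' Generate a synthetic patient cohort
#'
#' Clinical covariates are drawn marginally; zone involvement is sampled in
#' the fixed topological order of the truth DAG with any configured
#' covariate effects applied as log-odds shifts; resected-node counts are
#' negative binomial per zone, forced to at least one node in involved
#' zones; positive counts are one plus a binomial thinning of the remaining
#' resected nodes.  FIGO stage is assigned after zone sampling: any
#' involvement implies III-IV, node-negative patients are III-IV with
#' probability `figo_adv_prob`.  The same configuration and seed always
#' reproduce the identical cohort.
#'
#' @param config A [sim_config()].
#' @return Data.frame with one row per patient: identifiers, clinical
#'   covariates, `zone_01..zone_14` (0/1 involvement), `resected_01..14`
#'   and `positive_01..14` counts.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  tabs <- truth_cpts(config)
  with_seed(config$seed, {
    age <- round(pmin(pmax(stats::rnorm(n, 53, 10), 22), 90), 1)
    menopause <- stats::rbinom(n, 1, 0.535)
    parity <- sample(c("0", "1-3", ">3"), n, replace = TRUE,
                     prob = c(0.077, 0.676, 0.247))
    ca125 <- round(stats::rlnorm(n, log(330), 1.6), 1)
    he4 <- round(stats::rlnorm(n, log(170), 1.1), 1)
    ascites_ml <- round(stats::rlnorm(n, log(120), 1.5))
    tumor_size_mm <- round(stats::rlnorm(n, log(91.5), 0.5))
    grade <- sample(c("G1", "G2", "G3"), n, replace = TRUE,
                    prob = c(0.0605, 0.0988, 0.8407))
    histology <- sample(c("serous", "non-serous"), n, replace = TRUE,
                        prob = c(0.344, 0.656))
    laterality <- sample(c("left", "right", "bilateral"), n, replace = TRUE,
                         prob = config$laterality_probs)
    nact <- stats::rbinom(n, 1, config$nact_prob)

    base_frame <- data.frame(age = age, menopause = menopause,
                             parity = parity, ca125 = ca125, he4 = he4,
                             ascites_ml = ascites_ml,
                             tumor_size_mm = tumor_size_mm, grade = grade,
                             histology = histology, figo = "III-IV",
                             laterality = laterality, nact = nact,
                             stringsAsFactors = FALSE)
    disc <- discretize_clinical(base_frame)

    zones <- matrix(0L, n, 14, dimnames = list(NULL, zone_names()))
    for (v in dag_topo_sort(config$truth_dag)) {
      ct <- tabs[[v]]
      q <- nrow(ct$prob)
      cfg_idx <- rep(1L, n)
      mult <- 1L
      for (pp in ct$parents) {
        cfg_idx <- cfg_idx + zones[, pp] * mult
        mult <- mult * 2L
      }
      p1 <- ct$prob[cfg_idx, 2]
      zid <- zone_ids(v)
      for (ef in config$effects) {
        if (ef$zone == zid) {
          hit <- as.character(disc[[ef$variable]]) == as.character(ef$state)
          hit[is.na(hit)] <- FALSE
          p1 <- ifelse(hit,
                       stats::plogis(stats::qlogis(pmin(pmax(p1, 1e-9),
                                                        1 - 1e-9)) +
                                       ef$log_odds),
                       p1)
        }
      }
      zones[, v] <- stats::rbinom(n, 1, p1)
    }

    resected <- matrix(0L, n, 14, dimnames = list(NULL, sprintf("resected_%02d", 1:14)))
    positive <- matrix(0L, n, 14, dimnames = list(NULL, sprintf("positive_%02d", 1:14)))
    for (z in 1:14) {
      r <- stats::rnbinom(n, size = config$resected_size,
                          mu = config$resected_mean[z])
      inv <- zones[, z] == 1L
      r[inv] <- pmax(r[inv], 1L)
      pos <- integer(n)
      if (any(inv)) {
        pos[inv] <- 1L + stats::rbinom(sum(inv), pmax(r[inv] - 1L, 0L),
                                       config$positive_rate)
      }
      resected[, z] <- r
      positive[, z] <- pos
    }

    any_inv <- rowSums(zones) > 0
    figo <- ifelse(any_inv, "III-IV",
                   ifelse(stats::runif(n) < config$figo_adv_prob,
                          "III-IV", "I-II"))

    out <- cbind(
      data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                 stringsAsFactors = FALSE),
      base_frame[, setdiff(names(base_frame), "figo")],
      data.frame(figo = figo, stringsAsFactors = FALSE)
    )
    out <- out[, c("patient_id", "age", "menopause", "parity", "ca125",
                   "he4", "ascites_ml", "tumor_size_mm", "grade",
                   "histology", "figo", "laterality", "nact")]
    cbind(out, as.data.frame(zones), as.data.frame(resected),
          as.data.frame(positive))
  })
}

#' Which patients are lymph-node positive?
#'
#' @param cohort Cohort data.frame.
#' @return Logical vector: any involved zone.
#' @export
lnm_positive <- function(cohort) {
  rowSums(cohort[, zone_names()]) > 0
}
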