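# Regional distribution metrics: node-level and patient-level zone
# involvement, overall nodal positivity, resection summaries, and
# laterality stratification.

#' Node-level regional distribution of positive lymph nodes
#'
#' For each zone, the fraction of all positive nodes found in that zone:
#' (positive nodes in the region) / (total positive nodes).
#'
#' @param cohort Cohort data.frame with `positive_01..positive_14` columns.
#' @param atlas A [zone_atlas()] (names for the report).
#' @return Data.frame: `zone`, `name`, `n_positive`, `node_share`; shares
#'   sum to 1.  Attribute `n_positive_nodes` carries the grand total.
#' @export
node_level_distribution <- function(cohort, atlas = zone_atlas()) {
  pos <- as.matrix(cohort[, sprintf("positive_%02d", 1:14)])
  totals <- colSums(pos)
  grand <- sum(totals)
  if (grand == 0) stop("no positive nodes in cohort: distribution undefined")
  out <- data.frame(zone = 1:14, name = atlas$zones$name,
                    n_positive = unname(totals),
                    node_share = unname(totals) / grand)
  attr(out, "n_positive_nodes") <- grand
  out
}

#' Patient-level regional distribution of lymph node metastasis
#'
#' For each zone, the fraction of LN-positive patients with that zone
#' involved: (patients with positive nodes in the region) / (patients with
#' any LNM).  The denominator is the LN-positive subset, not the whole
#' cohort; set `denominator = "all_patients"` for the whole-cohort variant.
#'
#' @param cohort Cohort data.frame.
#' @param atlas A [zone_atlas()].
#' @param denominator `"lnm_patients"` (default) or `"all_patients"`.
#' @return Data.frame: `zone`, `name`, `n_patients`, `patient_share`;
#'   attribute `n_lnm_patients`.
#' @export
patient_level_distribution <- function(cohort, atlas = zone_atlas(),
                                       denominator = c("lnm_patients",
                                                       "all_patients")) {
  denominator <- match.arg(denominator)
  inv <- as.matrix(cohort[, zone_names()])
  lnm <- rowSums(inv) > 0
  if (!any(lnm)) stop("no LN-positive patients: distribution undefined")
  denom <- if (denominator == "lnm_patients") sum(lnm) else nrow(cohort)
  counts <- colSums(inv)
  out <- data.frame(zone = 1:14, name = atlas$zones$name,
                    n_patients = unname(counts),
                    patient_share = unname(counts) / denom)
  attr(out, "n_lnm_patients") <- sum(lnm)
  out
}

#' Overall lymph node positivity rate
#'
#' Total positive nodes over total resected nodes across the cohort.
#'
#' @param cohort Cohort data.frame.
#' @return Fraction in `[0, 1]`.
#' @export
overall_positivity_rate <- function(cohort) {
  res <- sum(cohort[, sprintf("resected_%02d", 1:14)])
  pos <- sum(cohort[, sprintf("positive_%02d", 1:14)])
  if (res == 0) stop("no resected nodes: positivity rate undefined")
  pos / res
}

#' Per-zone resection summary
#'
#' For each zone: total nodes removed, number of patients with at least one
#' node removed, and the median (minimum, maximum) removed per patient.
#' Zones where no patient had nodes removed report a median of 0 (with a
#' note attribute), matching the convention of reporting 0 for rarely
#' dissected stations.
#'
#' @param cohort Non-empty cohort data.frame.
#' @param atlas A [zone_atlas()].
#' @return Data.frame: `zone`, `name`, `total_removed`,
#'   `patients_with_removal`, `median_removed`, `min_removed`,
#'   `max_removed`.
#' @export
resection_summary <- function(cohort, atlas = zone_atlas()) {
  stopifnot(nrow(cohort) >= 1)
  res <- as.matrix(cohort[, sprintf("resected_%02d", 1:14)])
  out <- data.frame(
    zone = 1:14,
    name = atlas$zones$name,
    total_removed = unname(colSums(res)),
    patients_with_removal = unname(colSums(res > 0)),
    median_removed = unname(apply(res, 2, stats::median)),
    min_removed = unname(apply(res, 2, min)),
    max_removed = unname(apply(res, 2, max))
  )
  attr(out, "grand_total") <- sum(res)
  out
}

#' Stratify a cohort by primary tumor laterality
#'
#' Partitions the cohort into left-sided, right-sided and bilateral tumors;
#' optionally drops NACT-treated patients first (the default upstream of
#' the mapping and network analyses, to avoid treatment-related bias).
#'
#' @param cohort Cohort data.frame with a `laterality` column.
#' @param exclude_nact Drop records with `nact == 1` before partitioning.
#' @return Named list of three data.frames: `left`, `right`, `bilateral`.
#' @export
stratify_by_laterality <- function(cohort, exclude_nact = FALSE) {
  bad <- !cohort$laterality %in% c("left", "right", "bilateral")
  if (any(bad)) {
    stop("unknown laterality for record(s): ",
         paste(cohort$patient_id[bad], collapse = ", "))
  }
  if (exclude_nact) cohort <- cohort[cohort$nact == 0, , drop = FALSE]
  list(left = cohort[cohort$laterality == "left", , drop = FALSE],
       right = cohort[cohort$laterality == "right", , drop = FALSE],
       bilateral = cohort[cohort$laterality == "bilateral", , drop = FALSE])
}
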