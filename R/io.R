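# Cohort CSV schema, validated readers/writers, and graph/table exports.

#' Column schema of the patient cohort CSV
#'
#' @return Character vector of the 55 column names in canonical order.
#' @export
cohort_schema <- function() {
  c("patient_id", "age", "menopause", "parity", "ca125", "he4",
    "ascites_ml", "tumor_size_mm", "grade", "histology", "figo",
    "laterality", "nact",
    zone_names(), sprintf("resected_%02d", 1:14),
    sprintf("positive_%02d", 1:14))
}

#' Validate a cohort data.frame against the schema and record invariants
#'
#' Checks: exact header; binary columns contain only 0/1; counts
#' non-negative integers; `positive <= resected` per zone;
#' `zone_involved = 1` exactly when `positive >= 1`; FIGO I-II implies all
#' zones negative.  All row-level violations are collected and reported
#' together.
#'
#' @param cohort Data.frame.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  extra_cols <- setdiff(names(cohort), cohort_schema())
  if (length(missing_cols) || length(extra_cols)) {
    stop("cohort schema mismatch",
         if (length(missing_cols)) paste0("; missing: ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unexpected: ",
                                        paste(extra_cols, collapse = ", ")))
  }
  problems <- character(0)
  bad_rows <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      problems <<- c(problems,
                     paste0(what, " in row(s): ",
                            paste(utils::head(idx, 10), collapse = ", "),
                            if (length(idx) > 10) " ..."))
    }
  }
  for (col in c("menopause", "nact", zone_names())) {
    bad_rows(!cohort[[col]] %in% c(0, 1), paste0("non-binary ", col))
  }
  for (z in 1:14) {
    rz <- cohort[[sprintf("resected_%02d", z)]]
    pz <- cohort[[sprintf("positive_%02d", z)]]
    bad_rows(rz < 0 | rz != round(rz), sprintf("negative/non-integer resected_%02d", z))
    bad_rows(pz < 0 | pz > rz, sprintf("positive_%02d exceeds resected or negative", z))
    bad_rows((pz >= 1) != (cohort[[zone_names(z)]] == 1),
             sprintf("zone_%02d involvement inconsistent with positive count", z))
  }
  lnpos <- rowSums(cohort[, zone_names()]) > 0
  bad_rows(cohort$figo == "I-II" & lnpos, "FIGO I-II with involved zones")
  if (length(problems)) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(cohort)
}

#' Read or write a cohort CSV
#'
#' @param path File path.
#' @return `read_cohort` returns a validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character"))
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_schema()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export or import a DAG as an edge-list TSV
#'
#' @param dag A `bn_dag`.
#' @param path File path.
#' @export
write_edge_list <- function(dag, path) {
  e <- dag_edges(dag)
  utils::write.table(as.data.frame(e), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes Node universe for the imported graph (default: the zone
#'   variables).
#' @export
read_edge_list <- function(path, nodes = zone_names()) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  dag_new(nodes, as.matrix(e[, c("parent", "child")]))
}

#' Export a network or pathway graph in DOT format
#'
#' Pathway graphs style highlighted routes distinctly (bold red edges,
#' labelled with their bootstrap frequency).
#'
#' @param x A `bn_dag` or `pathway_graph`.
#' @param path File path.
#' @export
write_dot <- function(x, path) {
  lines <- c("digraph lnm {", "  node [shape=ellipse];")
  if (inherits(x, "bn_dag")) {
    for (v in x$nodes) lines <- c(lines, paste0("  \"", v, "\";"))
    e <- dag_edges(x)
    for (i in seq_len(nrow(e))) {
      lines <- c(lines, paste0("  \"", e[i, 1], "\" -> \"", e[i, 2], "\";"))
    }
  } else if (inherits(x, "pathway_graph")) {
    for (v in zone_names()) {
      lines <- c(lines, paste0("  \"", v, "\" [xlabel=\"",
                               x$node_labels[[v]], "\"];"))
    }
    hi <- x$highlighted
    for (i in seq_len(nrow(hi))) {
      lines <- c(lines, paste0(
        "  \"", zone_names(hi$parent[i]), "\" -> \"",
        zone_names(hi$child[i]),
        "\" [color=red, penwidth=2, label=\"",
        formatC(hi$directed_freq[i], format = "f", digits = 2), "\"];"))
    }
  } else {
    stop("cannot render object of class ", paste(class(x), collapse = "/"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Export fitted CPTs as JSON
#'
#' @param cpts A `bn_cpts`.
#' @param path File path.
#' @export
write_cpts_json <- function(cpts, path) {
  obj <- lapply(unclass(cpts), function(ct) {
    list(node = ct$node, parents = ct$parents,
         levels = ct$levels, prob = ct$prob)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
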