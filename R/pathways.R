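# Dual-criterion pathway extraction: a directed zone connection is a
# high-probability metastatic route when its bootstrap edge strength
# reaches the threshold AND its unordered pair ranks in the top quantile
# of co-occurrence, AND the two zones are anatomically plausible
# neighbours.  Excluded candidates are recorded with their first failing
# reason in the fixed order strength -> co-occurrence -> adjacency.

#' Extract high-probability metastatic routes
#'
#' @param edges An [bootstrap_edge_strength()] result.
#' @param pairs Top-quantile pair set from [top_quantile_pairs()].
#' @param atlas A [zone_atlas()].
#' @param tau Bootstrap edge-strength threshold in (0, 1]; default 0.6.
#' @return Object of class `pathway_graph`: list with `highlighted`
#'   (data.frame: parent, child zone ids, `directed_freq`, `cooccurrence`),
#'   `excluded` (same plus `reason`), `node_labels` (from
#'   [classify_nodes()]) and the `tau` used.
#' @export
extract_routes <- function(edges, pairs, atlas = zone_atlas(), tau = 0.6) {
  stopifnot(inherits(edges, "edge_strength"), tau > 0, tau <= 1)
  zone_nodes <- intersect(edges$nodes, zone_names())
  cand <- which(edges$directed_freq > 0, arr.ind = TRUE)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    pn <- edges$nodes[cand[i, 1]]
    cn <- edges$nodes[cand[i, 2]]
    if (!pn %in% zone_nodes || !cn %in% zone_nodes) next
    a <- zone_ids(pn)
    b <- zone_ids(cn)
    freq <- edges$directed_freq[cand[i, 1], cand[i, 2]]
    in_top <- any(pairs$zone_a == min(a, b) & pairs$zone_b == max(a, b))
    cooc_val <- if (in_top) {
      pairs$value[pairs$zone_a == min(a, b) & pairs$zone_b == max(a, b)][1]
    } else NA_real_
    reason <- if (freq < tau) {
      "below_strength"
    } else if (!in_top) {
      "below_cooccurrence"
    } else if (!zone_adjacent(atlas, a, b)) {
      "anatomically_distant"
    } else {
      NA_character_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parent = a, child = b, directed_freq = freq,
      cooccurrence = cooc_val, reason = reason,
      stringsAsFactors = FALSE)
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = integer(0), child = integer(0),
               directed_freq = numeric(0), cooccurrence = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  hi <- all_rows[is.na(all_rows$reason), setdiff(names(all_rows), "reason"),
                 drop = FALSE]
  ex <- all_rows[!is.na(all_rows$reason), , drop = FALSE]
  ord <- order(-hi$directed_freq, hi$parent, hi$child)
  hi <- hi[ord, , drop = FALSE]
  rownames(hi) <- rownames(ex) <- NULL
  g <- structure(list(highlighted = hi, excluded = ex, tau = tau,
                      atlas = atlas),
                 class = "pathway_graph")
  g$node_labels <- classify_nodes(g)
  g
}

#' Classify zones by their role in the pathway graph
#'
#' Hubs are zones with total degree (in + out over highlighted edges) at
#' least `hub_min`; terminals receive at least one highlighted edge and
#' emit none; zones with no highlighted edge are isolated; everything else
#' is intermediate.  Precedence: hub > terminal > intermediate > isolated,
#' so the labels partition the zones.
#'
#' @param graph A `pathway_graph`.
#' @param hub_min Minimum total degree for a hub (default 3).
#' @return Named character vector over `zone_01..zone_14`.
#' @export
classify_nodes <- function(graph, hub_min = 3L) {
  stopifnot(inherits(graph, "pathway_graph"))
  hi <- graph$highlighted
  outdeg <- indeg <- stats::setNames(integer(14), zone_names())
  for (i in seq_len(nrow(hi))) {
    outdeg[zone_names(hi$parent[i])] <- outdeg[zone_names(hi$parent[i])] + 1L
    indeg[zone_names(hi$child[i])] <- indeg[zone_names(hi$child[i])] + 1L
  }
  deg <- indeg + outdeg
  labels <- ifelse(deg >= hub_min, "hub",
                   ifelse(indeg >= 1 & outdeg == 0, "terminal",
                          ifelse(deg == 0, "isolated", "intermediate")))
  stats::setNames(labels, zone_names())
}

#' Enumerate maximal route chains through the highlighted edges
#'
#' Lists every maximal simple directed path through the highlighted edge
#' set (paths that can be extended neither backwards nor forwards), longest
#' first, ties broken lexicographically by zone sequence.  Highlighted
#' edges are aggregated across bootstrap networks and may in principle form
#' a directed cycle; cycles are broken by dropping the lowest-frequency
#' edge (with a message) before enumeration.
#'
#' @param graph A `pathway_graph`.
#' @return List of integer vectors (zone id sequences).
#' @export
chain_report <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  hi <- graph$highlighted
  if (!nrow(hi)) return(list())
  # break aggregation cycles: drop weakest edges until acyclic
  repeat {
    adj <- matrix(FALSE, 14, 14)
    adj[cbind(hi$parent, hi$child)] <- TRUE
    if (.adj_is_acyclic(adj)) break
    drop <- which.min(hi$directed_freq)
    message("cycle among highlighted edges: dropping ",
            hi$parent[drop], " -> ", hi$child[drop],
            " (frequency ", format(hi$directed_freq[drop]), ")")
    hi <- hi[-drop, , drop = FALSE]
  }
  children <- lapply(1:14, function(z) sort(hi$child[hi$parent == z]))
  indeg <- tabulate(hi$child, nbins = 14)
  starts <- sort(unique(hi$parent[indeg[hi$parent] == 0]))
  paths <- list()
  walk <- function(path) {
    nxt <- children[[path[length(path)]]]
    if (!length(nxt)) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (v in nxt) walk(c(path, v))
    }
  }
  for (s in starts) walk(s)
  key <- vapply(paths, function(p) paste(sprintf("%02d", p), collapse = "-"),
                character(1))
  paths[order(-lengths(paths), key)]
}

#' Specification of the clinical-variable-augmented network
#'
#' @param variables Discretized clinical covariates to append as network
#'   nodes; defaults to the eight key covariates: age, menopausal status,
#'   CA125, HE4, FIGO stage, histological grade, tumor size and
#'   pathological subtype.
#' @return Object of class `clinical_bn_spec`.
#' @export
clinical_bn_spec <- function(variables = c("age", "menopause", "ca125",
                                           "he4", "figo", "grade",
                                           "tumor_size", "histology")) {
  structure(list(variables = variables), class = "clinical_bn_spec")
}

#' Learn the clinical-variable-augmented network
#'
#' Appends discretized clinical covariates to the 14 zone variables and
#' runs structure learning, CPT fitting and bootstrap edge-confidence
#' estimation over the augmented node set.  Edges between clinical and
#' zone nodes are permitted in both directions unless a blacklist is
#' supplied.  Covariates with a single observed state are dropped with a
#' warning.
#'
#' @param cohort Cohort data.frame.
#' @param spec A [clinical_bn_spec()].
#' @param B Bootstrap iterations (default 100).
#' @param seed Integer seed.
#' @param alpha CPT pseudo-count (default 0).
#' @param max_indegree,blacklist,restarts Passed to the learners.
#' @return List: `dag`, `cpts`, `edges` (an `edge_strength`), `data`
#'   (the augmented discrete frame used).
#' @export
augment_with_clinical <- function(cohort, spec = clinical_bn_spec(),
                                  B = 100L, seed = 1L, alpha = 0,
                                  max_indegree = Inf, blacklist = NULL,
                                  restarts = 0L) {
  stopifnot(inherits(spec, "clinical_bn_spec"))
  disc <- discretize_clinical(cohort)
  missing_vars <- setdiff(spec$variables, names(disc))
  if (length(missing_vars)) {
    stop("unknown clinical variable(s): ", paste(missing_vars, collapse = ", "))
  }
  clin <- disc[, spec$variables, drop = FALSE]
  single <- vapply(clin, function(x) length(unique(x[!is.na(x)])) < 2, TRUE)
  if (any(single)) {
    warning("dropping single-state clinical variable(s): ",
            paste(names(clin)[single], collapse = ", "))
    clin <- clin[, !single, drop = FALSE]
  }
  aug <- cbind(cohort[, zone_names()], clin)
  dag <- hill_climb(aug, restarts = restarts, seed = stage_seed(seed, "hc"),
                    max_indegree = max_indegree, blacklist = blacklist)
  cpts <- fit_cpts(dag, aug, alpha = alpha)
  edges <- bootstrap_edge_strength(aug, B = B, seed = stage_seed(seed, "boot"),
                                   restarts = restarts,
                                   max_indegree = max_indegree,
                                   blacklist = blacklist)
  list(dag = dag, cpts = cpts, edges = edges, data = aug)
}

#' Conditional probability report
#'
#' Evaluates a list of posterior queries against a fitted network; rows
#' with inconsistent evidence (zero probability under the model) are
#' flagged rather than fatal.
#'
#' @param dag A `bn_dag`.
#' @param cpts Matching `bn_cpts`.
#' @param queries List of queries, each `list(target = c(var = state),
#'   evidence = c(var = state, ...))`.
#' @return Data.frame: `target`, `state`, `evidence`, `probability`,
#'   `flag` (`"ok"` or `"inconsistent_evidence"`).
#' @export
conditional_probability_report <- function(dag, cpts, queries) {
  rows <- lapply(queries, function(qr) {
    ev <- qr$evidence
    ev_str <- if (length(ev)) {
      paste(names(ev), unlist(ev), sep = "=", collapse = ", ")
    } else ""
    pr <- tryCatch(posterior_query(dag, cpts, qr$target, ev),
                   error = function(e) NA_real_)
    data.frame(target = names(qr$target),
               state = as.character(qr$target[[1]]),
               evidence = ev_str,
               probability = pr,
               flag = if (is.na(pr)) "inconsistent_evidence" else "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
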