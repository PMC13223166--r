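# Bootstrap edge-confidence estimation and pairwise co-occurrence
# probabilities -- the two evidence streams combined by the pathway rule.

#' Bootstrap edge strength of a learned network
#'
#' Resamples the rows of `data` with replacement `B` times, relearns the
#' structure with [hill_climb()] on each resample, and records for every
#' ordered pair the fraction of iterations in which the directed edge
#' appeared, and for every unordered pair the fraction in which the pair
#' was connected in either orientation.  The undirected frequency is
#' therefore always at least the larger directed frequency.  Deterministic
#' given `seed`.
#'
#' @param data Data.frame or 0/1 matrix of discrete observations (rows are
#'   patients).
#' @param B Number of bootstrap iterations (>= 1).
#' @param seed Integer seed.
#' @param restarts,max_indegree,blacklist Passed to [hill_climb()].
#' @return Object of class `edge_strength`: list with `B`, `seed`, `nodes`,
#'   `directed_freq` (matrix parent x child) and `undirected_freq`
#'   (symmetric matrix).
#' @export
bootstrap_edge_strength <- function(data, B = 200L, seed = 1L,
                                    restarts = 0L, max_indegree = Inf,
                                    blacklist = NULL) {
  stopifnot(B >= 1)
  xm <- as_discrete_matrix(data)
  if (nrow(xm) < 2L) stop("need at least 2 observations")
  nodes <- colnames(xm)
  p <- length(nodes)
  dir_cnt <- matrix(0, p, p, dimnames = list(nodes, nodes))
  und_cnt <- matrix(0, p, p, dimnames = list(nodes, nodes))
  df <- as.data.frame(data)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(df), replace = TRUE)
      g <- hill_climb(df[idx, , drop = FALSE], restarts = restarts,
                      seed = if (restarts > 0) sample.int(2^31 - 1, 1) else NULL,
                      max_indegree = max_indegree, blacklist = blacklist)
      e <- dag_edges(g)
      if (nrow(e)) {
        ij <- cbind(match(e[, 1], nodes), match(e[, 2], nodes))
        dir_cnt[ij] <- dir_cnt[ij] + 1
        und_cnt[ij] <- und_cnt[ij] + 1
        und_cnt[ij[, 2:1, drop = FALSE]] <- und_cnt[ij[, 2:1, drop = FALSE]] + 1
      }
    }
  })
  structure(list(B = as.integer(B), seed = as.integer(seed), nodes = nodes,
                 directed_freq = dir_cnt / B,
                 undirected_freq = und_cnt / B),
            class = "edge_strength")
}

#' Edge-strength summary as a data.frame
#'
#' @param x An `edge_strength` object.
#' @param min_freq Report ordered pairs with directed frequency above this
#'   value (default 0: all pairs that ever appeared).
#' @return Data.frame: `parent`, `child`, `directed_freq`,
#'   `undirected_freq`, sorted by decreasing directed frequency.
#' @export
edge_strength_table <- function(x, min_freq = 0) {
  stopifnot(inherits(x, "edge_strength"))
  idx <- which(x$directed_freq > min_freq, arr.ind = TRUE)
  out <- data.frame(
    parent = x$nodes[idx[, 1]],
    child = x$nodes[idx[, 2]],
    directed_freq = x$directed_freq[idx],
    undirected_freq = x$undirected_freq[idx]
  )
  out[order(-out$directed_freq, out$parent, out$child), , drop = FALSE]
}

#' Pairwise co-occurrence matrix of zone involvement
#'
#' Entry (a, b) is the fraction of patients with metastasis in both zones;
#' the diagonal holds marginal involvement frequencies.  The denominator is
#' either the LN-positive subset (default, matching a mapping cohort that
#' is conditioned on having any metastasis) or the whole cohort.
#'
#' @param cohort Cohort data.frame with `zone_01..zone_14`.
#' @param denominator_mode `"lnm_patients"` (default) or `"all_patients"`.
#' @return Object of class `cooccurrence`: list with `matrix` (14 x 14,
#'   symmetric, zone-named) and `denominator` (patient count used).
#' @export
cooccurrence_matrix <- function(cohort,
                                denominator_mode = c("lnm_patients",
                                                     "all_patients")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(nrow(cohort) >= 1)
  inv <- as.matrix(cohort[, zone_names()])
  if (denominator_mode == "lnm_patients") {
    inv <- inv[rowSums(inv) > 0, , drop = FALSE]
  }
  denom <- nrow(inv)
  if (denom == 0) stop("empty denominator set for co-occurrence")
  m <- crossprod(inv) / denom
  dimnames(m) <- list(zone_names(), zone_names())
  structure(list(matrix = m, denominator = denom,
                 denominator_mode = denominator_mode),
            class = "cooccurrence")
}

#' Top-quantile co-occurring zone pairs
#'
#' Ranks all `C(14, 2) = 91` unordered off-diagonal pairs by co-occurrence
#' probability and returns the top `ceiling(q * 91)`; ties at the cut value
#' are all included.
#'
#' @param cooc A [cooccurrence_matrix()] result (or a plain symmetric
#'   matrix).
#' @param q Quantile fraction in (0, 1]; default 0.3 (the "top 30%" rule).
#' @return Data.frame: `zone_a`, `zone_b` (a < b), `value`, sorted by
#'   decreasing value then pair order.
#' @export
top_quantile_pairs <- function(cooc, q = 0.3) {
  stopifnot(q > 0, q <= 1)
  m <- if (inherits(cooc, "cooccurrence")) cooc$matrix else as.matrix(cooc)
  p <- nrow(m)
  pairs <- t(utils::combn(p, 2))
  vals <- m[pairs]
  ord <- order(-vals, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  vals <- vals[ord]
  k <- ceiling(q * nrow(pairs))
  cut_val <- vals[k]
  keep <- vals >= cut_val  # include ties at the cut
  data.frame(zone_a = pairs[keep, 1], zone_b = pairs[keep, 2],
             value = vals[keep])
}
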