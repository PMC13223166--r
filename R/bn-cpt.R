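# Conditional probability tables: constructors, maximum-likelihood fitting
# with optional Laplace smoothing, and forward sampling.

#' Construct a conditional probability table
#'
#' A CPT stores, for one node, the distribution over its states for every
#' configuration of its parents.  Parent configurations are enumerated in
#' mixed-radix order with the FIRST parent varying fastest.
#'
#' @param node Variable name.
#' @param parents Character vector of parent names (may be empty).
#' @param levels Named list of state labels: one entry for `node` and one
#'   per parent.
#' @param prob Numeric matrix, `prod(parent state counts)` rows by
#'   `length(levels[[node]])` columns; each row sums to 1.
#' @return Object of class `bn_cpt`.
#' @examples
#' cpt("B", "A", list(B = c("0", "1"), A = c("0", "1")),
#'     rbind(c(0.95, 0.05), c(0.1, 0.9)))
#' @export
cpt <- function(node, parents, levels, prob) {
  prob <- as.matrix(prob)
  dimnames(prob) <- NULL
  q <- prod(vapply(levels[parents], length, 1L))
  if (nrow(prob) != q || ncol(prob) != length(levels[[node]])) {
    stop("CPT for '", node, "': prob must be ", q, " x ",
         length(levels[[node]]))
  }
  if (any(prob < -1e-12) || any(abs(rowSums(prob) - 1) > 1e-9)) {
    stop("CPT for '", node, "': rows must be probability vectors summing to 1")
  }
  structure(list(node = node, parents = parents,
                 levels = levels[c(parents, node)], prob = prob),
            class = "bn_cpt")
}

#' Shorthand for a binary-node CPT
#'
#' @param node Variable name.
#' @param parents Character vector of (binary) parent names.
#' @param p1 Vector of `P(node = 1 | parent configuration)`, one entry per
#'   configuration, first parent varying fastest; for a root node a single
#'   probability.
#' @return `bn_cpt` with levels `"0"`/`"1"` throughout.
#' @export
binary_cpt <- function(node, parents = character(0), p1) {
  levels <- stats::setNames(rep(list(c("0", "1")), length(parents) + 1L),
                            c(parents, node))
  cpt(node, parents, levels, cbind(1 - p1, p1))
}

#' Fit conditional probability tables by (smoothed) maximum likelihood
#'
#' Each CPT entry is `(count + alpha) / (configuration total + alpha * k)`
#' where `k` is the node's state count.  `alpha = 0` is pure maximum
#' likelihood; parent configurations never observed then yield a uniform
#' vector and are flagged via a message and the `unseen_configs` attribute.
#'
#' @param dag A `bn_dag`.
#' @param data Data.frame or 0/1 matrix with columns covering `dag$nodes`.
#' @param alpha Pseudo-count (default 0).
#' @return Object of class `bn_cpts`: named list of `bn_cpt`, one per node,
#'   with attribute `alpha`.
#' @examples
#' d <- data.frame(A = c(1, 1, 1, 1, 0), B = c(1, 1, 1, 0, 0))
#' fit_cpts(dag_new(c("A", "B"), rbind(c("A", "B"))), d)
#' @export
fit_cpts <- function(dag, data, alpha = 0) {
  stopifnot(inherits(dag, "bn_dag"), alpha >= 0)
  xm <- as_discrete_matrix(data)
  if (!all(dag$nodes %in% colnames(xm))) {
    stop("data columns do not cover all network nodes")
  }
  nlev <- attr(xm, "nlev")
  levs <- attr(xm, "levels")
  unseen <- character(0)
  out <- lapply(dag$nodes, function(v) {
    pa <- dag$parents[[v]]
    j <- match(v, colnames(xm))
    pj <- match(pa, colnames(xm))
    kj <- nlev[[j]]
    q <- if (length(pj)) prod(nlev[pj]) else 1L
    cfg <- rep(1L, nrow(xm))
    mult <- 1L
    for (pp in pj) {
      cfg <- cfg + (xm[, pp] - 1L) * mult
      mult <- mult * nlev[[pp]]
    }
    cnt <- matrix(tabulate(cfg + (xm[, j] - 1L) * q, nbins = q * kj),
                  nrow = q)
    tot <- rowSums(cnt)
    prob <- (cnt + alpha) / (tot + alpha * kj)
    if (any(tot == 0) && alpha == 0) {
      prob[tot == 0, ] <- 1 / kj
      unseen <<- c(unseen, v)
    }
    cpt(v, pa, levs[c(pa, v)], prob)
  })
  names(out) <- dag$nodes
  if (length(unseen)) {
    message("unseen parent configurations set to uniform for: ",
            paste(unseen, collapse = ", "))
  }
  structure(out, class = "bn_cpts", alpha = alpha,
            unseen_configs = unseen)
}

#' Ancestral (forward) sampling from a fitted or specified network
#'
#' Nodes are sampled in the deterministic topological order of
#' [dag_topo_sort()]; given a seed the sample is fully reproducible.
#'
#' @param dag A `bn_dag`.
#' @param cpts Matching `bn_cpts` (or plain named list of `bn_cpt`).
#' @param n Number of records.
#' @param seed Optional integer seed.
#' @return Data.frame of sampled states; binary `"0"`/`"1"` variables are
#'   returned as integer 0/1, others as factors.
#' @export
sample_bn <- function(dag, cpts, n, seed = NULL) {
  stopifnot(inherits(dag, "bn_dag"), n >= 1)
  ord <- dag_topo_sort(dag)
  with_seed(seed, {
    cols <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
    code <- matrix(0L, n, length(dag$nodes),
                   dimnames = list(NULL, dag$nodes))
    for (v in ord) {
      ct <- cpts[[v]]
      pa <- ct$parents
      q <- nrow(ct$prob)
      cfg <- rep(1L, n)
      mult <- 1L
      for (pp in pa) {
        cfg <- cfg + (code[, pp] - 1L) * mult
        mult <- mult * length(ct$levels[[pp]])
      }
      u <- stats::runif(n)
      cum <- ct$prob %*% upper.tri(diag(ncol(ct$prob)), diag = TRUE)
      # state = 1 + number of cumulative bounds strictly below u
      st <- rep(1L, n)
      for (s in seq_len(ncol(ct$prob) - 1L)) {
        st <- st + as.integer(u > cum[cfg, s])
      }
      code[, v] <- st
      labs <- ct$levels[[v]]
      cols[[v]] <- if (identical(labs, c("0", "1"))) {
        st - 1L
      } else {
        factor(labs[st], levels = labs)
      }
    }
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat("CPT for", x$node,
      if (length(x$parents)) paste("| parents:", paste(x$parents, collapse = ", "))
      else "(root)", "\n")
  print(x$prob)
  invisible(x)
}
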