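# BIC scoring and hill-climbing structure search for discrete networks.
#
# The score is the standard structure-learning BIC (higher is better):
#   score(G) = sum_j [ max log-likelihood of X_j given Pa(X_j) ]
#              - (log n)/2 * sum_j (k_j - 1) * prod_{p in Pa(j)} k_p
# It decomposes over nodes, so local terms are cached by (node, parent set).

# local BIC term for column j with parent columns pa (integer indices)
.local_bic <- function(xm, nlev, j, pa, logn) {
  n <- nrow(xm)
  kj <- nlev[[j]]
  if (length(pa) == 0L) {
    cnt <- tabulate(xm[, j], nbins = kj)
    ll <- xlogx_sum(cnt) - n * log(n)
    return(ll - logn / 2 * (kj - 1))
  }
  q <- prod(nlev[pa])
  cfg <- rep(1L, n)
  mult <- 1L
  for (pp in pa) {
    cfg <- cfg + (xm[, pp] - 1L) * mult
    mult <- mult * nlev[[pp]]
  }
  cnt <- tabulate(cfg + (xm[, j] - 1L) * q, nbins = q * kj)
  tot <- tabulate(cfg, nbins = q)
  ll <- xlogx_sum(cnt) - xlogx_sum(tot)
  ll - logn / 2 * q * (kj - 1)
}

# memoising wrapper around .local_bic; cache is an environment
.local_bic_cached <- function(cache, xm, nlev, j, pa, logn) {
  key <- paste0(j, "|", paste(pa, collapse = ","))
  v <- cache[[key]]
  if (is.null(v)) {
    v <- .local_bic(xm, nlev, j, pa, logn)
    cache[[key]] <- v
  }
  v
}

#' BIC score of a network structure on discrete data
#'
#' Penalized maximized log-likelihood, higher is better, with penalty
#' `(log n)/2` per free parameter; a node with `k` states and parent
#' configuration count `q` contributes `q * (k - 1)` parameters.  Zero
#' counts contribute zero to the likelihood (`0 * log 0 = 0`).
#'
#' @param dag A [dag_new()] structure whose nodes name columns of `data`.
#' @param data A data.frame or 0/1 matrix of discrete observations.
#' @return Numeric scalar score.
#' @examples
#' d <- data.frame(A = rep(0:1, each = 5))
#' bic_score(dag_new("A"), d)  # 10*log(0.5) - log(10)/2
#' @export
bic_score <- function(dag, data) {
  stopifnot(inherits(dag, "bn_dag"))
  xm <- as_discrete_matrix(data)
  if (!all(dag$nodes %in% colnames(xm))) {
    stop("data columns do not cover all network nodes: missing ",
         paste(setdiff(dag$nodes, colnames(xm)), collapse = ", "))
  }
  nlev <- attr(xm, "nlev")
  logn <- log(nrow(xm))
  sum(vapply(dag$nodes, function(v) {
    .local_bic(xm, nlev, match(v, colnames(xm)),
               match(dag$parents[[v]], colnames(xm)), logn)
  }, numeric(1)))
}

#' Hill-climbing structure search with BIC scoring
#'
#' Greedy steepest-ascent search over DAGs using the operators add, delete
#' and reverse edge, keeping the graph acyclic, applying the single best
#' score-improving operator per step until none improves.  Tie-breaking is
#' deterministic: operator type order add < delete < reverse, then
#' lexicographic by (parent, child) node name; score improvements are
#' compared with a `1e-9` tolerance so floating-point-equal alternatives
#' resolve by that order.  With `restarts > 0` the search is repeated from
#' randomly perturbed copies of the incumbent best graph and the
#' highest-scoring result is returned; given `seed` the whole procedure is
#' deterministic.
#'
#' @param data Data.frame or 0/1 matrix of discrete observations
#'   (n >= 2 rows, >= 2 columns).
#' @param restarts Number of random restarts (default 0).
#' @param seed Optional integer seed for the restart perturbations.
#' @param max_indegree Maximum number of parents per node (default
#'   unlimited); operators that would exceed it are skipped.
#' @param blacklist Optional two-column matrix of forbidden (parent, child)
#'   edges.
#' @return A `bn_dag` with attribute `score` (its BIC score).
#' @examples
#' set.seed(1)
#' a <- rbinom(200, 1, 0.5)
#' b <- ifelse(a == 1, rbinom(200, 1, 0.9), rbinom(200, 1, 0.1))
#' hill_climb(data.frame(A = a, B = b))
#' @export
hill_climb <- function(data, restarts = 0L, seed = NULL,
                       max_indegree = Inf, blacklist = NULL) {
  xm <- as_discrete_matrix(data)
  n <- nrow(xm)
  p <- ncol(xm)
  if (n < 2L) stop("need at least 2 observations")
  if (p < 2L) stop("need at least 2 variables")
  nodes <- colnames(xm)
  nlev <- attr(xm, "nlev")
  logn <- log(n)
  ord <- order(nodes)  # lexicographic candidate order
  bl <- matrix(FALSE, p, p)
  if (!is.null(blacklist)) {
    blacklist <- as.matrix(blacklist)
    bl[cbind(match(blacklist[, 1], nodes), match(blacklist[, 2], nodes))] <- TRUE
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  ls_of <- function(j, pa) .local_bic_cached(cache, xm, nlev, j, sort(pa), logn)

  climb <- function(pl) {
    # pl: list of sorted integer parent vectors
    cur <- vapply(seq_len(p), function(j) ls_of(j, pl[[j]]), numeric(1))
    repeat {
      adj <- matrix(FALSE, p, p)
      for (v in seq_len(p)) adj[pl[[v]], v] <- TRUE
      reach <- .transitive_closure(adj)
      best_delta <- 0
      best_op <- NULL
      eps <- 1e-9
      # additions, lexicographic (parent, child)
      for (u in ord) for (v in ord) {
        if (u == v || adj[u, v] || bl[u, v] || reach[v, u]) next
        if (length(pl[[v]]) + 1L > max_indegree) next
        d <- ls_of(v, c(pl[[v]], u)) - cur[v]
        if (d > best_delta + eps) {
          best_delta <- d
          best_op <- list("add", u, v)
        }
      }
      # deletions
      for (u in ord) for (v in ord) {
        if (!adj[u, v]) next
        d <- ls_of(v, setdiff(pl[[v]], u)) - cur[v]
        if (d > best_delta + eps) {
          best_delta <- d
          best_op <- list("del", u, v)
        }
      }
      # reversals: u -> v becomes v -> u
      for (u in ord) for (v in ord) {
        if (!adj[u, v] || bl[v, u]) next
        if (length(pl[[u]]) + 1L > max_indegree) next
        # after removing u -> v, adding v -> u closes a cycle iff a
        # directed path u ~> v survives through other edges
        adj2 <- adj
        adj2[u, v] <- FALSE
        if (.transitive_closure(adj2)[u, v]) next
        d <- (ls_of(v, setdiff(pl[[v]], u)) - cur[v]) +
             (ls_of(u, c(pl[[u]], v)) - cur[u])
        if (d > best_delta + eps) {
          best_delta <- d
          best_op <- list("rev", u, v)
        }
      }
      if (is.null(best_op)) break
      u <- best_op[[2]]
      v <- best_op[[3]]
      if (best_op[[1]] == "add") {
        pl[[v]] <- sort(c(pl[[v]], u))
      } else if (best_op[[1]] == "del") {
        pl[[v]] <- setdiff(pl[[v]], u)
      } else {
        pl[[v]] <- setdiff(pl[[v]], u)
        pl[[u]] <- sort(c(pl[[u]], v))
      }
      cur <- vapply(seq_len(p), function(j) ls_of(j, pl[[j]]), numeric(1))
    }
    list(pl = pl, score = sum(cur))
  }

  perturb <- function(pl, n_ops = 4L) {
    for (i in seq_len(n_ops)) {
      adj <- matrix(FALSE, p, p)
      for (v in seq_len(p)) adj[pl[[v]], v] <- TRUE
      reach <- .transitive_closure(adj)
      cand_add <- which(!adj & !bl & !t(reach) & !diag(p), arr.ind = TRUE)
      cand_add <- cand_add[colSums(adj)[cand_add[, 2]] < max_indegree, ,
                           drop = FALSE]
      cand_del <- which(adj, arr.ind = TRUE)
      moves <- rbind(
        if (nrow(cand_add)) cbind(cand_add, op = rep(1L, nrow(cand_add))),
        if (nrow(cand_del)) cbind(cand_del, op = rep(2L, nrow(cand_del))))
      if (is.null(moves) || !nrow(moves)) break
      mv <- moves[sample.int(nrow(moves), 1L), ]
      if (mv[["op"]] == 1L) {
        pl[[mv[[2]]]] <- sort(c(pl[[mv[[2]]]], mv[[1]]))
      } else {
        pl[[mv[[2]]]] <- setdiff(pl[[mv[[2]]]], mv[[1]])
      }
    }
    pl
  }

  empty <- rep(list(integer(0)), p)
  best <- climb(empty)
  if (restarts > 0L) {
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        res <- climb(perturb(best$pl))
        if (res$score > best$score + 1e-9) best <- res
      }
    })
  }
  edges <- do.call(rbind, lapply(seq_len(p), function(v) {
    if (length(best$pl[[v]])) cbind(nodes[best$pl[[v]]], nodes[v]) else NULL
  }))
  out <- dag_new(nodes, edges)
  attr(out, "score") <- best$score
  out
}

#' Skeleton F1 of a learned structure against a reference
#'
#' Precision and recall of the learned undirected edge set (the skeleton)
#' against the reference skeleton, combined as their harmonic mean.
#'
#' @param learned,truth `bn_dag` objects over the same nodes.
#' @return List: `f1`, `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
skeleton_f1 <- function(learned, truth) {
  und <- function(dag) {
    e <- dag_edges(dag)
    if (!nrow(e)) return(character(0))
    unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  le <- und(learned)
  te <- und(truth)
  tp <- length(intersect(le, te))
  fp <- length(setdiff(le, te))
  fn <- length(setdiff(te, le))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(f1 = f1, precision = precision, recall = recall,
       tp = tp, fp = fp, fn = fn)
}
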