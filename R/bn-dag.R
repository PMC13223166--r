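#' Directed acyclic graph over named discrete variables
#'
#' Minimal DAG container used throughout the network engine.  Nodes are
#' variable names; edges are ordered (parent, child) pairs.  Acyclicity is
#' enforced on construction and after every mutation.
#'
#' @param nodes Character vector of variable names (unique, non-empty).
#' @param edges Optional two-column matrix or data.frame of (parent, child)
#'   name pairs.
#' @return An object of class `bn_dag`: list with `nodes` and `parents`
#'   (named list mapping each node to its sorted parent names).
#' @examples
#' g <- dag_new(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' dag_edges(g)
#' @export
dag_new <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  g <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    for (i in seq_len(nrow(edges))) {
      g <- dag_add_edge(g, edges[i, 1], edges[i, 2])
    }
  }
  g
}

#' @rdname dag_new
#' @param dag A `bn_dag`.
#' @return `dag_edges` returns a two-column character matrix (parent, child),
#'   ordered lexicographically.
#' @export
dag_edges <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  out <- do.call(rbind, lapply(dag$nodes, function(v) {
    pa <- dag$parents[[v]]
    if (length(pa)) cbind(parent = pa, child = rep(v, length(pa))) else NULL
  }))
  if (is.null(out)) {
    out <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  }
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname dag_new
#' @param parent,child Node names.
#' @export
dag_add_edge <- function(dag, parent, child) {
  stopifnot(inherits(dag, "bn_dag"))
  parent <- unname(as.character(parent))
  child <- unname(as.character(child))
  if (!parent %in% dag$nodes || !child %in% dag$nodes) {
    stop("unknown node in edge ", parent, " -> ", child)
  }
  if (parent == child) stop("self-loop ", parent, " -> ", child)
  if (parent %in% dag$parents[[child]]) {
    stop("duplicate edge ", parent, " -> ", child)
  }
  if (dag_has_path(dag, child, parent)) {
    stop("edge ", parent, " -> ", child, " would create a cycle")
  }
  dag$parents[[child]] <- sort(c(dag$parents[[child]], parent))
  dag
}

#' @rdname dag_new
#' @export
dag_remove_edge <- function(dag, parent, child) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!parent %in% dag$parents[[child]]) {
    stop("no edge ", parent, " -> ", child)
  }
  dag$parents[[child]] <- setdiff(dag$parents[[child]], parent)
  dag
}

#' @rdname dag_new
#' @param from,to Node names.
#' @return `dag_has_path` returns TRUE if a directed path (length >= 1)
#'   exists from `from` to `to`.
#' @export
dag_has_path <- function(dag, from, to) {
  children <- dag_children_map(dag)
  seen <- character(0)
  stack <- children[[from]]
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v == to) return(TRUE)
    if (!v %in% seen) {
      seen <- c(seen, v)
      stack <- c(stack, children[[v]])
    }
  }
  FALSE
}

# named list node -> children
dag_children_map <- function(dag) {
  ch <- stats::setNames(rep(list(character(0)), length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) {
    for (p in dag$parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; among simultaneously available nodes the one earliest
#' in lexicographic name order is emitted first, so the order is a
#' deterministic function of the graph.  Zone variable names are
#' zero-padded, so for zone networks this tie-break equals "smallest zone
#' id first".
#'
#' @param dag A `bn_dag`.
#' @return Character vector of node names in topological order.
#' @export
dag_topo_sort <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)
  remaining <- sort(dag$nodes)
  children <- dag_children_map(dag)
  out <- character(0)
  while (length(remaining)) {
    avail <- remaining[indeg[remaining] == 0L]
    if (!length(avail)) stop("graph contains a directed cycle")
    v <- avail[[1]]
    remaining <- setdiff(remaining, v)
    out <- c(out, v)
    for (w in children[[v]]) indeg[[w]] <- indeg[[w]] - 1L
  }
  out
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("bn_dag:", length(x$nodes), "nodes,", nrow(e), "edges\n")
  if (nrow(e)) {
    cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Exhaustively enumerate all DAGs on a small node set
#'
#' Test oracle for the structure search: every labelled DAG on up to four
#' nodes, generated by assigning each unordered node pair one of three
#' states (no edge, forward, backward) and discarding cyclic results.  The
#' counts are the labelled-DAG sequence 1, 3, 25, 543 for 1-4 nodes.
#'
#' @param nodes Either a node count (1-4) or a character vector of at most
#'   four node names.
#' @return List of `bn_dag` objects, duplicate-free.
#' @examples
#' length(enumerate_dags(3))  # 25
#' @export
enumerate_dags <- function(nodes = 3) {
  if (is.numeric(nodes) && length(nodes) == 1L) {
    nodes <- LETTERS[seq_len(nodes)]
  }
  k <- length(nodes)
  if (k < 1L || k > 4L) {
    stop("enumerate_dags is an exhaustive oracle and refuses node counts > 4")
  }
  if (k == 1L) return(list(dag_new(nodes)))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- vector("list", 3^m)
  n_found <- 0L
  for (code in 0:(3^m - 1)) {
    digits <- (code %/% 3^(seq_len(m) - 1)) %% 3
    adj <- matrix(FALSE, k, k)
    for (e in seq_len(m)) {
      if (digits[e] == 1) adj[pairs[1, e], pairs[2, e]] <- TRUE
      if (digits[e] == 2) adj[pairs[2, e], pairs[1, e]] <- TRUE
    }
    if (.adj_is_acyclic(adj)) {
      idx <- which(adj, arr.ind = TRUE)
      edges <- if (nrow(idx)) {
        cbind(nodes[idx[, 1]], nodes[idx[, 2]])
      } else {
        NULL
      }
      n_found <- n_found + 1L
      out[[n_found]] <- dag_new(nodes, edges)
    }
  }
  out[seq_len(n_found)]
}

# Kahn acyclicity test on a logical adjacency matrix adj[parent, child]
.adj_is_acyclic <- function(adj) {
  k <- nrow(adj)
  indeg <- colSums(adj)
  alive <- rep(TRUE, k)
  for (step in seq_len(k)) {
    v <- which(alive & indeg == 0)
    if (!length(v)) return(FALSE)
    v <- v[[1]]
    alive[v] <- FALSE
    indeg <- indeg - adj[v, ]
  }
  TRUE
}

# reach[i, j] TRUE if directed path i -> ... -> j (length >= 1); Warshall
.transitive_closure <- function(adj) {
  reach <- adj
  k <- nrow(adj)
  for (mid in seq_len(k)) {
    reach <- reach | (reach[, mid] %o% reach[mid, ])
  }
  reach
}
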