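# Exact inference by variable elimination over discrete factors.
#
# A factor is a list(vars, dims, p) where p is the table in mixed-radix
# vector order with the FIRST variable in vars varying fastest -- the same
# convention as CPT rows, so a CPT over (parents..., node) converts to a
# factor by concatenating its probability matrix column-wise.

.factor_from_cpt <- function(ct) {
  vars <- c(ct$parents, ct$node)
  dims <- vapply(ct$levels[vars], length, 1L)
  list(vars = vars, dims = dims, p = as.vector(ct$prob))
}

.strides <- function(dims) {
  if (!length(dims)) return(integer(0))
  cumprod(c(1L, dims[-length(dims)]))
}

.factor_reduce <- function(f, var, state) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  keep <- arrayInd(seq_along(f$p), f$dims)[, k] == state
  list(vars = f$vars[-k], dims = f$dims[-k], p = f$p[keep])
}

.factor_product <- function(f1, f2) {
  if (!length(f1$vars)) {
    return(list(vars = f2$vars, dims = f2$dims, p = f2$p * f1$p))
  }
  if (!length(f2$vars)) {
    return(list(vars = f1$vars, dims = f1$dims, p = f1$p * f2$p))
  }
  vars <- union(f1$vars, f2$vars)
  dims <- f1$dims[match(vars, f1$vars)]
  miss <- is.na(dims)
  dims[miss] <- f2$dims[match(vars[miss], f2$vars)]
  idx <- arrayInd(seq_len(prod(dims)), dims)
  i1 <- 1 + (idx[, match(f1$vars, vars), drop = FALSE] - 1) %*% .strides(f1$dims)
  i2 <- 1 + (idx[, match(f2$vars, vars), drop = FALSE] - 1) %*% .strides(f2$dims)
  list(vars = vars, dims = dims, p = f1$p[i1] * f2$p[i2])
}

.factor_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  if (length(f$vars) == 1L) {
    return(list(vars = character(0), dims = integer(0), p = sum(f$p)))
  }
  a <- array(f$p, dim = f$dims)
  s <- apply(a, setdiff(seq_along(f$dims), k), sum)
  list(vars = f$vars[-k], dims = f$dims[-k], p = as.vector(s))
}

# greedy min-degree elimination order over the factor interaction graph
.elim_order <- function(factors, elim) {
  order_out <- character(0)
  scopes <- lapply(factors, `[[`, "vars")
  while (length(elim)) {
    deg <- vapply(elim, function(v) {
      nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
      length(setdiff(nb, v))
    }, 1L)
    v <- elim[order(deg, elim)][1L]
    joined <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
    scopes <- c(scopes[!vapply(scopes, function(s) v %in% s, TRUE)],
                list(setdiff(joined, v)))
    order_out <- c(order_out, v)
    elim <- setdiff(elim, v)
  }
  order_out
}

#' Exact posterior probability in a discrete network
#'
#' Computes `P(target = state | evidence)` by variable elimination with a
#' greedy min-degree ordering.  Exact up to floating point; evidence with
#' zero probability under the model raises an error.
#'
#' @param dag The `bn_dag` (used for validation; the tables in `cpts` carry
#'   the distribution).
#' @param cpts `bn_cpts` for `dag`.
#' @param target Length-1 named vector or list, `c(variable = state)`.
#' @param evidence Named vector of observed states (possibly empty).
#'   States may be given as level labels (`"1"`, `"G3"`) or numeric 0/1 for
#'   binary variables.
#' @return Probability in `[0, 1]`.
#' @examples
#' g <- dag_new(c("A", "B"), rbind(c("A", "B")))
#' tabs <- list(A = binary_cpt("A", p1 = 0.5),
#'              B = binary_cpt("B", "A", c(0.1, 0.9)))
#' posterior_query(g, tabs, c(B = "1"), c(A = "1"))  # 0.9
#' @export
posterior_query <- function(dag, cpts, target, evidence = NULL) {
  stopifnot(inherits(dag, "bn_dag"), length(target) == 1L)
  tvar <- names(target)
  if (is.null(tvar) || !tvar %in% dag$nodes) {
    stop("target must be a named state for a known variable")
  }
  evars <- names(evidence)
  if (tvar %in% evars) stop("target may not appear in the evidence")
  if (length(evars) && !all(evars %in% dag$nodes)) {
    stop("unknown evidence variable: ",
         paste(setdiff(evars, dag$nodes), collapse = ", "))
  }
  state_index <- function(v, s) {
    labs <- cpts[[v]]$levels[[v]]
    i <- match(as.character(s), labs)
    if (is.na(i)) stop("unknown state '", s, "' for variable ", v)
    i
  }
  factors <- lapply(dag$nodes, function(v) .factor_from_cpt(cpts[[v]]))
  for (v in evars) {
    si <- state_index(v, evidence[[v]])
    factors <- lapply(factors, .factor_reduce, var = v, state = si)
  }
  elim <- setdiff(dag$nodes, c(tvar, evars))
  for (v in .elim_order(factors, elim)) {
    has_v <- vapply(factors, function(f) v %in% f$vars, TRUE)
    psi <- Reduce(.factor_product, factors[has_v])
    factors <- c(factors[!has_v], list(.factor_marginalize(psi, v)))
  }
  res <- Reduce(.factor_product, factors)
  z <- sum(res$p)
  if (z <= 0) stop("inconsistent evidence: P(evidence) = 0")
  ti <- state_index(tvar, target[[1]])
  res$p[ti] / z
}

#' Full joint distribution by brute-force enumeration
#'
#' Independent oracle for [posterior_query()]: enumerates every joint state
#' with `expand.grid` and multiplies CPT entries looked up row by row,
#' without using the factor algebra of the variable-elimination path.
#' Tractable up to the 14-zone network (2^14 states).
#'
#' @param dag A `bn_dag`.
#' @param cpts Matching `bn_cpts`.
#' @return Data.frame with one column per node (state labels) plus `prob`.
#' @export
joint_table <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  if (length(dag$nodes) > 14L) {
    stop("joint enumeration limited to 14 nodes")
  }
  labs <- lapply(dag$nodes, function(v) cpts[[v]]$levels[[v]])
  names(labs) <- dag$nodes
  grid <- expand.grid(labs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(grid))
  for (v in dag$nodes) {
    ct <- cpts[[v]]
    row <- rep(1L, nrow(grid))
    mult <- 1L
    for (pp in ct$parents) {
      row <- row + (match(grid[[pp]], ct$levels[[pp]]) - 1L) * mult
      mult <- mult * length(ct$levels[[pp]])
    }
    col <- match(grid[[v]], ct$levels[[v]])
    prob <- prob * ct$prob[cbind(row, col)]
  }
  grid$prob <- prob
  grid
}
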