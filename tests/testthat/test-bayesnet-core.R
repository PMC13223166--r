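test_that("BIC matches closed-form hand computations", {
  # one binary variable, 10 observations, 5 ones, empty graph:
  # 10*log(0.5) - log(10)/2
  d <- data.frame(A = rep(0:1, each = 5))
  expect_equal(bic_score(dag_new("A"), d), 10 * log(0.5) - log(10) / 2,
               tolerance = 1e-9)
  # two perfectly correlated fair binary variables, n = 100:
  # score(A -> B) - score(empty) = 100*log(2) - log(100)/2
  d2 <- data.frame(A = rep(0:1, each = 50), B = rep(0:1, each = 50))
  gain <- bic_score(dag_new(c("A", "B"), rbind(c("A", "B"))), d2) -
    bic_score(dag_new(c("A", "B")), d2)
  expect_equal(gain, 100 * log(2) - log(100) / 2, tolerance = 1e-9)
})

test_that("an edge from a constant variable never increases the score", {
  set.seed(4)
  d <- data.frame(K = rep(1, 80), B = rbinom(80, 1, 0.5))
  s_empty <- bic_score(dag_new(c("K", "B")), d)
  s_edge <- bic_score(dag_new(c("K", "B"), rbind(c("K", "B"))), d)
  expect_lte(s_edge, s_empty)
})

test_that("DAG enumeration reproduces the labelled-DAG counts", {
  expect_equal(length(enumerate_dags(1)), 1)
  expect_equal(length(enumerate_dags(2)), 3)
  expect_equal(length(enumerate_dags(3)), 25)
  expect_equal(length(enumerate_dags(4)), 543)
  keys <- vapply(enumerate_dags(4), function(g) {
    paste(apply(dag_edges(g), 1, paste, collapse = ">"), collapse = ";")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_error(enumerate_dags(5), "refuses")
})

test_that("DAG mutations are guarded against cycles and duplicates", {
  g <- dag_new(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_error(dag_add_edge(g, "C", "A"), "cycle")
  expect_error(dag_add_edge(g, "A", "B"), "duplicate")
  expect_error(dag_add_edge(g, "A", "A"), "self-loop")
  expect_equal(dag_topo_sort(g), c("A", "B", "C"))
})

test_that("hill climbing attains the exhaustive optimum on a planted chain", {
  set.seed(13)
  n <- 500
  a <- rbinom(n, 1, 0.5)
  b <- ifelse(a == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.05))
  c2 <- ifelse(b == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.05))
  d <- data.frame(A = a, B = b, C = c2)
  g <- hill_climb(d)
  best <- max(vapply(enumerate_dags(c("A", "B", "C")), bic_score,
                     numeric(1), data = d))
  expect_equal(attr(g, "score"), best, tolerance = 1e-9)
  expect_equal(bic_score(g, d), attr(g, "score"), tolerance = 1e-9)
})

test_that("independent fair coins yield the empty graph almost always", {
  set.seed(21)
  empty_count <- sum(vapply(1:50, function(r) {
    d <- as.data.frame(matrix(rbinom(4 * 2000, 1, 0.5), ncol = 4,
                              dimnames = list(NULL, c("A", "B", "C", "D"))))
    nrow(dag_edges(hill_climb(d))) == 0
  }, logical(1)))
  expect_gte(empty_count / 50, 0.95)
})

test_that("the search never scores below the empty graph", {
  set.seed(34)
  for (r in 1:10) {
    d <- as.data.frame(matrix(rbinom(5 * 100, 1, runif(1, 0.2, 0.8)),
                              ncol = 5))
    names(d) <- paste0("V", 1:5)
    g <- hill_climb(d)
    expect_gte(attr(g, "score"), bic_score(dag_new(names(d)), d) - 1e-9)
  }
})

test_that("CPT fitting matches direct ratios with and without smoothing", {
  d <- data.frame(P = c(1, 1, 1, 1, 0, 0), C = c(1, 1, 1, 0, 0, 0))
  g <- dag_new(c("P", "C"), rbind(c("P", "C")))
  mle <- fit_cpts(g, d)
  expect_equal(mle$C$prob[2, 2], 0.75)
  lap <- fit_cpts(g, d, alpha = 1)
  expect_equal(lap$C$prob[2, 2], 4 / 6, tolerance = 1e-12)
  for (ct in mle) expect_equal(rowSums(ct$prob), rep(1, nrow(ct$prob)),
                               tolerance = 1e-9)
})

test_that("unseen parent configurations yield flagged uniform rows", {
  d <- data.frame(P = c(0, 0, 0, 0), C = c(0, 1, 0, 1))
  g <- dag_new(c("P", "C"), rbind(c("P", "C")))
  expect_message(tabs <- fit_cpts(g, d), "unseen")
  expect_equal(tabs$C$prob[2, ], c(0.5, 0.5))
  expect_equal(attr(tabs, "unseen_configs"), "C")
})

test_that("chain queries return CPT entries exactly", {
  g <- dag_new(c("A", "B"), rbind(c("A", "B")))
  tabs <- list(A = binary_cpt("A", p1 = 0.3),
               B = binary_cpt("B", "A", c(0.1, 0.9)))
  expect_equal(posterior_query(g, tabs, c(B = "1"), c(A = "1")), 0.9,
               tolerance = 1e-12)
  expect_equal(posterior_query(g, tabs, c(B = "1"), c(A = "0")), 0.1,
               tolerance = 1e-12)
})

test_that("v-structure posterior matches 8-state enumeration", {
  g <- dag_new(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  tabs <- list(A = binary_cpt("A", p1 = 0.5),
               B = binary_cpt("B", p1 = 0.5),
               C = binary_cpt("C", c("A", "B"), c(0.1, 0.1, 0.1, 0.9)))
  jt <- joint_table(g, tabs)
  oracle <- sum(jt$prob[jt$A == "1" & jt$C == "1"]) /
    sum(jt$prob[jt$C == "1"])
  expect_equal(posterior_query(g, tabs, c(A = "1"), c(C = "1")), oracle,
               tolerance = 1e-9)
  # C = 1 needs both causes here, so learning B = 0 makes A uninformative
  # and drops its posterior back to the prior
  expect_lt(posterior_query(g, tabs, c(A = "1"), c(C = "1", B = "0")),
            posterior_query(g, tabs, c(A = "1"), c(C = "1")))
  expect_equal(posterior_query(g, tabs, c(A = "1"), c(C = "1", B = "0")),
               0.5, tolerance = 1e-9)
})

test_that("posterior queries are normalized and reject impossible evidence", {
  g <- dag_new(c("A", "B"), rbind(c("A", "B")))
  tabs <- list(A = binary_cpt("A", p1 = 0), # A is never 1
               B = binary_cpt("B", "A", c(0.2, 0.8)))
  expect_error(posterior_query(g, tabs, c(B = "1"), c(A = "1")),
               "inconsistent")
  tabs$A <- binary_cpt("A", p1 = 0.4)
  p1 <- posterior_query(g, tabs, c(B = "1"), c(A = "1"))
  p0 <- posterior_query(g, tabs, c(B = "0"), c(A = "1"))
  expect_equal(p1 + p0, 1, tolerance = 1e-12)
  expect_error(posterior_query(g, tabs, c(A = "1"), c(A = "0")),
               "evidence")
})

# random network generator for the inference equivalence suite
random_network <- function(p, seed) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(p))
  ord <- sample(nodes)
  edges <- NULL
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (runif(1) < 0.4) edges <- rbind(edges, c(ord[i], ord[j]))
    }
  }
  g <- dag_new(nodes, edges)
  tabs <- lapply(nodes, function(v) {
    q <- 2^length(g$parents[[v]])
    binary_cpt(v, g$parents[[v]], runif(q, 0.05, 0.95))
  })
  names(tabs) <- nodes
  list(dag = g, cpts = tabs)
}

test_that("variable elimination equals brute-force joint enumeration", {
  worst <- 0
  for (r in 1:50) {
    p <- sample(3:6, 1)
    net <- random_network(p, seed = 1000 + r)
    jt <- joint_table(net$dag, net$cpts)
    tvar <- net$dag$nodes[1]
    evars <- net$dag$nodes[seq(2, min(3, p))]
    ev <- stats::setNames(as.character(rbinom(length(evars), 1, 0.5)), evars)
    sel <- rep(TRUE, nrow(jt))
    for (v in names(ev)) sel <- sel & jt[[v]] == ev[[v]]
    if (sum(jt$prob[sel]) <= 0) next
    oracle <- sum(jt$prob[sel & jt[[tvar]] == "1"]) / sum(jt$prob[sel])
    ve <- posterior_query(net$dag, net$cpts, stats::setNames("1", tvar), ev)
    worst <- max(worst, abs(ve - oracle))
  }
  expect_lt(worst, 1e-9)
})

test_that("BIC decomposes: a one-node mutation changes only that local term", {
  set.seed(77)
  d <- as.data.frame(matrix(rbinom(5 * 200, 1, 0.5), ncol = 5))
  names(d) <- paste0("V", 1:5)
  base <- dag_new(names(d), rbind(c("V1", "V2"), c("V2", "V3")))
  local_only <- function(dag, v) {
    # graph keeping only v's incoming edges; all other nodes parentless
    e <- dag_edges(dag)
    dag_new(dag$nodes, e[e[, "child"] == v, , drop = FALSE])
  }
  for (r in 1:100) {
    v <- sample(names(d), 1)
    new_pa <- sample(setdiff(names(d), v), sample(0:2, 1))
    mut <- tryCatch(
      dag_new(names(d), rbind(
        dag_edges(base)[dag_edges(base)[, "child"] != v, , drop = FALSE],
        if (length(new_pa)) cbind(new_pa, v) else NULL)),
      error = function(e) NULL)  # mutation would close a cycle
    if (is.null(mut)) next
    delta_total <- bic_score(mut, d) - bic_score(base, d)
    delta_local <- bic_score(local_only(mut, v), d) -
      bic_score(local_only(base, v), d)
    expect_equal(delta_total, delta_local, tolerance = 1e-9)
  }
})

test_that("restarted search matches the 543-DAG oracle on random data", {
  set.seed(55)
  for (r in 1:5) {
    net <- random_network(4, seed = 300 + r)
    d <- sample_bn(net$dag, net$cpts, 300, seed = 400 + r)
    names(d) <- c("A", "B", "C", "D")
    g <- hill_climb(d, restarts = 20, seed = r)
    best <- max(vapply(enumerate_dags(4), bic_score, numeric(1), data = d))
    expect_equal(attr(g, "score"), best, tolerance = 1e-9)
  }
})

test_that("planted 14-zone structures are recovered with high skeleton F1", {
  f1s <- vapply(1:3, function(s) {
    cfg <- sim_config(2000, seed = 500 + s)
    cfg <- plant_pathway(cfg, c(3, 5, 1), 0.85, root_p1 = 0.5)
    cfg <- plant_pathway(cfg, c(4, 6, 2), 0.85, root_p1 = 0.5)
    cfg <- plant_pathway(cfg, c(11, 12), 0.85, root_p1 = 0.4)
    cfg <- plant_pathway(cfg, c(7, 13), 0.85, root_p1 = 0.4)
    ch <- generate_cohort(cfg)
    g <- hill_climb(ch[, zone_names()])
    skeleton_f1(g, cfg$truth_dag)$f1
  }, numeric(1))
  expect_gte(median(f1s), 0.8)
})

test_that("forward sampling reproduces configured conditionals", {
  g <- dag_new(c("A", "B"), rbind(c("A", "B")))
  tabs <- list(A = binary_cpt("A", p1 = 0.6),
               B = binary_cpt("B", "A", c(0.2, 0.85)))
  d <- sample_bn(g, tabs, 8000, seed = 12)
  expect_identical(d, sample_bn(g, tabs, 8000, seed = 12))
  expect_lt(abs(mean(d$A) - 0.6), 0.02)
  expect_lt(abs(mean(d$B[d$A == 1]) - 0.85), 0.02)
  expect_lt(abs(mean(d$B[d$A == 0]) - 0.2), 0.025)
})
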