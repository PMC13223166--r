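test_that("the dual criterion highlights qualifying edges only", {
  es <- fake_edge_strength(list(list(3, 5, 0.8), list(3, 9, 0.9),
                                list(5, 1, 0.65), list(7, 8, 0.4),
                                list(11, 12, 0.95)))
  top <- fake_top_pairs(list(c(3, 5), c(3, 9), c(11, 12), c(7, 8)))
  g <- extract_routes(es, top, tau = 0.6)
  hi <- paste(g$highlighted$parent, g$highlighted$child)
  expect_true("3 5" %in% hi)
  expect_true("11 12" %in% hi)
  # strong edge between non-adjacent zones is excluded as distant
  expect_false("3 9" %in% hi)
  ex <- g$excluded
  expect_equal(ex$reason[ex$parent == 3 & ex$child == 9],
               "anatomically_distant")
  # below-threshold strength takes precedence over all other reasons
  expect_equal(ex$reason[ex$parent == 7 & ex$child == 8], "below_strength")
  # strong edge whose pair is not in the top quantile
  expect_equal(ex$reason[ex$parent == 5 & ex$child == 1],
               "below_cooccurrence")
  # highlighted and excluded sets are disjoint
  expect_equal(length(intersect(hi, paste(ex$parent, ex$child))), 0)
})

test_that("an empty edge summary yields an empty pathway graph", {
  es <- fake_edge_strength(list())
  g <- extract_routes(es, fake_top_pairs(list(c(3, 5))), tau = 0.6)
  expect_equal(nrow(g$highlighted), 0)
  expect_equal(nrow(g$excluded), 0)
  expect_true(all(g$node_labels == "isolated"))
})

test_that("every highlighted edge satisfies both criteria and adjacency", {
  atlas <- zone_atlas()
  set.seed(81)
  for (r in 1:10) {
    n_edges <- sample(5:15, 1)
    es <- fake_edge_strength(lapply(seq_len(n_edges), function(i) {
      pair <- sample(14, 2)
      list(pair[1], pair[2], runif(1))
    }))
    top <- fake_top_pairs(lapply(1:20, function(i) sample(14, 2)))
    tau <- runif(1, 0.2, 0.8)
    g <- extract_routes(es, top, atlas = atlas, tau = tau)
    hi <- g$highlighted
    for (i in seq_len(nrow(hi))) {
      expect_gte(hi$directed_freq[i], tau)
      expect_true(any(top$zone_a == min(hi$parent[i], hi$child[i]) &
                        top$zone_b == max(hi$parent[i], hi$child[i])))
      expect_true(zone_adjacent(atlas, hi$parent[i], hi$child[i]))
    }
  }
})

test_that("lowering tau never removes a highlighted edge", {
  es <- fake_edge_strength(list(list(3, 5, 0.9), list(5, 1, 0.7),
                                list(11, 12, 0.5)))
  top <- fake_top_pairs(list(c(3, 5), c(1, 5), c(11, 12)))
  hi_strict <- extract_routes(es, top, tau = 0.8)$highlighted
  hi_loose <- extract_routes(es, top, tau = 0.4)$highlighted
  key <- function(h) paste(h$parent, h$child)
  expect_true(all(key(hi_strict) %in% key(hi_loose)))
})

test_that("node classification follows hub > terminal > intermediate > isolated", {
  es <- fake_edge_strength(list(list(3, 5, 0.9), list(5, 1, 0.9)))
  top <- fake_top_pairs(list(c(3, 5), c(1, 5)))
  g <- extract_routes(es, top, tau = 0.6)
  expect_equal(unname(g$node_labels["zone_01"]), "terminal")
  expect_equal(unname(g$node_labels["zone_03"]), "intermediate")
  expect_equal(unname(g$node_labels["zone_05"]), "intermediate")
  expect_equal(unname(g$node_labels["zone_09"]), "isolated")
  # star with centre degree 4: centre is a hub
  es2 <- fake_edge_strength(list(list(7, 5, 0.9), list(7, 8, 0.9),
                                 list(7, 9, 0.9), list(3, 7, 0.9)))
  top2 <- fake_top_pairs(list(c(5, 7), c(7, 8), c(7, 9), c(3, 7)))
  g2 <- extract_routes(es2, top2, tau = 0.6)
  expect_equal(unname(g2$node_labels["zone_07"]), "hub")
  # labels always partition the 14 zones
  expect_equal(length(g2$node_labels), 14)
  expect_true(all(g2$node_labels %in%
                    c("hub", "terminal", "intermediate", "isolated")))
})

test_that("chain report joins highlighted edges into maximal routes", {
  es <- fake_edge_strength(list(list(4, 2, 0.9), list(2, 14, 0.9)))
  top <- fake_top_pairs(list(c(2, 4), c(2, 14)))
  g <- extract_routes(es, top, tau = 0.6)
  chains <- chain_report(g)
  expect_equal(chains, list(c(4, 2, 14)))
  es2 <- fake_edge_strength(list(list(11, 12, 0.9)))
  g2 <- extract_routes(es2, fake_top_pairs(list(c(11, 12))), tau = 0.6)
  expect_equal(chain_report(g2), list(c(11, 12)))
  expect_equal(chain_report(extract_routes(fake_edge_strength(list()),
                                           fake_top_pairs(list(c(1, 2))))),
               list())
})

test_that("aggregation cycles are broken by dropping the weakest edge", {
  g <- structure(list(
    highlighted = data.frame(parent = c(3, 5), child = c(5, 3),
                             directed_freq = c(0.9, 0.62),
                             cooccurrence = c(0.5, 0.5)),
    excluded = data.frame(), tau = 0.6, atlas = zone_atlas()),
    class = "pathway_graph")
  expect_message(chains <- chain_report(g), "dropping")
  expect_equal(chains, list(c(3, 5)))
})

test_that("clinical augmentation recovers a planted grade effect", {
  cfg <- sim_config(1000, seed = 91,
                    effects = list(list(variable = "grade", state = "G3",
                                        zone = 5, log_odds = 2.0)))
  ch <- generate_cohort(cfg)
  aug <- augment_with_clinical(ch, clinical_bn_spec("grade"),
                               B = 100, seed = 17)
  expect_equal(length(aug$dag$nodes), 15)
  expect_gte(aug$edges$undirected_freq["grade", "zone_05"], 0.6)
})

test_that("augmented networks default to the eight clinical covariates", {
  spec <- clinical_bn_spec()
  expect_equal(spec$variables,
               c("age", "menopause", "ca125", "he4", "figo", "grade",
                 "tumor_size", "histology"))
  ch <- generate_cohort(planted_config(150, seed = 92))
  aug <- augment_with_clinical(ch, B = 2, seed = 3)
  # single-state covariates (if any) are dropped, the rest are appended
  expect_true(all(setdiff(aug$dag$nodes, zone_names()) %in% spec$variables))
  expect_equal(length(aug$dag$nodes),
               14 + length(setdiff(aug$dag$nodes, zone_names())))
})

test_that("single-state covariates are dropped with a warning", {
  ch <- generate_cohort(planted_config(120, seed = 93))
  ch$figo <- "III-IV"
  ch$zone_01 <- pmax(ch$zone_01, 0L)  # keep schema valid
  expect_warning(aug <- augment_with_clinical(ch, clinical_bn_spec(
    c("figo", "grade")), B = 2, seed = 4), "single-state")
  expect_false("figo" %in% aug$dag$nodes)
})

test_that("conditional probability reports evaluate and flag queries", {
  g <- dag_new(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  tabs <- list(A = binary_cpt("A", p1 = 0.5),
               B = binary_cpt("B", p1 = 0.5),
               C = binary_cpt("C", c("A", "B"), c(0.1, 0.1, 0.1, 0.9)))
  jt <- joint_table(g, tabs)
  oracle <- sum(jt$prob[jt$A == "1" & jt$C == "1"]) /
    sum(jt$prob[jt$C == "1"])
  rep_ <- conditional_probability_report(g, tabs, list(
    list(target = c(C = "1"), evidence = c(A = "1", B = "1")),
    list(target = c(A = "1"), evidence = c(C = "1"))))
  expect_equal(rep_$probability[1], 0.9, tolerance = 1e-9)
  expect_equal(rep_$probability[2], oracle, tolerance = 1e-9)
  expect_true(all(rep_$flag == "ok"))
  tabs$A <- binary_cpt("A", p1 = 0)
  rep2 <- conditional_probability_report(g, tabs, list(
    list(target = c(C = "1"), evidence = c(A = "1"))))
  expect_equal(rep2$flag, "inconsistent_evidence")
})

test_that("a planted conditional probability is recovered from data", {
  # P(zone5 = 1 | zone3 = 1, grade = G3) designed as 0.875:
  # route 3 -> 5 at strength 0.7 plus a G3 log-odds shift of
  # qlogis(0.875) - qlogis(0.7)
  shift <- qlogis(0.875) - qlogis(0.7)
  cfg <- sim_config(2000, seed = 95,
                    effects = list(list(variable = "grade", state = "G3",
                                        zone = 5, log_odds = shift)))
  cfg <- plant_pathway(cfg, c(3, 5), 0.7, root_p1 = 0.6)
  ch <- generate_cohort(cfg)
  d <- data.frame(zone_03 = ch$zone_03, zone_05 = ch$zone_05,
                  grade = factor(ch$grade, levels = c("G1", "G2", "G3")))
  g <- dag_new(c("zone_03", "zone_05", "grade"),
               rbind(c("zone_03", "zone_05"), c("grade", "zone_05")))
  tabs <- fit_cpts(g, d)
  est <- posterior_query(g, tabs, c(zone_05 = "1"),
                         c(zone_03 = "1", grade = "G3"))
  expect_lt(abs(est - 0.875), 0.05)
})
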