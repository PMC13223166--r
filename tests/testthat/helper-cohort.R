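# shared fixture builders (everything is generated in code)

# build a schema-complete cohort from a zone involvement matrix; positives
# default to the involvement indicator itself (one positive node per
# involved zone) and resected counts to positives + 2
toy_cohort <- function(zones, resected = NULL, positive = NULL,
                       laterality = "bilateral", nact = 0L,
                       figo = NULL) {
  zones <- as.matrix(zones)
  n <- nrow(zones)
  stopifnot(ncol(zones) == 14)
  if (is.null(positive)) positive <- zones
  if (is.null(resected)) resected <- positive + 2L
  lnpos <- rowSums(zones) > 0
  if (is.null(figo)) figo <- ifelse(lnpos, "III-IV", "I-II")
  out <- data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    age = rep(55, n), menopause = rep(1L, n), parity = rep("1-3", n),
    ca125 = rep(300, n), he4 = rep(160, n), ascites_ml = rep(100, n),
    tumor_size_mm = rep(90, n), grade = rep("G3", n),
    histology = rep("non-serous", n), figo = figo,
    laterality = rep(laterality, length.out = n),
    nact = rep(nact, length.out = n),
    stringsAsFactors = FALSE
  )
  colnames(zones) <- zone_names()
  colnames(resected) <- sprintf("resected_%02d", 1:14)
  colnames(positive) <- sprintf("positive_%02d", 1:14)
  cbind(out, as.data.frame(zones), as.data.frame(resected),
        as.data.frame(positive))
}

# involvement matrix from a list of involved-zone id sets
zones_from_sets <- function(sets) {
  m <- matrix(0L, length(sets), 14)
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

# canonical planted-routes configuration (3 -> 5 -> 1 and 11 -> 12)
planted_config <- function(n, seed) {
  reference_sim_config(n, seed)
}

# hand-constructed edge-strength summary for pathway-rule tests
fake_edge_strength <- function(directed, nodes = zone_names()) {
  p <- length(nodes)
  dm <- matrix(0, p, p, dimnames = list(nodes, nodes))
  um <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (e in directed) {
    dm[zone_names(e[[1]]), zone_names(e[[2]])] <- e[[3]]
  }
  um <- pmax(dm, t(dm))
  structure(list(B = 100L, seed = 0L, nodes = nodes,
                 directed_freq = dm, undirected_freq = um),
            class = "edge_strength")
}

# top-pair set covering given zone pairs with descending dummy values
fake_top_pairs <- function(pairs) {
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(zone_a = min(p), zone_b = max(p),
               value = 0.9 - 0.01 * i)
  }))
}
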