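test_that("rank aggregation groups counts and flags dark-matter nodes", {
  counts <- matrix(as.integer(c(
    2, 3, 1, 4,
    0, 5, 2, 1
  )), 2, 4, byrow = TRUE,
  dimnames = list(c("s1", "s2"), paste0("o", 1:4))
  )
  tax <- data.frame(
    otu_id = paste0("o", 1:4), kingdom = "Bacteria", phylum = "p1",
    class = "c1", order = "or1", family = c("f1", "f1", "f2", "f2"),
    genus = c("gA", "gA", "Uncultured bacterium", "gB"),
    species = NA_character_, stringsAsFactors = FALSE
  )
  agg <- aggregate_to_rank(counts, tax, "genus")
  expect_equal(agg$counts[, "gA"], c(s1 = 5L, s2 = 5L)) # two OTUs merged
  expect_true(agg$unknown[["unknown_f2"]]) # flagged via marker label
  expect_false(agg$unknown[["gA"]])
  # group-by oracle on a random instance
  rc <- random_counts(4, 9, seed = 55)
  fams <- rep(c("fx", "fy", "fz"), each = 3)
  tax2 <- data.frame(
    otu_id = colnames(rc), kingdom = "Bacteria", phylum = "p",
    class = "c", order = "o", family = fams, genus = "g",
    species = NA_character_, stringsAsFactors = FALSE
  )
  agg2 <- aggregate_to_rank(rc, tax2, "family")
  for (f in unique(fams)) {
    expect_equal(agg2$counts[, f], rowSums(rc[, fams == f]))
  }
})

test_that("network construction finds planted associations, not noise", {
  n <- 200
  base <- withr::with_seed(56, {
    m <- matrix(rpois(n * 20, 30), n, 20)
    latent <- rpois(n, 40)
    m[, 1] <- latent + rpois(n, 2) # two taxa driven by the
    m[, 2] <- latent + rpois(n, 2) # same latent factor
    m
  })
  dimnames(base) <- list(sprintf("s%03d", 1:n), sprintf("t%02d", 1:20))
  storage.mode(base) <- "integer"
  unknown <- stats::setNames(rep(FALSE, 20), colnames(base))
  net <- build_network(list(counts = base, unknown = unknown))
  expect_true(net$adjacency["t01", "t02"])
  # independent shuffled taxa: edge density stays below 2 percent
  shuf <- withr::with_seed(57, apply(base, 2, sample))
  dimnames(shuf) <- dimnames(base)
  storage.mode(shuf) <- "integer"
  net0 <- build_network(list(counts = shuf, unknown = unknown))
  dens <- sum(net0$adjacency) / (20 * 19)
  expect_lt(dens, 0.02)
  # impossible threshold leaves no edges
  net1 <- build_network(list(counts = base, unknown = unknown),
    threshold = 1.01
  )
  expect_identical(sum(net1$adjacency), 0L)
  expect_error(
    build_network(list(counts = base[1:3, ], unknown = unknown)),
    "4 samples"
  )
})

test_that("centralities match closed forms and the brute-force oracle", {
  # star K_{1,4}: center carries all 6 leaf pairs, harmonic closeness 1
  star <- matrix(0L, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star[1, 2:5] <- star[2:5, 1] <- 1L
  unknown <- stats::setNames(rep(FALSE, 5), letters[1:5])
  cent <- network_centralities(network_model(star, unknown))
  expect_equal(cent$betweenness[1], 6)
  expect_equal(cent$closeness[1], 1)
  expect_equal(cent$degree[1], 4)
  expect_equal(cent$closeness[2], (1 + 3 * 0.5) / 4)

  # isolated node scores zero everywhere
  iso <- rbind(cbind(star, 0L), 0L)
  dimnames(iso) <- list(letters[1:6], letters[1:6])
  cent6 <- network_centralities(
    network_model(iso, stats::setNames(rep(FALSE, 6), letters[1:6]))
  )
  expect_equal(unlist(cent6[6, c("degree", "betweenness", "closeness")]),
    c(degree = 0, betweenness = 0, closeness = 0)
  )

  # exhaustive all-pairs oracle on random graphs with n <= 12
  for (seed in c(58, 59)) {
    a <- random_adjacency(10, 0.3, seed = seed)
    cent_r <- network_centralities(
      network_model(a, stats::setNames(rep(FALSE, 10), rownames(a)))
    )
    bf <- bf_centralities(a)
    expect_equal(cent_r$degree, unname(bf$degree), tolerance = 1e-9)
    expect_equal(cent_r$betweenness, bf$betweenness, tolerance = 1e-9)
    expect_equal(cent_r$closeness, bf$closeness, tolerance = 1e-9)
  }
})

test_that("hub scores equal the principal eigenvector", {
  for (seed in c(60, 61)) {
    a <- random_adjacency(9, 0.4, seed = seed)
    net <- network_model(a, stats::setNames(rep(FALSE, 9), rownames(a)))
    hs <- hub_scores(net)
    ev <- eigen(a, symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    expect_equal(unname(hs), v / max(v), tolerance = 1e-6)
  }
  # regular graph: all scores equal
  ring <- matrix(0L, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (i in 1:6) {
    ring[i, i %% 6 + 1] <- 1L
    ring[i %% 6 + 1, i] <- 1L
  }
  hs_ring <- hub_scores(
    network_model(ring, stats::setNames(rep(FALSE, 6), letters[1:6]))
  )
  expect_equal(unname(hs_ring), rep(1, 6), tolerance = 1e-8)
  # edgeless graph warns and returns zeros
  empty <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(
    z <- hub_scores(
      network_model(empty, stats::setNames(rep(FALSE, 3), letters[1:3]))
    ),
    "edgeless"
  )
  expect_equal(unname(z), rep(0, 3))
})

test_that("top-hub unknown fraction is deterministic and bounded", {
  cg <- connector_graph()
  net <- network_model(cg$adjacency, cg$unknown)
  expect_equal(
    top_hub_unknown_fraction(network_model(cg$adjacency,
      stats::setNames(rep(TRUE, nrow(cg$adjacency)), rownames(cg$adjacency))
    )),
    1.0
  )
  expect_equal(
    top_hub_unknown_fraction(network_model(cg$adjacency,
      stats::setNames(rep(FALSE, nrow(cg$adjacency)), rownames(cg$adjacency))
    )),
    0.0
  )
  frac <- top_hub_unknown_fraction(net, k = 10)
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})

test_that("node deletion never increases remaining degrees", {
  a <- random_adjacency(12, 0.35, seed = 62)
  net <- network_model(a, stats::setNames(
    rep(c(TRUE, FALSE), 6), rownames(a)
  ))
  before <- network_centralities(net)
  after <- network_centralities(
    trophoweb:::delete_nodes(net, net$nodes[net$unknown])
  )
  common <- intersect(before$node, after$node)
  expect_true(all(
    after$degree[match(common, after$node)] <=
      before$degree[match(common, before$node)]
  ))
})

test_that("removing planted connector nodes collapses betweenness", {
  cg <- connector_graph(n_modules = 5, module_size = 6)
  net <- network_model(cg$adjacency, cg$unknown)
  pert <- perturb_and_compare(net, B = 100, seed = 63)
  w <- pert$wilcoxon
  row_b <- w[w$comparison == "without_vs_bootstrap" & w$metric == "betweenness", ]
  expect_lt(row_b$p_value, 0.05)
  expect_identical(row_b$direction, "increase") # bootstrap keeps connectors
  expect_lt(
    mean(pert$distributions$betweenness$without_unknown),
    mean(pert$distributions$betweenness$bootstrap)
  )
  # replicate-rank test flags the same signal
  rr <- pert$replicate_rank
  expect_lt(rr$p_value[rr$metric == "betweenness"], 0.05)
})

test_that("randomly flagged nodes look like the bootstrap null", {
  a <- random_adjacency(30, 0.25, seed = 64)
  ps <- withr::with_seed(65, vapply(1:20, function(r) {
    unknown <- stats::setNames(rep(FALSE, 30), rownames(a))
    unknown[sample(30, 5)] <- TRUE
    net <- network_model(a, unknown)
    pert <- perturb_and_compare(net, B = 39, seed = r)
    pert$replicate_rank$p_value[pert$replicate_rank$metric == "closeness"]
  }, numeric(1)))
  expect_gte(mean(ps > 0.05), 0.8)

  # zero flagged nodes: degenerate result, no test
  net0 <- network_model(a, stats::setNames(rep(FALSE, 30), rownames(a)))
  expect_warning(p0 <- perturb_and_compare(net0, B = 5, seed = 1), "no unknown")
  expect_true(p0$degenerate)
})
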