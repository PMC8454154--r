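plain <- function(m) {
  attr(m, "metric") <- NULL
  unname(m)
}

test_that("unweighted UniFrac matches trivial cases and the branch-walk oracle", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  counts <- matrix(as.integer(c(
    1, 1, 0, 0,
    0, 0, 2, 3,
    1, 1, 0, 0
  )), 3, 4, byrow = TRUE,
  dimnames = list(c("x", "y", "z"), c("A", "B", "C", "D"))
  )
  d <- unweighted_unifrac(counts, star)
  expect_equal(d["x", "z"], 0) # identical presence profiles
  expect_equal(d["x", "y"], 1) # disjoint tip sets on a star tree

  tree <- withr::with_seed(11, ape::rtree(8))
  tree$tip.label <- sprintf("OTU%d", 1:8)
  rc <- random_counts(4, 8, lambda = 1, seed = 12)
  colnames(rc) <- tree$tip.label
  rc[rowSums(rc) == 0, 1] <- 1L
  expect_equal(
    plain(unweighted_unifrac(rc, tree)),
    unname(bf_unifrac(rc, tree, weighted = FALSE)),
    tolerance = 1e-12
  )
  # second, fully independent implementation
  expect_equal(
    plain(unweighted_unifrac(rc, tree)),
    unname(as.matrix(picante::unifrac(rc, tree))[rownames(rc), rownames(rc)]),
    tolerance = 1e-10
  )
  bad <- rc
  colnames(bad)[1] <- "not_a_tip"
  expect_error(unweighted_unifrac(bad, tree), "not_a_tip")
})

test_that("weighted UniFrac matches closed forms and the branch-walk oracle", {
  two <- ape::read.tree(text = "(A:0.3,B:0.7);")
  counts <- matrix(as.integer(c(10, 0, 0, 5)), 2, 2,
    dimnames = list(c("x", "y"), c("A", "B"))
  )
  raw <- weighted_unifrac(counts, two, normalized = FALSE)
  expect_equal(raw["x", "y"], 1.0) # sum of both branch lengths
  same <- matrix(as.integer(c(10, 5, 2, 1)), 2, 2,
    dimnames = list(c("x", "y"), c("A", "B"))
  )
  expect_equal(weighted_unifrac(same, two)["x", "y"], 0) # same profiles

  tree <- withr::with_seed(13, ape::rtree(8))
  tree$tip.label <- sprintf("OTU%d", 1:8)
  rc <- random_counts(4, 8, lambda = 2, seed = 14)
  colnames(rc) <- tree$tip.label
  rc[rowSums(rc) == 0, 1] <- 1L
  expect_equal(
    plain(weighted_unifrac(rc, tree, normalized = TRUE)),
    unname(bf_unifrac(rc, tree, weighted = TRUE, normalized = TRUE)),
    tolerance = 1e-12
  )
  expect_equal(
    plain(weighted_unifrac(rc, tree, normalized = FALSE)),
    unname(bf_unifrac(rc, tree, weighted = TRUE, normalized = FALSE)),
    tolerance = 1e-12
  )
})

test_that("Jaccard distance equals set algebra and vegan's binary jaccard", {
  counts <- random_counts(6, 30, lambda = 0.5, seed = 15)
  counts[rowSums(counts) == 0, 1] <- 1L
  d <- jaccard_distance(counts)
  dv <- as.matrix(vegan::vegdist(counts, method = "jaccard", binary = TRUE))
  expect_equal(plain(d), unname(dv), tolerance = 1e-12)
  ident <- rbind(a = c(1L, 0L, 2L), b = c(3L, 0L, 1L))
  colnames(ident) <- paste0("o", 1:3)
  expect_equal(jaccard_distance(ident)["a", "b"], 0)
  disj <- rbind(a = c(1L, 0L), b = c(0L, 4L))
  colnames(disj) <- paste0("o", 1:2)
  expect_equal(jaccard_distance(disj)["a", "b"], 1)
})

test_that("classical PCoA reconstructs Euclidean configurations", {
  pts <- withr::with_seed(16, matrix(rnorm(10 * 2), 10, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  pc <- pcoa_classic(d)
  rec <- as.matrix(dist(pc$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  # agrees with cmdscale eigenvalues
  cm <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  expect_equal(pc$eigenvalues[1:2], cm$eig[1:2], tolerance = 1e-9)

  # three equidistant points: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  pc3 <- pcoa_classic(eq)
  pos <- pc3$eigenvalues[pc3$eigenvalues > 1e-10]
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(pcoa_classic(z)$coordinates == 0))
  ns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa_classic(ns), "symmetric")
})

test_that("PERMANOVA matches adonis2 and the exhaustive oracle", {
  counts <- random_counts(6, 20, lambda = 3, seed = 17)
  d <- jaccard_distance(counts)
  labs <- rep(c("a", "b"), each = 3)

  res <- permanova(d, labs, n_perm = 99, seed = 1)
  a2 <- suppressMessages(vegan::adonis2(stats::as.dist(d) ~ g,
    data = data.frame(g = labs), permutations = 99
  ))
  expect_equal(res$f, a2$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, a2$R2[1], tolerance = 1e-10)
  expect_identical(res$df, c(1L, 4L) * 1)

  # exact p by enumerating all 720 orderings, against an independent
  # from-scratch pseudo-F computed over sample pairs
  perms <- all_permutations(6)
  res_ex <- permanova(d, labs, permutations = perms)
  f_direct <- function(lab) {
    d2 <- d^2
    sst <- sum(d2[upper.tri(d2)]) / 6
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  f_obs <- f_direct(labs)
  f_all <- apply(perms, 1, function(ord) f_direct(labs[ord]))
  p_exact <- (1 + sum(f_all >= f_obs - 1e-12)) / (1 + length(f_all))
  expect_equal(res_ex$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res_ex$f, f_obs, tolerance = 1e-12)

  expect_error(permanova(d, rep("a", 6)), "two groups")
})

test_that("PERMANOVA is invariant to sample reordering", {
  counts <- random_counts(9, 25, lambda = 2, seed = 18)
  d <- jaccard_distance(counts)
  labs <- rep(c("a", "b", "c"), 3)
  ord <- withr::with_seed(19, sample(9))
  r1 <- permanova(d, labs, n_perm = 49, seed = 5)
  r2 <- permanova(d[ord, ord], labs[ord], n_perm = 49, seed = 5)
  expect_equal(r1$f, r2$f, tolerance = 1e-12)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
})

test_that("pairwise PERMANOVA letters reflect adjusted significance", {
  # two clearly different groups
  counts <- rbind(
    random_counts(5, 30, lambda = 5, seed = 20),
    random_counts(5, 30, lambda = 5, seed = 21) + 20L
  )
  counts[6:10, 1:15] <- 0L
  rownames(counts) <- sprintf("s%02d", 1:10)
  d <- jaccard_distance(counts)
  labs <- rep(c("a", "b"), each = 5)
  pw <- pairwise_permanova(d, labs, n_perm = 99, seed = 2)
  expect_identical(nrow(pw$pairs), 1L)
  if (pw$pairs$p_adjusted < 0.05) {
    expect_false(pw$letters["a"] == pw$letters["b"])
  } else {
    expect_identical(pw$letters[["a"]], pw$letters[["b"]])
  }

  # three identical groups share a letter
  same <- random_counts(12, 30, lambda = 3, seed = 22)
  d3 <- jaccard_distance(same)
  labs3 <- rep(c("a", "b", "c"), each = 4)
  pw3 <- pairwise_permanova(d3, labs3, n_perm = 99, seed = 3)
  expect_true(length(unique(pw3$letters)) == 1)

  # per-pair p-values reproduce standalone calls with the derived seeds
  for (k in seq_len(nrow(pw3$pairs))) {
    g1 <- pw3$pairs$group1[k]
    g2 <- pw3$pairs$group2[k]
    idx <- which(labs3 %in% c(g1, g2))
    solo <- permanova(d3[idx, idx], labs3[idx], n_perm = 99,
      seed = trophoweb:::child_seed(3, k)
    )
    expect_equal(pw3$pairs$p_value[k], solo$p_value)
  }
})
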