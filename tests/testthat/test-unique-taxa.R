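toy_study <- function() {
  counts <- matrix(as.integer(c(
    # o1 o2 o3 o4 o5
    5, 1, 0, 0, 0, # soil1
    3, 0, 0, 0, 0, # soil2
    2, 0, 4, 0, 0, # wormA1
    1, 0, 0, 6, 0, # wormA2
    0, 2, 0, 3, 2 # miteB1
  )), 5, 5, byrow = TRUE,
  dimnames = list(
    c("soil1", "soil2", "wormA1", "wormA2", "miteB1"),
    paste0("o", 1:5)
  )
  )
  meta <- data.frame(
    sample_id = rownames(counts),
    sample_type = c("soil", "soil", "wormA", "wormA", "miteB"),
    stringsAsFactors = FALSE
  )
  list(counts = counts, meta = meta)
}

test_that("soil exclusion is absolute and shared OTUs appear in both groups", {
  ts <- toy_study()
  rep_u <- unique_otus(ts$counts, ts$meta)
  # o2 has a single soil read: excluded everywhere
  expect_false("o2" %in% rep_u$all_unique)
  # o4 detected in both faunal groups, never in soil: in both sets
  expect_true("o4" %in% rep_u$per_group$wormA)
  expect_true("o4" %in% rep_u$per_group$miteB)
  expect_setequal(rep_u$per_group$wormA, c("o3", "o4"))
  expect_setequal(rep_u$per_group$miteB, c("o4", "o5"))
  # every reported unique OTU has zero soil reads (invariant)
  soil <- ts$counts[ts$meta$sample_type == "soil", ]
  expect_identical(max(soil[, rep_u$all_unique]), 0L)
  expect_error(
    unique_otus(ts$counts[3:5, ], ts$meta[3:5, ]),
    "no soil"
  )
})

test_that("planted unique sets are recovered exactly from the simulator", {
  sim <- simulate_foodweb_dataset(tiny_sim_config(seed = 51))
  rep_u <- unique_otus(sim$counts, sim$metadata)
  for (g in names(sim$truth$unique_otus)) {
    expect_setequal(rep_u$per_group[[g]], sim$truth$unique_otus[[g]])
  }
})

test_that("dominance filter applies strict thresholds and commutes", {
  counts <- random_counts(10, 50, lambda = 2, seed = 52)
  ids <- prevalence_abundance_filter(counts,
    min_max_rel_abund = 0.02, min_prevalence = 0.6
  )
  rel <- counts / rowSums(counts)
  brute <- colnames(counts)[
    apply(rel, 2, max) > 0.02 & colMeans(counts > 0) > 0.6
  ]
  expect_setequal(ids, brute)

  # boundary: an OTU exactly at the abundance threshold is excluded
  one <- matrix(as.integer(c(3, 97, 3, 97)), 2, 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), c("oA", "oB"))
  )
  expect_false("oA" %in%
    prevalence_abundance_filter(one, min_max_rel_abund = 0.03,
      min_prevalence = 0
    ))
  expect_true("oA" %in%
    prevalence_abundance_filter(one, min_max_rel_abund = 0.029,
      min_prevalence = 0
    ))
  # prevalence boundary is strict too
  expect_false("oA" %in%
    prevalence_abundance_filter(one, min_max_rel_abund = 0,
      min_prevalence = 1
    ))
  # (0, 0) keeps every detected OTU
  expect_setequal(
    prevalence_abundance_filter(counts, min_max_rel_abund = 0,
      min_prevalence = 0
    ),
    colnames(counts)[colSums(counts) > 0]
  )
  expect_error(
    prevalence_abundance_filter(counts, samples = character(0)),
    "empty"
  )
})

test_that("Venn region counts agree with direct set algebra", {
  counts <- random_counts(9, 40, lambda = 0.7, seed = 53)
  meta <- data.frame(
    sample_id = rownames(counts),
    sample_type = rep(c("a", "b", "c"), each = 3),
    stringsAsFactors = FALSE
  )
  venn <- shared_otu_counts(counts, meta)
  det <- lapply(c("a", "b", "c"), function(g) {
    colnames(counts)[colSums(counts[meta$sample_type == g, ]) > 0]
  })
  names(det) <- c("a", "b", "c")
  only_a <- setdiff(det$a, union(det$b, det$c))
  abc <- Reduce(intersect, det)
  if (length(only_a) > 0) expect_identical(venn$regions[["a"]], length(only_a))
  expect_identical(venn$shared_all, length(abc))
  expect_equal(
    venn$shared_all_fraction,
    length(abc) / length(Reduce(union, det))
  )
  expect_identical(sum(venn$regions), length(Reduce(union, det)))

  # identical and disjoint edge cases
  two <- rbind(a1 = c(1L, 1L, 0L), b1 = c(2L, 3L, 0L))
  colnames(two) <- paste0("o", 1:3)
  m2 <- data.frame(sample_id = c("a1", "b1"), sample_type = c("a", "b"))
  expect_equal(shared_otu_counts(two, m2)$shared_all_fraction, 1)
  disj <- rbind(a1 = c(1L, 0L), b1 = c(0L, 1L))
  colnames(disj) <- paste0("o", 1:2)
  expect_equal(shared_otu_counts(disj, m2)$shared_all_fraction, 0)

  m7 <- data.frame(
    sample_id = rownames(counts),
    sample_type = c(paste0("g", 1:7), "g1", "g2")
  )
  expect_error(shared_otu_counts(counts, m7), "2-6")
})

test_that("unique-taxon counts rise with planted trophic level", {
  sim <- simulate_foodweb_dataset(tiny_sim_config(seed = 54))
  rep_u <- unique_otus(sim$counts, sim$metadata)
  tl <- trophic_assignments(sim$metadata)
  tlv <- stats::setNames(tl$trophic_level, tl$sample_id)
  res <- unique_counts_by_level(rep_u, sim$counts, tlv)
  expect_gt(res$trend$rho, 0)
  expect_lt(res$trend$p_value, 0.01)
  # distinct unique taxa at the top level exceed the bottom level
  expect_gt(
    res$per_level_counts[[length(res$per_level_counts)]],
    res$per_level_counts[[1]]
  )
})
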