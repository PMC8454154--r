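test_that("occurrence statistics match direct computation", {
  counts <- random_counts(6, 15, lambda = 1, seed = 28)
  counts <- rarefy_table(counts, min(rowSums(counts)), seed = 1)$table
  st <- occurrence_stats(counts)
  n_reads <- rowSums(counts)[1]
  for (k in seq_len(nrow(st))) {
    j <- st$otu_id[k]
    expect_equal(st$p[k], mean(counts[, j] / n_reads), tolerance = 1e-12)
    expect_equal(st$f[k], mean(counts[, j] >= 1), tolerance = 1e-12)
  }
  # absent OTUs dropped, ubiquitous OTUs have f = 1
  zero <- counts
  zero[, 1] <- 0L
  zero[, 2] <- 1L
  zero <- rarefy_table(zero, min(rowSums(zero)), seed = 2)$table
  zero[, 1] <- 0L
  st2 <- occurrence_stats(zero)
  expect_false(colnames(zero)[1] %in% st2$otu_id)
  expect_error(occurrence_stats(random_counts(4, 5, seed = 1)), "rarefy")
})

test_that("neutral frequency predictions match quadrature oracles", {
  # threshold form vs direct integration of the beta density
  q <- stats::integrate(function(x) dbeta(x, 1000 * 0.1 * 0.001, 1000 * 0.1 * 0.999),
    0.001, 1,
    rel.tol = 1e-12
  )$value
  expect_equal(sncm_predict(0.001, 1000, 0.1, 0.001), q, tolerance = 1e-8)

  # exact occupancy vs integration of beta density times detection prob
  N <- 500
  a <- 5
  b <- 45
  q2 <- stats::integrate(function(x) dbeta(x, a, b) * (1 - (1 - x)^N),
    0, 1,
    rel.tol = 1e-12
  )$value
  expect_equal(sncm_occupancy(a / (a + b), N, (a + b) / N), q2,
    tolerance = 1e-8
  )

  # limits and monotonicity
  expect_gt(sncm_predict(0.999, 1000, 0.5), 0.999)
  grid <- seq(1e-4, 0.05, length.out = 40)
  expect_false(is.unsorted(sncm_predict(grid, 1000, 0.1)))
  expect_false(is.unsorted(sncm_occupancy(grid, 1000, 0.1)))
  expect_error(sncm_predict(0, 1000, 0.1), "p")
  expect_error(sncm_predict(0.5, 1000, 0), "m")
})

test_that("the Sloan fit recovers the generating migration rate", {
  pool <- simulate_source_pool(500, seed = 33)
  counts <- simulate_neutral_community(pool, N = 10000, m = 0.1,
    n_samples = 300, seed = 34
  )
  fit <- fit_sloan(occurrence_stats(counts))
  expect_lt(abs(fit$Nm / 1000 - 1), 0.15)
  expect_lt(fit$aic_neutral, fit$aic_binomial)
  expect_gt(fit$r_squared, 0.9)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  # neutral data: 'within' dominates
  expect_gte(fit$fractions[["within"]], 0.75)
  # the threshold convention remains available and fits the same data
  fit_thr <- fit_sloan(occurrence_stats(counts), prediction = "threshold")
  expect_gt(fit_thr$Nm, 0)
  expect_lt(fit_thr$r_squared, 1)
})

test_that("fitted Nm is monotone in the generating Nm", {
  fits <- vapply(c(200, 1000, 5000), function(nm) {
    pool <- simulate_source_pool(400, seed = 35)
    counts <- simulate_neutral_community(pool, N = 10000, m = nm / 10000,
      n_samples = 200, seed = 36
    )
    fit_sloan(occurrence_stats(counts))$Nm
  }, numeric(1))
  expect_false(is.unsorted(fits))
})

test_that("a perfect fit is handled without infinite AIC", {
  p <- seq(0.0005, 0.02, length.out = 50)
  N <- 5000
  m <- 0.15
  st <- data.frame(otu_id = sprintf("o%02d", 1:50), p = p,
    f = sncm_occupancy(p, N, m)
  )
  fit <- fit_sloan(st, N = N, n_samples = 200)
  expect_equal(fit$m, m, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_true(is.finite(fit$aic_neutral))
  # degenerate SST
  flat <- data.frame(otu_id = sprintf("o%02d", 1:20),
    p = seq(0.001, 0.01, length.out = 20), f = 0.5
  )
  expect_error(fit_sloan(flat, N = 1000, n_samples = 50), "degenerate")
})

test_that("above/below partitions are disjoint and conserve counts", {
  pool <- simulate_source_pool(200, seed = 37)
  counts <- simulate_neutral_community(pool, N = 3000, m = 0.05,
    n_samples = 100, seed = 38
  )
  fit <- fit_sloan(occurrence_stats(counts))
  parts <- suppressWarnings(partition_communities(counts, fit))
  expect_length(intersect(colnames(parts$above), colnames(parts$below)), 0)
  expect_true(all(colnames(parts$above) %in% colnames(counts)))
  for (j in colnames(parts$above)) {
    expect_identical(sum(parts$above[, j]), sum(counts[, j]))
  }
})

test_that("host filtering pushes OTUs outside the neutral band", {
  pool <- simulate_source_pool(300, seed = 39)
  neutral <- simulate_neutral_community(pool, N = 5000, m = 0.2,
    n_samples = 150, seed = 40
  )
  f_neu <- fit_sloan(occurrence_stats(neutral))
  # strong host filtering: sample from a heavily tilted pool but fit
  # against statistics that mix two different environments
  tilt <- withr::with_seed(41, pool * rlnorm(300, 0, 2))
  tilt <- tilt / sum(tilt)
  filtered <- simulate_neutral_community(tilt, N = 5000, m = 0.2,
    n_samples = 75, seed = 42
  )
  mixed <- rbind(neutral[1:75, ], filtered)
  rownames(mixed) <- sprintf("s%03d", seq_len(nrow(mixed)))
  f_det <- fit_sloan(occurrence_stats(mixed))
  expect_gt(
    f_det$fractions[["above"]] + f_det$fractions[["below"]],
    f_neu$fractions[["above"]] + f_neu$fractions[["below"]]
  )
})
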