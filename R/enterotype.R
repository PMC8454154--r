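# Enterotyping: genus-level relative-abundance profiles, Jensen-Shannon
# distance, k-medoids (PAM) clustering, and data-driven choice of the
# number of clusters by the Calinski-Harabasz index (silhouette reported
# alongside). Clustering is always per host group, never across groups.

#' Genus-level relative-abundance profiles
#'
#' Sums counts per genus and row-normalizes. OTUs whose genus is an
#' unknown marker (or that are absent from the taxonomy) are pooled under
#' a synthetic label `unclassified_<deepest resolved rank>`.
#'
#' @param counts samples x OTUs matrix.
#' @param taxonomy data.frame as from [read_taxonomy()].
#' @return samples x genera matrix of relative abundances (rows sum to 1).
#' @export
genus_profiles <- function(counts, taxonomy) {
  counts <- validate_otu_counts(counts)
  labels <- taxon_label_at_rank(colnames(counts), taxonomy, "genus")$label
  agg <- t(rowsum(t(counts), labels))
  totals <- rowSums(agg)
  if (any(totals == 0)) {
    stopf("all-zero sample: %s", rownames(agg)[which(totals == 0)[1]])
  }
  agg / totals
}

#' Jensen-Shannon distance matrix
#'
#' `D(a, b) = sqrt(JSD(a, b))` with `JSD = KL(a||m)/2 + KL(b||m)/2`,
#' `m = (a + b)/2`, log base 2 (so D is in [0, 1]); `0 * log 0 = 0`.
#'
#' @param profiles samples x features matrix; rows sum to 1.
#' @return symmetric distance matrix.
#' @export
jsd_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("negative entries in profiles", call. = FALSE)
  if (max(abs(rowSums(profiles) - 1)) > 1e-6) {
    stop("profile rows must sum to 1", call. = FALSE)
  }
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- nrow(profiles)
  h <- apply(profiles, 1, ent)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mix <- (profiles[i, ] + profiles[j, ]) / 2
      jsd <- ent(mix) - (h[i] + h[j]) / 2
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  finish_dist(d, rownames(profiles), "jensen_shannon")
}

#' Partitioning around medoids on a distance matrix
#'
#' BUILD + SWAP k-medoids (via `cluster::pam`), minimizing total distance
#' to the cluster medoid. Deterministic; ties resolve to the lowest sample
#' index.
#'
#' @param d symmetric distance matrix.
#' @param k number of clusters, `2 <= k <= n - 1`.
#' @param seed accepted for interface stability; the algorithm is
#'   deterministic and does not consume randomness.
#' @return list with `assignment` (named integer), `medoids` (sample ids),
#'   `objective` (total within-cluster distance to medoid).
#' @export
pam_medoids <- function(d, k, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k > n - 1) {
    stopf("`k` must be in [2, %d]", n - 1)
  }
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  assignment <- fit$clustering
  names(assignment) <- rownames(d)
  medoids <- rownames(d)[fit$id.med]
  obj <- sum(vapply(seq_len(n), function(i) {
    d[i, fit$id.med[assignment[i]]]
  }, numeric(1)))
  list(assignment = assignment, medoids = medoids, objective = obj)
}

# Calinski-Harabasz index generalized to a distance matrix: sums of
# squared distances give total and within-cluster dispersion.
ch_index <- function(d, assignment) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  k <- length(unique(assignment))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(assignment)) {
    idx <- which(assignment == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' Choose the number of clusters for PAM
#'
#' Runs PAM for each k and selects the k maximizing the Calinski-Harabasz
#' index on the distance matrix; mean silhouette width is reported
#' alongside.
#'
#' @param d symmetric distance matrix.
#' @param k_range candidate cluster numbers (subset of `2:(n-1)`).
#' @param seed passed to [pam_medoids()].
#' @return list with `k_best` and `index` (data.frame: k, ch, silhouette).
#' @export
choose_k <- function(d, k_range = 2:10, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("empty `k_range`", call. = FALSE)
  rows <- lapply(k_range, function(k) {
    fit <- pam_medoids(d, k, seed = seed)
    sil <- cluster::silhouette(fit$assignment, dmatrix = d)
    data.frame(
      k = k, ch = ch_index(d, fit$assignment),
      silhouette = mean(sil[, "sil_width"])
    )
  })
  index <- do.call(rbind, rows)
  list(k_best = index$k[which.max(index$ch)], index = index)
}

#' Enterotype each host group
#'
#' For every faunal group separately: genus profiles, Jensen-Shannon
#' distances, k chosen by [choose_k()], PAM at that k, and a driver genus
#' per cluster (highest mean relative abundance). Cluster labels combine
#' the group's initial with the driver genus initial, suffixed on
#' collision.
#'
#' @param counts samples x OTUs matrix.
#' @param taxonomy taxonomy data.frame.
#' @param metadata sample metadata.
#' @param group_field metadata column holding the host group.
#' @param exclude groups to skip (default `"soil"`).
#' @param k_range candidate cluster numbers.
#' @param seed integer seed or `NULL`.
#' @return named list per group of class `enterotype_result`: `k`,
#'   `assignment`, `cluster_labels`, `medoids`, `drivers`, `index`.
#' @export
enterotype_groups <- function(counts, taxonomy, metadata,
                              group_field = "sample_type",
                              exclude = "soil", k_range = 2:10,
                              seed = NULL) {
  idx <- match(rownames(counts), metadata$sample_id)
  groups <- setdiff(unique(metadata[[group_field]][idx]), exclude)
  out <- list()
  for (g in groups) {
    sel <- rownames(counts)[metadata[[group_field]][idx] == g]
    if (length(sel) < 4) next
    prof <- genus_profiles(counts[sel, , drop = FALSE], taxonomy)
    d <- jsd_matrix(prof)
    ch <- choose_k(d, k_range, seed = seed)
    fit <- pam_medoids(d, ch$k_best, seed = seed)
    drivers <- vapply(seq_len(ch$k_best), function(cl) {
      members <- names(fit$assignment)[fit$assignment == cl]
      mu <- colMeans(prof[members, , drop = FALSE])
      names(mu)[which.max(mu)]
    }, character(1))
    lab <- paste0(
      toupper(substr(g, 1, 1)),
      tolower(substr(drivers, 1, 1))
    )
    lab <- make.unique(lab, sep = "")
    out[[g]] <- structure(
      list(
        group = g, k = ch$k_best, assignment = fit$assignment,
        cluster_labels = lab, medoids = fit$medoids,
        drivers = drivers, index = ch$index
      ),
      class = "enterotype_result"
    )
  }
  out
}
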