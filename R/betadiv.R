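# Between-sample distances (weighted/unweighted UniFrac on the OTU
# phylogeny, Jaccard on presence/absence), classical PCoA, and
# PERMANOVA with pairwise comparisons. UniFrac works on a tip x edge
# incidence of the tree: each edge carries the set of tips below it, so
# per-sample branch "mass" is a single matrix product.

# tips x edges logical incidence: desc[t, e] is TRUE when tip t descends
# from edge e.
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  desc <- matrix(FALSE, nrow = nt, ncol = ne)
  node_tips <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) node_tips[[t]] <- t
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    tips <- node_tips[[child]]
    desc[tips, e] <- TRUE
    node_tips[[parent]] <- c(node_tips[[parent]], tips)
  }
  rownames(desc) <- tree$tip.label
  desc
}

# samples x tips matrix in tree tip order; errors if an occupied OTU is
# not a tip. Tips absent from the table get zero abundance.
align_to_tips <- function(counts, tree) {
  present <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0) {
    stopf("OTU(s) not found as tree tips: %s",
      paste(utils::head(missing, 3), collapse = ", ")
    )
  }
  m <- matrix(0, nrow = nrow(counts), ncol = length(tree$tip.label),
    dimnames = list(rownames(counts), tree$tip.label)
  )
  common <- intersect(colnames(counts), tree$tip.label)
  m[, common] <- counts[, common]
  m
}

finish_dist <- function(d, ids, metric) {
  d[d < 0 & d > -1e-12] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(ids, ids)
  attr(d, "metric") <- metric
  d
}

#' Unweighted UniFrac distance matrix
#'
#' For each sample pair, the fraction of branch length unique to one
#' sample's set of occupied tips, out of the branch length in either set.
#' Presence means count >= 1.
#'
#' @param counts samples x OTUs matrix.
#' @param tree rooted `phylo` tree whose tips cover all occupied OTUs.
#' @return symmetric distance matrix with attribute `metric`.
#' @export
unweighted_unifrac <- function(counts, tree) {
  counts <- validate_otu_counts(counts)
  tipm <- align_to_tips(counts, tree)
  desc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  pres <- (tipm > 0) * 1
  occ <- (pres %*% desc) > 0        # samples x edges: any tip below?
  s_len <- (occ * 1) %*% (len)      # branch length occupied per sample
  shared <- (occ * 1) %*% (len * t(occ * 1)) # pairwise shared branch length
  tot <- as.vector(s_len)
  union <- outer(tot, tot, "+") - shared
  d <- (union - shared) / ifelse(union > 0, union, 1)
  finish_dist(d, rownames(counts), "unweighted_unifrac")
}

#' Weighted UniFrac distance matrix
#'
#' Raw value: sum over branches of `length * |A - B|`, where `A` and `B`
#' are the fractions of each sample's reads descending from the branch.
#' The normalized variant (default) divides by `sum(length * (A + B))`,
#' bounding the distance in [0, 1].
#'
#' @param counts samples x OTUs matrix.
#' @param tree rooted `phylo` tree.
#' @param normalized logical; divide by the standard normalization sum.
#' @return symmetric distance matrix.
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  counts <- validate_otu_counts(counts)
  tipm <- align_to_tips(counts, tree)
  totals <- rowSums(tipm)
  if (any(totals == 0)) stop("all-zero sample in table", call. = FALSE)
  rel <- tipm / totals
  desc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  aw <- rel %*% desc                 # samples x edges: mass below branch
  n <- nrow(aw)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    diffs <- abs(aw[rest, , drop = FALSE] -
      matrix(aw[i, ], nrow = length(rest), ncol = ncol(aw), byrow = TRUE))
    raw <- as.vector(diffs %*% len)
    if (normalized) {
      sums <- as.vector((aw[rest, , drop = FALSE] +
        matrix(aw[i, ], nrow = length(rest), ncol = ncol(aw),
          byrow = TRUE
        )) %*% len)
      raw <- raw / ifelse(sums > 0, sums, 1)
    }
    d[i, rest] <- raw
    d[rest, i] <- raw
  }
  finish_dist(d, rownames(counts),
    if (normalized) "weighted_unifrac_normalized" else "weighted_unifrac"
  )
}

#' Jaccard distance matrix on presence/absence
#'
#' `1 - |A intersect B| / |A union B|` over detected-OTU sets; two empty
#' samples are at distance 0.
#'
#' @param counts samples x OTUs matrix.
#' @return symmetric distance matrix.
#' @export
jaccard_distance <- function(counts) {
  counts <- validate_otu_counts(counts)
  pres <- (counts > 0) * 1
  inter <- pres %*% t(pres)
  sizes <- rowSums(pres)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / ifelse(union > 0, union, 1)
  d[union == 0] <- 0
  finish_dist(d, rownames(counts), "jaccard")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns coordinates
#' from the positive eigenpairs in descending order. Negative eigenvalues
#' are reported, not corrected; explained variance fractions are over
#' positive eigenvalues only.
#'
#' @param d symmetric distance matrix.
#' @return list with `coordinates` (samples x axes), `explained`
#'   (fractions summing to 1), `eigenvalues` (all, descending).
#' @export
pcoa_classic <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > max(tol, 1e-12))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  rownames(coords) <- rownames(d)
  if (length(pos) > 0) {
    colnames(coords) <- paste0("PCo", seq_along(pos))
  }
  list(
    coordinates = coords,
    explained = if (length(pos) > 0) e$values[pos] / sum(e$values[pos]) else numeric(0),
    eigenvalues = e$values
  )
}

permanova_f <- function(d2, groups, n, a) {
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssa <- sst - ssw
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  c(f = f, r2 = ssa / sst)
}

#' PERMANOVA (one-way, Anderson's pseudo-F) on a distance matrix
#'
#' Pseudo-F from total and within-group sums of squared distances;
#' significance by seeded label permutation,
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix.
#' @param labels grouping factor (>= 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed or `NULL`.
#' @param permutations optional matrix of permuted orderings (rows), e.g.
#'   an exhaustive enumeration; overrides `n_perm`.
#' @return object of class `permanova`: `f`, `r_squared`, `p_value`, `df`,
#'   `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` must have one entry per sample", call. = FALSE)
  }
  a <- length(unique(labels))
  if (a < 2) stop("PERMANOVA needs at least two groups", call. = FALSE)
  d2 <- d^2
  obs <- permanova_f(d2, labels, n, a)
  if (!is.null(permutations)) {
    fs <- apply(permutations, 1, function(ord) {
      permanova_f(d2, labels[ord], n, a)["f"]
    })
    n_perm <- nrow(permutations)
  } else {
    fs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        permanova_f(d2, labels[sample.int(n)], n, a)["f"]
      }, numeric(1))
    })
  }
  p <- (1 + sum(fs >= obs["f"] - 1e-12)) / (1 + n_perm)
  structure(
    list(
      f = unname(obs["f"]), r_squared = unname(obs["r2"]), p_value = p,
      df = c(a - 1, n - a), n_perm = n_perm
    ),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: F_%d,%d = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$df[1], x$df[2], x$f, x$r_squared, x$p_value, x$n_perm
  ))
  invisible(x)
}

# Compact letter display via insert-and-absorb: groups sharing a letter
# are not significantly different.
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[k]
    b <- sig_pairs$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' Pairwise PERMANOVA with multiplicity correction and letter display
#'
#' One PERMANOVA per unordered group pair on the corresponding submatrix;
#' p-values adjusted by `p_adjust_method`; compact letters assigned so
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param d symmetric distance matrix.
#' @param labels grouping factor.
#' @param n_perm permutations per pair.
#' @param seed integer seed or `NULL` (per-pair seeds derived).
#' @param p_adjust_method passed to [stats::p.adjust()] (default `"BH"`).
#' @param alpha significance level for the letter display.
#' @return list with `pairs` (data.frame: group1, group2, f, r_squared,
#'   p_value, p_adjusted) and `letters` (named character).
#' @export
pairwise_permanova <- function(d, labels, n_perm = 999, seed = NULL,
                               p_adjust_method = "BH", alpha = 0.05) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  combs <- utils::combn(groups, 2)
  rows <- vector("list", ncol(combs))
  for (k in seq_len(ncol(combs))) {
    g1 <- combs[1, k]
    g2 <- combs[2, k]
    idx <- which(labels %in% c(g1, g2))
    res <- permanova(d[idx, idx, drop = FALSE], labels[idx],
      n_perm = n_perm, seed = child_seed(seed, k)
    )
    rows[[k]] <- data.frame(
      group1 = g1, group2 = g2, f = res$f, r_squared = res$r_squared,
      p_value = res$p_value, stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- stats::p.adjust(pairs$p_value, method = p_adjust_method)
  sig <- pairs[pairs$p_adjusted < alpha, c("group1", "group2")]
  list(pairs = pairs, letters = compact_letters(groups, sig))
}
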