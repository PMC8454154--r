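# Alpha diversity and hierarchical additive diversity partitioning.
# Total (gamma) Shannon diversity is decomposed into mean within-sample
# alpha plus one beta component per hierarchy level; the components sum to
# gamma exactly by construction (telescoping means of pooled communities).

#' Shannon diversity of a count vector (or per row of a matrix)
#'
#' `H = -sum(p_i * log(p_i))` over positive entries, `p = counts / total`.
#'
#' @param counts non-negative numeric vector, or a samples x OTUs matrix
#'   (computed per row).
#' @param base logarithm base (default natural log).
#' @return a number, or a named vector for matrix input.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (is.matrix(counts)) {
    return(apply(counts, 1, shannon_index, base = base))
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("all-zero sample has no Shannon diversity", call. = FALSE)
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Number of observed OTUs (count >= 1)
#'
#' @param counts numeric vector or samples x OTUs matrix.
#' @return integer, or named integer vector for matrix input.
#' @export
observed_species <- function(counts) {
  if (is.matrix(counts)) {
    return(apply(counts, 1, observed_species))
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  sum(counts >= 1)
}

pooled_mean_shannon <- function(counts, labels, base) {
  pooled <- rowsum(counts, labels)
  mean(shannon_index(pooled, base = base))
}

#' Additive hierarchical partitioning of Shannon diversity
#'
#' Decomposes gamma (Shannon of the fully pooled community) into alpha
#' (mean per-sample Shannon) plus one beta per hierarchy level: the beta at
#' level l is the mean Shannon of communities pooled at level l minus the
#' mean at level l-1, and the top beta is gamma minus the mean at the
#' coarsest level. Additivity `alpha + sum(beta) = gamma` is exact.
#'
#' Significance is assessed by permuting the sample-to-group assignment
#' (all hierarchy columns jointly reshuffled across samples, preserving
#' group sizes) and recomputing each beta; `p = (1 + #{beta* >= beta}) /
#' (1 + n_perm)`. Alpha is invariant under label permutation, so its p is
#' reported as `NA`.
#'
#' @param counts samples x OTUs matrix.
#' @param metadata data.frame with `sample_id` and the hierarchy fields.
#' @param hierarchy character vector of metadata fields, ordered fine to
#'   coarse (e.g. `c("sample_type")` or `c("site", "landuse")`).
#' @param base log base for Shannon (default natural log).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed or `NULL`.
#' @param scheme optional label for the partition scheme.
#' @return object of class `diversity_partition`: data.frame `levels`
#'   (level, component, percent, p_value), `gamma`, `n_perm`.
#' @export
additive_partition <- function(counts, metadata, hierarchy,
                               base = exp(1), n_perm = 999, seed = NULL,
                               scheme = paste(hierarchy, collapse = "/")) {
  counts <- validate_otu_counts(counts)
  missing_f <- setdiff(hierarchy, names(metadata))
  if (length(missing_f) > 0) {
    stopf("hierarchy field(s) not in metadata: %s",
      paste(missing_f, collapse = ", ")
    )
  }
  idx <- match(rownames(counts), metadata$sample_id)
  if (anyNA(idx)) {
    stopf("sample(s) missing from metadata: %s",
      paste(rownames(counts)[is.na(idx)][1], collapse = ", ")
    )
  }
  labels <- lapply(hierarchy, function(f) {
    v <- metadata[[f]][idx]
    if (anyNA(v)) {
      stopf("sample '%s' unassigned at level '%s'",
        rownames(counts)[which(is.na(v))[1]], f
      )
    }
    as.character(v)
  })
  names(labels) <- hierarchy
  n_lev <- length(hierarchy)

  level_means <- function(labs) {
    # mean pooled Shannon at each hierarchy level, fine to coarse
    vapply(seq_len(n_lev), function(l) {
      pooled_mean_shannon(counts, labs[[l]], base)
    }, numeric(1))
  }

  alpha <- mean(shannon_index(counts, base = base))
  gamma <- shannon_index(colSums(counts), base = base)
  h_obs <- level_means(labels)
  comps <- diff(c(alpha, h_obs, gamma))
  comp_names <- paste0("beta_", seq_len(n_lev + 1))

  p_values <- rep(NA_real_, n_lev + 1)
  if (n_perm > 0) {
    exceed <- integer(n_lev + 1)
    n <- nrow(counts)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        ord <- sample.int(n)
        labs_p <- lapply(labels, function(v) v[ord])
        h_p <- level_means(labs_p)
        comps_p <- diff(c(alpha, h_p, gamma))
        exceed <- exceed + (comps_p >= comps - 1e-12)
      }
    })
    p_values <- (1 + exceed) / (1 + n_perm)
  }

  levels_df <- data.frame(
    level = c("alpha", comp_names, "gamma"),
    grouping = c("sample", hierarchy, "total", "total"),
    component = c(alpha, comps, gamma),
    percent = c(alpha, comps, gamma) / gamma * 100,
    p_value = c(NA_real_, p_values, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(
    list(scheme = scheme, levels = levels_df, alpha = alpha,
      gamma = gamma, n_perm = n_perm),
    class = "diversity_partition"
  )
}

#' @export
print.diversity_partition <- function(x, ...) {
  cat("Additive diversity partition (", x$scheme, ")\n", sep = "")
  df <- x$levels
  df$component <- round(df$component, 4)
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
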