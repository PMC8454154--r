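# Co-occurrence networks of rank-level taxa, with unknown ("dark matter")
# nodes flagged from the taxonomy labels. Association is estimated on
# centered-log-ratio transformed counts (the standard guard against
# compositional spurious correlation) with a fixed |r| threshold; the
# estimator is pluggable. Network roles are probed by deleting the
# unknown nodes and comparing centralities against deleting the same
# number of random nodes (bootstrap null).

#' Aggregate an OTU table to a taxonomic rank
#'
#' Counts are summed per rank label. A node is flagged unknown when its
#' rank label is an unknown marker (case-insensitive, trimmed); unknown
#' nodes are keyed by their deepest identified ancestor so distinct
#' dark-matter lineages remain distinct nodes (see
#' [taxon_label_at_rank()]).
#'
#' @param counts samples x OTUs matrix.
#' @param taxonomy taxonomy data.frame.
#' @param rank `"class"`, `"family"` or `"genus"`.
#' @return list with `counts` (samples x nodes) and `unknown` (named
#'   logical per node).
#' @export
aggregate_to_rank <- function(counts, taxonomy,
                              rank = c("genus", "family", "class")) {
  rank <- match.arg(rank)
  counts <- validate_otu_counts(counts)
  res <- taxon_label_at_rank(colnames(counts), taxonomy, rank,
    unknown_prefix = "unknown_"
  )
  agg <- t(rowsum(t(counts), res$label))
  unknown <- vapply(split(res$unknown, res$label), all, logical(1))
  list(counts = agg, unknown = unknown[colnames(agg)])
}

#' Construct a network model from an adjacency matrix
#'
#' Low-level constructor used by [build_network()] and directly by
#' analyses that study a given graph (e.g. planted perturbation tests).
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal, named.
#' @param unknown named logical vector of dark-matter flags per node.
#' @param weights optional symmetric numeric matrix of edge weights.
#' @param estimator label of the association estimator.
#' @return object of class `network_model`.
#' @export
network_model <- function(adjacency, unknown, weights = NULL,
                          estimator = "given") {
  adjacency <- as.matrix(adjacency) != 0
  if (nrow(adjacency) != ncol(adjacency) ||
    !isTRUE(all(adjacency == t(adjacency)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  diag(adjacency) <- FALSE
  nodes <- rownames(adjacency) %||% sprintf("n%03d", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(nodes, nodes)
  if (is.null(names(unknown))) names(unknown) <- nodes
  structure(
    list(
      nodes = nodes, adjacency = adjacency,
      unknown = unknown[nodes], weights = weights, estimator = estimator
    ),
    class = "network_model"
  )
}

#' Build a co-occurrence network from rank-aggregated counts
#'
#' Default estimator: centered-log-ratio transform per sample (zeros
#' replaced by a pseudocount of 0.5), pairwise Pearson correlation, edge
#' where `|r| >= threshold`. Nodes present in fewer than `min_prevalence`
#' of samples are dropped first. A custom `estimator` function
#' `(counts) -> symmetric association matrix` can be plugged in.
#'
#' @param agg result of [aggregate_to_rank()] (or a list with `counts`
#'   and `unknown`).
#' @param min_prevalence prevalence filter on nodes (default 0.2).
#' @param threshold absolute association threshold for an edge.
#' @param estimator `"clr_pearson"` or a function of the node count
#'   matrix returning an association matrix.
#' @param seed unused by the default estimator; accepted for pluggable
#'   stochastic estimators.
#' @return a `network_model`.
#' @export
build_network <- function(agg, min_prevalence = 0.2, threshold = 0.35,
                          estimator = "clr_pearson", seed = NULL) {
  counts <- agg$counts
  unknown <- agg$unknown
  if (nrow(counts) < 4) stop("need at least 4 samples", call. = FALSE)
  prev <- colMeans(counts > 0)
  keep <- prev >= min_prevalence
  counts <- counts[, keep, drop = FALSE]
  unknown <- unknown[colnames(counts)]
  if (ncol(counts) < 10) {
    stop("fewer than 10 nodes after the prevalence filter", call. = FALSE)
  }
  assoc <- if (is.function(estimator)) {
    with_seed(seed, estimator(counts))
  } else {
    x <- counts
    x[x == 0] <- 0.5
    lx <- log(x)
    clr <- lx - rowMeans(lx)
    stats::cor(clr)
  }
  adj <- abs(assoc) >= threshold
  diag(adj) <- FALSE
  network_model(adj, unknown,
    weights = assoc,
    estimator = if (is.function(estimator)) "custom" else estimator
  )
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency * 1,
    mode = "undirected", diag = FALSE
  )
}

#' Node centralities (degree, betweenness, harmonic closeness)
#'
#' Computed on the binarized graph. Betweenness counts, per node, the
#' (fractional) shortest paths passing through it; closeness is harmonic
#' (finite on disconnected graphs) normalized by n - 1. Isolated nodes
#' score zero on all three.
#'
#' @param net a `network_model`.
#' @return data.frame: `node`, `unknown`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
network_centralities <- function(net) {
  g <- as_igraph(net)
  data.frame(
    node = net$nodes,
    unknown = unname(net$unknown),
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE)),
    closeness = unname(igraph::harmonic_centrality(g, normalized = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Eigenvector hub scores
#'
#' Principal-eigenvector node importance (HITS hub score on an undirected
#' graph), computed by shifted power iteration (`A + I`, which shares
#' eigenvectors with `A` but breaks the +/- eigenvalue tie on bipartite
#' components), tolerance 1e-10, at most 1000 iterations; scores scaled
#' to max 1. An edgeless graph yields all-zero scores with a warning.
#'
#' @param net a `network_model`.
#' @return named numeric vector of hub scores.
#' @export
hub_scores <- function(net) {
  a <- net$adjacency * 1
  n <- nrow(a)
  if (sum(a) == 0) {
    warning("edgeless graph: hub scores are all zero", call. = FALSE)
    return(stats::setNames(numeric(n), net$nodes))
  }
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(1000)) {
    y <- as.vector(a %*% x) + x # (A + I) x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < 1e-10) {
      x <- y
      break
    }
    x <- y
  }
  x <- abs(x)
  stats::setNames(x / max(x), net$nodes)
}

#' Fraction of top-k hub nodes that are unknown taxa
#'
#' Deterministic ranking by hub score, ties broken by node id; `k` is
#' truncated to the node count.
#'
#' @param net a `network_model`.
#' @param k number of top hubs to inspect (default 50).
#' @return fraction in [0, 1].
#' @export
top_hub_unknown_fraction <- function(net, k = 50) {
  scores <- hub_scores(net)
  k <- min(k, length(scores))
  ord <- order(-scores, net$nodes)
  mean(net$unknown[net$nodes[ord[seq_len(k)]]])
}

delete_nodes <- function(net, drop) {
  keep <- setdiff(net$nodes, drop)
  network_model(
    net$adjacency[keep, keep, drop = FALSE],
    net$unknown[keep],
    weights = if (!is.null(net$weights)) {
      net$weights[keep, keep, drop = FALSE]
    },
    estimator = net$estimator
  )
}

#' Compare the network with and without its unknown nodes
#'
#' Builds the Without-Unknown network (all flagged nodes deleted) and `B`
#' Bootstrap networks (the same number of uniformly random nodes deleted),
#' recomputes degree, betweenness and harmonic closeness for each, and
#' reports:
#' * two-sided Wilcoxon rank-sum p-values between each pair of node-value
#'   distributions (Bootstrap values pooled over replicates), with the
#'   direction of the median shift, and
#' * an exchangeable replicate-rank p per metric: the Without-Unknown
#'   mean node value ranked among the B bootstrap replicate means,
#'   `p = 2 * min(r, B + 1 - r) / (B + 1)`. Under random flags the
#'   Without-Unknown network is one more draw from the bootstrap ensemble,
#'   so this p is uniform by construction; it is the calibrated test of
#'   whether unknown nodes matter more than random ones.
#'
#' @param net a `network_model` with at least one unknown node.
#' @param B bootstrap replicates (default 100).
#' @param seed integer seed or `NULL`.
#' @return object of class `perturbation_result`: `distributions` (per
#'   metric: original / without_unknown / bootstrap values),
#'   `wilcoxon` (data.frame comparison x metric with p and direction),
#'   `replicate_rank` (data.frame metric, statistic, p), `B`,
#'   `n_removed`.
#' @export
perturb_and_compare <- function(net, B = 100, seed = NULL) {
  flagged <- net$nodes[net$unknown]
  metrics <- c("degree", "betweenness", "closeness")
  if (length(flagged) == 0) {
    warning("no unknown nodes: nothing to remove", call. = FALSE)
    return(structure(
      list(
        distributions = NULL, wilcoxon = NULL, replicate_rank = NULL,
        B = B, n_removed = 0L, degenerate = TRUE
      ),
      class = "perturbation_result"
    ))
  }
  if (length(flagged) >= length(net$nodes) - 1) {
    stop("cannot remove (almost) all nodes", call. = FALSE)
  }
  orig <- network_centralities(net)
  wout <- network_centralities(delete_nodes(net, flagged))
  k <- length(flagged)
  boot <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      drop <- sample(net$nodes, k)
      network_centralities(delete_nodes(net, drop))
    })
  })
  boot_pooled <- do.call(rbind, boot)

  dists <- lapply(metrics, function(m) {
    list(
      original = orig[[m]], without_unknown = wout[[m]],
      bootstrap = boot_pooled[[m]]
    )
  })
  names(dists) <- metrics

  comparisons <- list(
    original_vs_without = c("original", "without_unknown"),
    original_vs_bootstrap = c("original", "bootstrap"),
    without_vs_bootstrap = c("without_unknown", "bootstrap")
  )
  rows <- list()
  for (m in metrics) {
    for (cn in names(comparisons)) {
      ab <- comparisons[[cn]]
      x <- dists[[m]][[ab[1]]]
      y <- dists[[m]][[ab[2]]]
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      shift <- mean(y) - mean(x) # means: centrality medians tie at zero
      rows[[length(rows) + 1]] <- data.frame(
        comparison = cn, metric = m, p_value = p,
        direction = if (shift > 0) {
          "increase"
        } else if (shift < 0) "decrease" else "none",
        stringsAsFactors = FALSE
      )
    }
  }
  wilcoxon <- do.call(rbind, rows)

  rep_rank <- do.call(rbind, lapply(metrics, function(m) {
    # mean, not median: medians of centrality distributions tie easily
    # (e.g. at zero betweenness), which would void the rank test
    obs <- mean(wout[[m]])
    boots <- vapply(boot, function(b) mean(b[[m]]), numeric(1))
    r_le <- sum(boots <= obs) + 1
    r_ge <- sum(boots >= obs) + 1
    data.frame(
      metric = m, statistic = obs,
      p_value = min(1, 2 * min(r_le, r_ge) / (B + 1)),
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(
      distributions = dists, wilcoxon = wilcoxon,
      replicate_rank = rep_rank, B = B, n_removed = k, degenerate = FALSE
    ),
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Perturbation result: no unknown nodes, nothing removed\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Perturbation: %d unknown node(s) removed, B = %d bootstrap replicates\n",
    x$n_removed, x$B
  ))
  print(x$wilcoxon, row.names = FALSE)
  cat("Replicate-rank test (without-unknown vs bootstrap):\n")
  print(x$replicate_rank, row.names = FALSE)
  invisible(x)
}
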