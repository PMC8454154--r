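# Shared fixtures and independent brute-force oracles. Everything is
# generated in code; no stored data.

# scaled-down synthetic study (seconds, not minutes)
tiny_sim_config <- function(seed = 1, ...) {
  gr <- default_groups()
  gr$n_per_site <- c(2L, 5L, 2L, 2L, 4L, 3L)
  args <- utils::modifyList(
    list(
      n_sites = 2, n_otus_shared = 200, read_depth = 2000,
      groups = gr, n_soil_per_site = 3, seed = seed
    ),
    list(...)
  )
  do.call(sim_config, args)
}

random_counts <- function(n_samples, n_otus, lambda = 5, seed = 1) {
  m <- withr::with_seed(seed, matrix(
    rpois(n_samples * n_otus, lambda),
    n_samples, n_otus,
    dimnames = list(
      sprintf("s%03d", seq_len(n_samples)),
      sprintf("OTU%04d", seq_len(n_otus))
    )
  ))
  storage.mode(m) <- "integer"
  m
}

# all n! orderings of 1:n (for exhaustive permutation oracles, n <= 6)
all_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# independent branch-walk UniFrac oracle: loops over edges, finds the
# tips below each via ape::extract.clade
bf_unifrac <- function(counts, tree, weighted = FALSE, normalized = TRUE) {
  nt <- length(tree$tip.label)
  tips_below <- lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= nt) {
      tree$tip.label[child]
    } else {
      ape::extract.clade(tree, child)$tip.label
    }
  })
  rel <- counts / rowSums(counts)
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- den <- 0
      for (e in seq_along(tips_below)) {
        tb <- intersect(tips_below[[e]], colnames(counts))
        len <- tree$edge.length[e]
        if (weighted) {
          a <- sum(rel[i, tb])
          b <- sum(rel[j, tb])
          num <- num + len * abs(a - b)
          den <- den + len * (a + b)
        } else {
          a <- any(counts[i, tb] > 0)
          b <- any(counts[j, tb] > 0)
          if (xor(a, b)) num <- num + len
          if (a || b) den <- den + len
        }
      }
      d[i, j] <- d[j, i] <- if (weighted && !normalized) {
        num
      } else if (den > 0) num / den else 0
    }
  }
  d
}

# brute-force centralities by BFS path enumeration (n <= 12)
bf_centralities <- function(adj) {
  n <- nrow(adj)
  # all-pairs shortest path lengths and path counts via BFS layers
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    dcur <- 0
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- dcur + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == dcur + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
      dcur <- dcur + 1
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    others <- setdiff(seq_len(n), v)
    sum(1 / dist[v, others][is.finite(dist[v, others])]) / (n - 1)
  }, numeric(1))
  list(degree = rowSums(adj), betweenness = btw, closeness = clo)
}

# Erdos-Renyi adjacency with names
random_adjacency <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
    a <- a + t(a)
    dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    a
  })
}

# modular graph: m cliques joined in a ring through dedicated connector
# nodes (the planted "dark matter" articulation points)
connector_graph <- function(n_modules = 4, module_size = 6) {
  n <- n_modules * module_size + n_modules
  a <- matrix(0L, n, n)
  for (k in seq_len(n_modules)) {
    idx <- ((k - 1) * module_size + 1):(k * module_size)
    a[idx, idx] <- 1L
  }
  diag(a) <- 0L
  connectors <- n_modules * module_size + seq_len(n_modules)
  for (k in seq_len(n_modules)) {
    c1 <- connectors[k]
    m1 <- (k - 1) * module_size + 1
    m2 <- (k %% n_modules) * module_size + 1
    a[c1, m1] <- a[m1, c1] <- 1L
    a[c1, m2] <- a[m2, c1] <- 1L
  }
  nodes <- c(
    sprintf("taxon%02d", seq_len(n_modules * module_size)),
    sprintf("dark%02d", seq_len(n_modules))
  )
  dimnames(a) <- list(nodes, nodes)
  unknown <- grepl("^dark", nodes)
  names(unknown) <- nodes
  list(adjacency = a, unknown = unknown)
}
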