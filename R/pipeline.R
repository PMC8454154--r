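# End-to-end orchestration: simulate (or read) a study, apply the global
# filters, then run the enabled analysis stages in dependency order,
# writing each stage's outputs as TSV/JSON with a manifest. Every stage
# draws its seed deterministically from the global seed, so a rerun with
# the same configuration reproduces every output.

#' Build a pipeline configuration
#'
#' @param sim a [sim_config()] used to generate inputs, or `NULL` when
#'   `input_dir` holds the study files.
#' @param input_dir directory with otu_table.tsv / taxonomy.tsv /
#'   metadata.tsv / tree.nwk (used when `sim` is `NULL`).
#' @param stages character vector of stages to run, a subset of
#'   `c("diversity", "betadiv", "enterotype", "neutral", "trophic",
#'   "unique", "network")`.
#' @param min_total minimum-count OTU filter threshold.
#' @param depth rarefaction depth.
#' @param n_perm permutations for partition and PERMANOVA.
#' @param bin_width trophic bin width (permil).
#' @param network_rank rank for the dark-matter network.
#' @param bootstrap_B bootstrap replicates for the network comparison.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       stages = c(
                         "diversity", "betadiv", "enterotype", "neutral",
                         "trophic", "unique", "network"
                       ),
                       min_total = 100, depth = 13551, n_perm = 999,
                       bin_width = 3.4, network_rank = "genus",
                       bootstrap_B = 100, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(
      sim = sim, input_dir = input_dir, stages = stages,
      min_total = min_total, depth = depth, n_perm = n_perm,
      bin_width = bin_width, network_rank = network_rank,
      bootstrap_B = bootstrap_B, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated or
#' on-disk study; each stage's tables land under `out_dir` and are listed,
#' with their parameters and seeds, in `manifest.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params,
      outputs = as.list(unname(vapply(files, basename, character(1))))
    )
  }

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- child_seed(config$seed, 1)
    study <- simulate_foodweb_dataset(sim)
    paths <- write_foodweb_dataset(study, file.path(out_dir, "inputs"))
    note("simulate", list(seed = sim$seed), paths)
  } else {
    study <- list(
      counts = read_otu_table(file.path(config$input_dir, "otu_table.tsv")),
      taxonomy = read_taxonomy(file.path(config$input_dir, "taxonomy.tsv")),
      metadata = read_sample_metadata(
        file.path(config$input_dir, "metadata.tsv")
      ),
      tree = read_otu_tree(file.path(config$input_dir, "tree.nwk")),
      truth = NULL
    )
  }

  filtered <- filter_low_count_otus(study$counts, config$min_total)
  rar <- rarefy_table(filtered, config$depth, seed = child_seed(config$seed, 2))
  counts <- rar$table
  if (nrow(counts) == 0) {
    stop("rarefaction depth exceeds every sample's post-filter read total",
      call. = FALSE
    )
  }
  meta <- study$metadata[study$metadata$sample_id %in% rownames(counts), ]
  f <- write_tsv(
    data.frame(discarded = rar$discarded_sample_ids),
    file.path(out_dir, "rarefaction_discarded.tsv")
  )
  note("filter_rarefy",
    list(min_total = config$min_total, depth = config$depth,
      seed = child_seed(config$seed, 2)),
    f
  )

  results <- list(study = study, counts = counts, metadata = meta,
    discarded = rar$discarded_sample_ids)

  if ("diversity" %in% config$stages) {
    alpha <- data.frame(
      sample_id = rownames(counts),
      shannon = shannon_index(counts),
      observed = observed_species(counts)
    )
    part <- additive_partition(counts, meta, "sample_type",
      n_perm = config$n_perm, seed = child_seed(config$seed, 3)
    )
    results$alpha <- alpha
    results$partition <- part
    files <- c(
      write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv")),
      write_tsv(part$levels, file.path(out_dir, "diversity_partition.tsv"))
    )
    note("diversity", list(n_perm = config$n_perm), files)
  }

  if ("betadiv" %in% config$stages) {
    dw <- weighted_unifrac(counts, study$tree)
    pc <- pcoa_classic(dw)
    pv <- permanova(dw, meta$sample_type[match(rownames(counts),
      meta$sample_id)],
      n_perm = config$n_perm, seed = child_seed(config$seed, 4)
    )
    results$betadiv <- list(distance = dw, pcoa = pc, permanova = pv)
    files <- c(
      write_tsv(
        data.frame(sample_id = rownames(counts),
          pc$coordinates[, seq_len(min(2, ncol(pc$coordinates))),
            drop = FALSE
          ]
        ),
        file.path(out_dir, "pcoa_weighted_unifrac.tsv")
      ),
      write_tsv(
        data.frame(f = pv$f, r_squared = pv$r_squared, p = pv$p_value),
        file.path(out_dir, "permanova.tsv")
      )
    )
    note("betadiv", list(n_perm = config$n_perm), files)
  }

  if ("enterotype" %in% config$stages) {
    et <- enterotype_groups(counts, study$taxonomy, meta,
      seed = child_seed(config$seed, 5)
    )
    results$enterotype <- et
    df <- do.call(rbind, lapply(et, function(e) {
      data.frame(
        sample_id = names(e$assignment), group = e$group,
        cluster = e$cluster_labels[e$assignment],
        stringsAsFactors = FALSE
      )
    }))
    files <- write_tsv(df, file.path(out_dir, "enterotypes.tsv"))
    note("enterotype", list(), files)
  }

  if ("neutral" %in% config$stages) {
    fits <- fit_sloan_by_group(counts, meta)
    results$neutral <- fits
    df <- do.call(rbind, lapply(names(fits), function(g) {
      f <- fits[[g]]
      data.frame(
        group = g, m = f$m, Nm = f$Nm, r_squared = f$r_squared,
        aic_neutral = f$aic_neutral, aic_binomial = f$aic_binomial,
        frac_within = f$fractions["within"],
        frac_above = f$fractions["above"],
        frac_below = f$fractions["below"],
        stringsAsFactors = FALSE
      )
    }))
    files <- write_tsv(df, file.path(out_dir, "neutral_fits.tsv"))
    note("neutral", list(), files)
  }

  if ("trophic" %in% config$stages) {
    tl <- trophic_assignments(meta, bin_width = config$bin_width)
    results$trophic <- tl
    files <- write_tsv(tl, file.path(out_dir, "trophic_levels.tsv"))
    if (!is.null(results$alpha)) {
      idx <- match(tl$sample_id, results$alpha$sample_id)
      reg <- regress_vs_trophic(tl$delta15N_adjusted,
        results$alpha$shannon[idx]
      )
      results$trophic_regression <- reg
      files <- c(files, write_tsv(
        data.frame(
          slope = reg$slope, intercept = reg$intercept,
          r_squared = reg$r_squared, p = reg$p_value, n = reg$n
        ),
        file.path(out_dir, "diversity_vs_delta15N.tsv")
      ))
    }
    note("trophic", list(bin_width = config$bin_width), files)
  }

  if ("unique" %in% config$stages) {
    rep_u <- unique_otus(counts, meta)
    results$unique <- rep_u
    df <- data.frame(
      group = rep(names(rep_u$per_group),
        vapply(rep_u$per_group, length, integer(1))
      ),
      otu_id = unlist(rep_u$per_group, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    files <- write_tsv(df, file.path(out_dir, "unique_taxa.tsv"))
    if (!is.null(results$trophic)) {
      tlv <- stats::setNames(
        results$trophic$trophic_level,
        results$trophic$sample_id
      )
      ul <- unique_counts_by_level(rep_u, counts, tlv)
      results$unique_by_level <- ul
      files <- c(files, write_tsv(ul$per_sample,
        file.path(out_dir, "unique_counts_per_sample.tsv")
      ))
    }
    note("unique", list(), files)
  }

  if ("network" %in% config$stages) {
    agg <- aggregate_to_rank(counts, study$taxonomy, config$network_rank)
    net <- build_network(agg)
    cent <- network_centralities(net)
    cent$hub_score <- unname(hub_scores(net))
    pert <- perturb_and_compare(net,
      B = config$bootstrap_B,
      seed = child_seed(config$seed, 6)
    )
    results$network <- list(net = net, centralities = cent,
      perturbation = pert)
    files <- c(
      write_tsv(cent, file.path(out_dir, "network_nodes.tsv")),
      if (!isTRUE(pert$degenerate)) {
        write_tsv(pert$wilcoxon, file.path(out_dir, "network_comparison.tsv"))
      }
    )
    note("network",
      list(rank = config$network_rank, B = config$bootstrap_B,
        seed = child_seed(config$seed, 6)),
      files
    )
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  results$manifest <- manifest
  invisible(results)
}
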