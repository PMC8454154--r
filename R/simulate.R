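# Synthetic study generator. Emulates the field design end-to-end: six
# faunal groups plus soil sampled at several sites under two landuses, a
# shared soil source pool assembled neutrally (Dirichlet-multinomial with
# group-specific Nm), planted group-unique OTUs whose number grows with
# trophic level, planted genus-level enterotypes, a delta-15N gradient with
# 3.4 permil steps, a configurable fraction of dark-matter labels, and a
# birth-death OTU phylogeny. Every planted feature is returned as ground
# truth so downstream stages can be tested against a known answer.

#' Default simulated faunal groups
#'
#' Trophic levels, migration (Nm) and planted-unique-OTU counts for the six
#' faunal groups. Trophic ranks follow the food-web ordering used in the
#' study system (soil/litter feeders low, predatory mites on top); Nm
#' defaults follow the per-group ordering reported for these hosts; the
#' planted unique-OTU counts are nondecreasing in trophic level so the
#' downstream uniqueness-vs-trophic-level regression has a known sign.
#'
#' @return data.frame with columns `group`, `trophic_level`, `Nm`,
#'   `n_unique`, `n_per_site`, `k_enterotypes`.
#' @export
default_groups <- function() {
  data.frame(
    group = c(
      "earthworm", "collembolan", "potworm", "nematode",
      "oribatid_mite", "predatory_mite"
    ),
    trophic_level = c(1L, 2L, 2L, 3L, 4L, 5L),
    Nm = c(1802, 4026, 999, 667, 1369, 2103),
    n_unique = c(20L, 25L, 35L, 50L, 65L, 80L),
    n_per_site = c(4L, 20L, 5L, 5L, 12L, 10L),
    k_enterotypes = c(2L, 2L, 3L, 2L, 3L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Defaults mirror the study conditions: 6 sites x {farmland, forest},
#' per-group sample sizes close to the field design, read depth 13,551,
#' delta-15N noise sd 0.8 permil against a 3.4 permil trophic step.
#'
#' @param n_sites number of sampling sites.
#' @param landuses character vector of landuse types.
#' @param groups data.frame as in [default_groups()]; `n_per_site` is per
#'   site x landuse.
#' @param n_soil_per_site soil samples per site x landuse.
#' @param n_otus_shared size of the shared soil source pool.
#' @param read_depth reads per sample.
#' @param Nm_soil migration parameter for soil samples.
#' @param delta15N_sd Gaussian noise sd on adjusted delta-15N (permil).
#' @param trophic_step delta-15N enrichment per trophic transfer (permil).
#' @param unknown_label_fraction fraction of OTUs relabelled as unknown at
#'   the class and genus ranks.
#' @param unique_read_fraction share of a faunal sample's reads coming from
#'   its group's planted unique OTUs.
#' @param enterotype_strength share of reads given to a cluster's driver
#'   genus (enterotype separation).
#' @param group_tilt_sd lognormal sd of the per-group host-filtering tilt
#'   applied to the shared pool.
#' @param otus_per_genus average OTUs per synthetic genus.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 6,
                       landuses = c("farmland", "forest"),
                       groups = default_groups(),
                       n_soil_per_site = 5,
                       n_otus_shared = 800,
                       read_depth = 13551,
                       Nm_soil = 3000,
                       delta15N_sd = 0.8,
                       trophic_step = 3.4,
                       unknown_label_fraction = 0.3,
                       unique_read_fraction = 0.15,
                       enterotype_strength = 0.35,
                       group_tilt_sd = 0.6,
                       otus_per_genus = 4,
                       seed = 1) {
  stopifnot(
    n_sites >= 1, length(landuses) >= 1, n_soil_per_site >= 1,
    n_otus_shared >= 2, read_depth >= 1, Nm_soil > 0,
    delta15N_sd >= 0, trophic_step > 0,
    unique_read_fraction >= 0, unique_read_fraction < 1,
    enterotype_strength >= 0, enterotype_strength < 1,
    group_tilt_sd >= 0, otus_per_genus >= 1
  )
  if (unknown_label_fraction < 0 || unknown_label_fraction > 1) {
    stop("`unknown_label_fraction` must be in [0, 1]", call. = FALSE)
  }
  need <- c(
    "group", "trophic_level", "Nm", "n_unique", "n_per_site",
    "k_enterotypes"
  )
  if (!is.data.frame(groups) || !all(need %in% names(groups))) {
    stopf("`groups` must contain columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(groups$group)) {
    stop("group names must be unique", call. = FALSE)
  }
  if (any(groups$Nm <= 0)) stop("Nm must be positive", call. = FALSE)
  if (any(groups$n_unique < 0) || any(groups$n_per_site < 1)) {
    stop("counts in `groups` must be non-negative", call. = FALSE)
  }
  # monotone design: higher trophic level never gets fewer unique OTUs
  o <- order(groups$trophic_level)
  if (is.unsorted(groups$n_unique[o])) {
    stop("`n_unique` must be nondecreasing in trophic level", call. = FALSE)
  }
  structure(
    list(
      n_sites = as.integer(n_sites), landuses = landuses, groups = groups,
      n_soil_per_site = as.integer(n_soil_per_site),
      n_otus_shared = as.integer(n_otus_shared),
      read_depth = as.integer(read_depth), Nm_soil = Nm_soil,
      delta15N_sd = delta15N_sd, trophic_step = trophic_step,
      unknown_label_fraction = unknown_label_fraction,
      unique_read_fraction = unique_read_fraction,
      enterotype_strength = enterotype_strength,
      group_tilt_sd = group_tilt_sd,
      otus_per_genus = otus_per_genus,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a regional source-pool rank-abundance vector
#'
#' Lognormal rank-abundance shape mixed with a small uniform floor so that
#' every pool member has non-negligible relative abundance (the floor keeps
#' rare pool taxa detectable in a realistic number of soil samples, which
#' is what makes host-unique taxa identifiable by soil exclusion).
#'
#' @param n_otus pool size (>= 2).
#' @param seed integer seed or `NULL`.
#' @param sdlog lognormal sd on the log scale.
#' @param floor_weight mixing weight of the uniform floor.
#' @return strictly positive numeric vector summing to 1.
#' @export
simulate_source_pool <- function(n_otus, seed = NULL, sdlog = 1.5,
                                 floor_weight = 0.1) {
  if (!is.numeric(n_otus) || length(n_otus) != 1 || n_otus < 2) {
    stop("`n_otus` must be a single integer >= 2", call. = FALSE)
  }
  n_otus <- as.integer(n_otus)
  p <- with_seed(seed, stats::rlnorm(n_otus, meanlog = 0, sdlog = sdlog))
  p <- sort(p, decreasing = TRUE)
  p <- p / sum(p)
  p <- (1 - floor_weight) * p + floor_weight / n_otus
  p / sum(p)
}

#' Simulate neutrally assembled communities
#'
#' Generative counterpart of the Sloan neutral community model: for each
#' sample, latent relative abundances are drawn from a Dirichlet with
#' concentration `N * m * pool` and counts from a multinomial of size `N`.
#' This is exactly the distributional assumption under which the
#' beta-approximation used by [fit_sloan()] is correct, which makes
#' parameter recovery a fair test of the fit.
#'
#' @param pool source-pool relative abundances (positive, sums to 1).
#' @param N reads per sample (community size).
#' @param m migration probability in (0, 1].
#' @param n_samples number of samples.
#' @param seed integer seed or `NULL`.
#' @return integer matrix, samples x OTUs.
#' @export
simulate_neutral_community <- function(pool, N, m, n_samples, seed = NULL) {
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m > 1) {
    stop("`m` must be in (0, 1]", call. = FALSE)
  }
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  stopifnot(all(pool > 0), abs(sum(pool) - 1) < 1e-6, n_samples >= 0)
  k <- length(pool)
  ids <- names(pool) %||% sprintf("OTU%04d", seq_len(k))
  out <- with_seed(seed, {
    m_counts <- matrix(0L, nrow = n_samples, ncol = k)
    alpha <- N * m * pool
    for (i in seq_len(n_samples)) {
      lat <- stats::rgamma(k, shape = alpha)
      s <- sum(lat)
      if (s == 0) lat <- pool else lat <- lat / s
      m_counts[i, ] <- stats::rmultinom(1, size = N, prob = lat)[, 1]
    }
    m_counts
  })
  dimnames(out) <- list(
    if (n_samples > 0) sprintf("S%04d", seq_len(n_samples)) else NULL,
    ids
  )
  out
}

rank_labels_for <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))

# Build a synthetic 7-rank taxonomy over the given OTU ids. Genera hold
# `per_genus` OTUs on average and nest deterministically into
# family/order/class/phylum.
synthesize_taxonomy <- function(otu_ids, per_genus) {
  n <- length(otu_ids)
  n_gen <- max(1L, ceiling(n / per_genus))
  genus_of <- rep(seq_len(n_gen), length.out = n)
  genus <- rank_labels_for(n_gen, "g")
  family <- rank_labels_for(max(1L, ceiling(n_gen / 3)), "f")
  order_ <- rank_labels_for(max(1L, ceiling(n_gen / 9)), "o")
  class_ <- rank_labels_for(max(1L, ceiling(n_gen / 18)), "c")
  phylum <- rank_labels_for(max(1L, ceiling(n_gen / 36)), "p")
  fam_of <- rep(seq_along(family), length.out = n_gen)
  ord_of <- rep(seq_along(order_), length.out = length(family))
  cls_of <- rep(seq_along(class_), length.out = length(order_))
  phy_of <- rep(seq_along(phylum), length.out = length(class_))
  g <- genus_of
  data.frame(
    otu_id = otu_ids,
    kingdom = "Bacteria",
    phylum = phylum[phy_of[cls_of[ord_of[fam_of[g]]]]],
    class = class_[cls_of[ord_of[fam_of[g]]]],
    order = order_[ord_of[fam_of[g]]],
    family = family[fam_of[g]],
    genus = genus[g],
    species = paste0(genus[g], "_sp_", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete food-web microbiome study
#'
#' Generates the five study artifacts (counts, taxonomy, metadata, tree,
#' delta-15N) plus the planted ground truth. Soil samples are drawn
#' neutrally from the shared source pool; each faunal group is drawn from a
#' group-tilted pool (host filtering) with its planted unique OTUs mixed in
#' at a fixed read share, so unique OTUs have exactly zero reads in every
#' soil sample by construction. Genus-level enterotypes are planted by
#' boosting one driver genus per cluster. Adjusted delta-15N per faunal
#' sample is `(TL - 1) * trophic_step + noise`; raw values add the site's
#' litter signature back.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts`, `taxonomy`, `metadata`, `tree`,
#'   `truth` (per-group unique OTU sets, per-sample trophic level and
#'   enterotype, per-group Nm, unknown OTU ids, source pool).
#' @export
simulate_foodweb_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()", call. = FALSE)
  }
  cfg <- config
  with_seed(cfg$seed, {
    gr <- cfg$groups
    n_shared <- cfg$n_otus_shared
    shared_ids <- sprintf("OTU_S%04d", seq_len(n_shared))
    unique_ids <- list()
    for (i in seq_len(nrow(gr))) {
      g <- gr$group[i]
      unique_ids[[g]] <- if (gr$n_unique[i] > 0) {
        sprintf("OTU_U_%s_%03d", g, seq_len(gr$n_unique[i]))
      } else {
        character(0)
      }
    }
    all_ids <- c(shared_ids, unlist(unique_ids, use.names = FALSE))
    n_all <- length(all_ids)

    pool <- simulate_source_pool(n_shared)
    names(pool) <- shared_ids

    # taxonomy + dark-matter labels at class and genus ranks
    tax <- synthesize_taxonomy(all_ids, cfg$otus_per_genus)
    n_unknown <- round(cfg$unknown_label_fraction * n_all)
    unknown_otus <- if (n_unknown > 0) sample(all_ids, n_unknown) else character(0)
    if (n_unknown > 0) {
      rows <- match(unknown_otus, tax$otu_id)
      marks <- sample(UNKNOWN_TAXON_MARKERS, n_unknown, replace = TRUE)
      tax$class[rows] <- marks
      tax$genus[rows] <- marks
      tax$species[rows] <- NA_character_
    }

    # site litter signatures (constant within site)
    sites <- sprintf("site%02d", seq_len(cfg$n_sites))
    litter <- stats::rnorm(cfg$n_sites, mean = 2, sd = 1.5)
    names(litter) <- sites

    # per-group tilted pools and enterotype driver genera
    shared_genus <- tax$genus[match(shared_ids, tax$otu_id)]
    tilted <- list()
    drivers <- list()
    for (i in seq_len(nrow(gr))) {
      g <- gr$group[i]
      tp <- pool * stats::rlnorm(n_shared, 0, cfg$group_tilt_sd)
      tilted[[g]] <- tp / sum(tp)
      cand <- names(sort(table(shared_genus[!is_unknown_label(shared_genus)]),
        decreasing = TRUE
      ))
      drivers[[g]] <- sample(cand, gr$k_enterotypes[i])
    }

    # sample frame
    frames <- list()
    for (s in sites) {
      for (lu in cfg$landuses) {
        frames[[length(frames) + 1]] <- data.frame(
          sample_type = "soil", species = "soil", site = s, landuse = lu,
          n = cfg$n_soil_per_site, stringsAsFactors = FALSE
        )
        for (i in seq_len(nrow(gr))) {
          frames[[length(frames) + 1]] <- data.frame(
            sample_type = gr$group[i],
            species = paste0(gr$group[i], "_sp_", match(s, sites)),
            site = s, landuse = lu, n = gr$n_per_site[i],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    frame <- do.call(rbind, frames)
    frame <- frame[rep(seq_len(nrow(frame)), frame$n), names(frame) != "n"]
    frame$sample_id <- sprintf("samp%04d", seq_len(nrow(frame)))
    rownames(frame) <- frame$sample_id

    counts <- matrix(0L, nrow = nrow(frame), ncol = n_all,
      dimnames = list(frame$sample_id, all_ids)
    )
    truth_tl <- integer(0)
    truth_et <- character(0)
    delta_adj <- rep(NA_real_, nrow(frame))
    names(delta_adj) <- frame$sample_id

    shared_idx <- seq_len(n_shared)
    for (r in seq_len(nrow(frame))) {
      st <- frame$sample_type[r]
      if (st == "soil") {
        lat <- stats::rgamma(n_shared, shape = cfg$Nm_soil * pool)
        lat <- lat / sum(lat)
        counts[r, shared_idx] <-
          stats::rmultinom(1, cfg$read_depth, lat)[, 1]
      } else {
        i <- match(st, gr$group)
        nm <- gr$Nm[i]
        lat <- stats::rgamma(n_shared, shape = nm * tilted[[st]])
        lat <- lat / sum(lat)
        # enterotype: boost driver genus of this sample's cluster
        k <- gr$k_enterotypes[i]
        cl <- sample.int(k, 1)
        drv <- drivers[[st]][cl]
        drv_otus <- shared_idx[shared_genus == drv]
        prob <- (1 - cfg$enterotype_strength - cfg$unique_read_fraction) * lat
        et_part <- numeric(n_shared)
        et_part[drv_otus] <- lat[drv_otus] + 1e-8
        et_part <- et_part / sum(et_part)
        prob <- prob + cfg$enterotype_strength * et_part
        full <- numeric(n_all)
        full[shared_idx] <- prob
        u <- unique_ids[[st]]
        if (length(u) > 0 && cfg$unique_read_fraction > 0) {
          w <- stats::rgamma(length(u), shape = nm / length(u) * 1)
          if (sum(w) == 0) w <- rep(1, length(u))
          full[match(u, all_ids)] <- cfg$unique_read_fraction * w / sum(w)
        }
        full <- full / sum(full)
        counts[r, ] <- stats::rmultinom(1, cfg$read_depth, full)[, 1]
        tl <- gr$trophic_level[i]
        truth_tl[frame$sample_id[r]] <- tl
        truth_et[frame$sample_id[r]] <- paste0(st, "_", cl)
        delta_adj[r] <- (tl - 1) * cfg$trophic_step +
          stats::rnorm(1, 0, cfg$delta15N_sd)
      }
    }

    metadata <- data.frame(
      sample_id = frame$sample_id,
      sample_type = frame$sample_type,
      species = frame$species,
      site = frame$site,
      landuse = frame$landuse,
      delta15N_litter = unname(litter[frame$site]),
      delta15N_animal = ifelse(frame$sample_type == "soil", NA_real_,
        delta_adj + litter[frame$site]
      ),
      stringsAsFactors = FALSE
    )
    rownames(metadata) <- NULL

    tree <- ape::rphylo(n_all, birth = 1, death = 0.4)
    tree$tip.label <- sample(all_ids)

    nm_truth <- gr$Nm
    names(nm_truth) <- gr$group
    list(
      counts = counts,
      taxonomy = tax,
      metadata = metadata,
      tree = tree,
      truth = list(
        unique_otus = unique_ids,
        trophic_level = truth_tl,
        enterotype = truth_et,
        Nm = nm_truth,
        unknown_otus = unknown_otus,
        pool = pool
      )
    )
  })
}

#' Write a simulated study to disk in the package's standard formats
#'
#' @param sim result of [simulate_foodweb_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_foodweb_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "otu_table.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_otu_table(sim$counts, paths["counts"])
  write_taxonomy(sim$taxonomy, paths["taxonomy"])
  write_sample_metadata(sim$metadata, paths["metadata"])
  write_otu_tree(sim$tree, paths["tree"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
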