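# Host-unique taxa: OTUs detected in a faunal group's microbiome but in
# no soil sample (all sites pooled), the prevalence/abundance dominance
# filters, shared-OTU (Venn) bookkeeping, and the unique-taxa-vs-trophic
# -level summary.

#' Identify OTUs unique to faunal microbiomes
#'
#' The soil-detected set is every OTU with at least one read in any soil
#' sample. A group's unique set is every OTU detected in at least one of
#' its samples and absent from the soil-detected set; the exclusion is
#' absolute. Computed on whatever table is passed in (conventionally the
#' post-rarefaction table).
#'
#' @param counts samples x OTUs matrix.
#' @param metadata sample metadata.
#' @param group_field metadata column with the host group.
#' @param soil_label value of `group_field` marking soil samples.
#' @return object of class `unique_taxa_report`: `per_group` (named list
#'   of OTU id sets), `all_unique`, `soil_detected`, `per_sample_counts`
#'   (unique OTUs of the sample's group present in the sample).
#' @export
unique_otus <- function(counts, metadata, group_field = "sample_type",
                        soil_label = "soil") {
  counts <- validate_otu_counts(counts)
  idx <- match(rownames(counts), metadata$sample_id)
  grp <- metadata[[group_field]][idx]
  if (!any(grp == soil_label)) {
    stop("no soil samples in the table", call. = FALSE)
  }
  soil <- counts[grp == soil_label, , drop = FALSE]
  soil_detected <- colnames(counts)[colSums(soil) > 0]
  groups <- setdiff(unique(grp), soil_label)
  per_group <- list()
  per_sample <- stats::setNames(
    integer(sum(grp != soil_label)),
    rownames(counts)[grp != soil_label]
  )
  for (g in groups) {
    sub <- counts[grp == g, , drop = FALSE]
    detected <- colnames(counts)[colSums(sub) > 0]
    uniq <- setdiff(detected, soil_detected)
    per_group[[g]] <- uniq
    if (length(uniq) > 0) {
      per_sample[rownames(sub)] <- rowSums(sub[, uniq, drop = FALSE] > 0)
    }
  }
  structure(
    list(
      per_group = per_group,
      all_unique = sort(unique(unlist(per_group, use.names = FALSE))),
      soil_detected = soil_detected,
      per_sample_counts = per_sample,
      group_of = stats::setNames(grp[grp != soil_label], names(per_sample))
    ),
    class = "unique_taxa_report"
  )
}

#' Dominance filter on maximal relative abundance and prevalence
#'
#' Keeps OTUs whose maximum per-sample relative abundance over the scope
#' strictly exceeds `min_max_rel_abund` AND whose detection prevalence
#' strictly exceeds `min_prevalence` (both strict, per the `>` convention
#' of the thresholds this filter mirrors, e.g. "> 0.3% and found in more
#' than 70% of samples"). The two conditions commute.
#'
#' @param counts samples x OTUs matrix.
#' @param samples scope: sample ids to evaluate over (default all).
#' @param min_max_rel_abund relative-abundance threshold in [0, 1].
#' @param min_prevalence prevalence threshold in [0, 1].
#' @return character vector of OTU ids passing both filters.
#' @export
prevalence_abundance_filter <- function(counts, samples = rownames(counts),
                                        min_max_rel_abund = 0.003,
                                        min_prevalence = 0.70) {
  counts <- validate_otu_counts(counts)
  if (length(samples) == 0) stop("empty sample scope", call. = FALSE)
  if (min_max_rel_abund < 0 || min_max_rel_abund > 1 ||
    min_prevalence < 0 || min_prevalence > 1) {
    stop("thresholds must be in [0, 1]", call. = FALSE)
  }
  sub <- counts[samples, , drop = FALSE]
  rel <- sub / rowSums(sub)
  max_rel <- apply(rel, 2, max)
  prev <- colMeans(sub > 0)
  colnames(sub)[max_rel > min_max_rel_abund & prev > min_prevalence]
}

#' Shared-OTU counts across groups (Venn regions)
#'
#' Counts, for every region of the Venn partition over the groups'
#' detected-OTU sets, the OTUs detected in exactly that combination of
#' groups, plus the fraction detected in all groups.
#'
#' @param counts samples x OTUs matrix.
#' @param metadata sample metadata.
#' @param group_field metadata column defining the sets (2-6 groups).
#' @return list with `regions` (named integer vector; names like
#'   `"a&b"`), `shared_all` (count in every group) and
#'   `shared_all_fraction` (of all detected OTUs).
#' @export
shared_otu_counts <- function(counts, metadata, group_field = "sample_type") {
  counts <- validate_otu_counts(counts)
  idx <- match(rownames(counts), metadata$sample_id)
  grp <- metadata[[group_field]][idx]
  groups <- sort(unique(grp))
  if (length(groups) < 2 || length(groups) > 6) {
    stop("Venn counting supports 2-6 groups", call. = FALSE)
  }
  detected <- vapply(groups, function(g) {
    colSums(counts[grp == g, , drop = FALSE]) > 0
  }, logical(ncol(counts)))
  any_det <- rowSums(detected) > 0
  detected <- detected[any_det, , drop = FALSE]
  key <- apply(detected, 1, function(z) paste(groups[z], collapse = "&"))
  regions <- table(key)
  shared_all <- sum(rowSums(detected) == length(groups))
  list(
    regions = stats::setNames(as.integer(regions), names(regions)),
    shared_all = shared_all,
    shared_all_fraction = shared_all / nrow(detected)
  )
}

#' Unique-taxon counts by trophic level, with trend test
#'
#' Per trophic level: the distinct unique OTUs detected in samples of that
#' level; per sample: the unique-OTU count from the report. The trend is a
#' Spearman rank correlation of per-sample unique counts against trophic
#' level.
#'
#' @param report result of [unique_otus()].
#' @param counts the samples x OTUs matrix the report was computed on.
#' @param trophic_level named integer vector (faunal samples).
#' @return list with `per_level_counts` (distinct unique OTUs per level),
#'   `per_sample` (data.frame sample_id, trophic_level, n_unique) and
#'   `trend` (`rho`, `p_value`).
#' @export
unique_counts_by_level <- function(report, counts, trophic_level) {
  samples <- names(report$per_sample_counts)
  tl <- trophic_level[samples]
  if (anyNA(tl)) {
    stopf("trophic level missing for sample '%s'", samples[is.na(tl)][1])
  }
  lv <- sort(unique(tl))
  per_level <- stats::setNames(integer(length(lv)), paste0("TL", lv))
  for (i in seq_along(lv)) {
    sel <- samples[tl == lv[i]]
    sub <- counts[sel, report$all_unique, drop = FALSE]
    per_level[i] <- sum(colSums(sub) > 0)
  }
  per_sample <- data.frame(
    sample_id = samples, trophic_level = tl,
    n_unique = unname(report$per_sample_counts),
    stringsAsFactors = FALSE
  )
  trend <- suppressWarnings(
    stats::cor.test(per_sample$n_unique, per_sample$trophic_level,
      method = "spearman"
    )
  )
  list(
    per_level_counts = per_level,
    per_sample = per_sample,
    trend = list(rho = unname(trend$estimate), p_value = trend$p.value)
  )
}
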