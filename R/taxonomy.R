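# Rank-label resolution shared by the genus-profile and network modules.

#' Resolve each OTU's label at a taxonomic rank
#'
#' Returns, per OTU, the label at `rank` if identified, or a synthetic
#' label `<unknown_prefix><deepest resolved ancestor rank label>` when the
#' rank label is an unknown marker or the OTU is absent from the taxonomy.
#' Keying unknown taxa by their most specific identified ancestor keeps
#' distinct dark-matter lineages distinct instead of collapsing every
#' "uncultured" into a single unit.
#'
#' @param otu_ids character vector.
#' @param taxonomy taxonomy data.frame (`otu_id` + the seven ranks).
#' @param rank one of [TAXONOMY_RANKS].
#' @param unknown_prefix prefix for unresolved labels.
#' @return data.frame with columns `otu_id`, `label`, `unknown` (logical).
#' @export
taxon_label_at_rank <- function(otu_ids, taxonomy, rank,
                                unknown_prefix = "unclassified_") {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  ridx <- match(rank, TAXONOMY_RANKS)
  row <- match(otu_ids, taxonomy$otu_id)
  lab <- character(length(otu_ids))
  unk <- logical(length(otu_ids))
  for (i in seq_along(otu_ids)) {
    if (is.na(row[i])) {
      lab[i] <- paste0(unknown_prefix, "unknown")
      unk[i] <- TRUE
      next
    }
    lineage <- as.character(taxonomy[row[i], TAXONOMY_RANKS[seq_len(ridx)]])
    target <- lineage[ridx]
    if (!is_unknown_label(target)) {
      lab[i] <- target
    } else {
      resolved <- lineage[!is_unknown_label(lineage)]
      anc <- if (length(resolved) > 0) resolved[length(resolved)] else "unknown"
      lab[i] <- paste0(unknown_prefix, anc)
      unk[i] <- TRUE
    }
  }
  data.frame(otu_id = otu_ids, label = lab, unknown = unk,
    stringsAsFactors = FALSE
  )
}
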