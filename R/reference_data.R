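# Published summary values from the continental-scale soil food-web
# microbiome survey whose design the synthetic generator emulates. They
# are inputs for bookkeeping and worked-example checks (partition
# additivity, sample accounting, trophic binning), not quantities this
# package computes from sequence data.

#' Reference hierarchical diversity partition components
#'
#' The published Shannon partition components (and their percentages of
#' gamma) for the survey's six alternative hierarchy schemes; scheme 1 is
#' the unstructured total (gamma) alone. Used to check that the printed
#' components reproduce the printed total under exact additivity.
#'
#' @return named list: `gamma`, and per scheme a numeric vector of
#'   components (alpha first, then the beta levels) plus the printed
#'   percentages.
#' @export
ref_partition_schemes <- function() {
  list(
    gamma = 7.72,
    schemes = list(
      individuals_and_groups = list(
        components = c(alpha = 5.15, beta1 = 1.75, beta2 = 0.82),
        percent = c(66.7, 22.7, 10.6)
      ),
      individuals_and_sites = list(
        components = c(alpha = 5.15, beta1 = 1.94, beta2 = 0.63),
        percent = c(66.7, 25.1, 8.2)
      ),
      individuals_and_landuse = list(
        components = c(alpha = 5.15, beta1 = 2.48, beta2 = 0.09),
        percent = c(66.7, 32.1, 1.2)
      ),
      individuals_and_trophic_levels = list(
        components = c(alpha = 5.15, beta1 = 2.18, beta2 = 0.39),
        percent = c(66.7, 28.2, 5.1)
      ),
      individuals_sites_landuse = list(
        components = c(alpha = 5.15, beta1 = 1.95, beta2 = 0.53,
          beta3 = 0.09
        ),
        percent = c(66.7, 25.2, 6.9, 1.2)
      )
    )
  )
}

#' Reference per-group sample counts
#'
#' Published sample counts per host group and soil, before rarefaction,
#' with the number of samples the rarefaction step discarded and the
#' published total retained for analysis.
#'
#' @return list with `per_group` (named integer vector),
#'   `n_discarded_by_rarefaction`, `total_analyzed`.
#' @export
ref_sample_counts <- function() {
  list(
    per_group = c(
      collembolan = 238L, nematode = 60L, potworm = 62L,
      oribatid_mite = 146L, predatory_mite = 122L, earthworm = 50L,
      soil = 60L
    ),
    n_discarded_by_rarefaction = 8L,
    total_analyzed = 730L
  )
}

#' Reference adjusted delta-15N range and trophic structure
#'
#' The published range of litter-adjusted delta-15N across all faunal
#' samples, the per-transfer enrichment step, and the number of trophic
#' levels the survey reports.
#'
#' @return list with `range` (permil), `bin_width`, `n_levels`.
#' @export
ref_delta15N_range <- function() {
  list(range = c(-0.25, 16.79), bin_width = 3.4, n_levels = 5L)
}
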