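---
title: "Methods: linking soil food-web position to the host microbiome"
author: "trophoweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking soil food-web position to the host microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trophoweb implements the computational chain by which a soil
invertebrate's position in the food web — measured by nitrogen stable
isotopes — is linked to the diversity, uniqueness, assembly regime and
network structure of its microbiome. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made
where more than one defensible option existed.

## The study design the package models

The unit of observation is a pooled-individual 16S sample: a community of
one invertebrate species from one site, or a bulk soil sample. Six
functional groups of soil fauna (collembolans, nematodes, potworms,
earthworms, oribatid mites, predatory mites) plus soil are sampled at
several sites under two landuses (farmland, forest). All analyses run on
a sample x OTU count table after two global filters:

* OTUs with fewer than 100 reads summed over all samples are removed
  (`filter_low_count_otus()`), and
* every sample is rarefied to a common read depth, discarding samples
  that fall short (`rarefy_table()`, subsampling without replacement —
  the convention of the upstream tooling; the scheme is seeded and
  reproducible).

The filter precedes rarefaction, so the rarefaction depth must sit below
the post-filter read totals; `run_pipeline()` stops with an explicit
error when it does not. Everywhere downstream, "detected" means count >=
1 in the post-rarefaction table.

## Trophic levels from delta-15N

Animal tissue is enriched in ^15^N by roughly 3.4 permil per trophic
transfer. `delta15N()` converts isotope ratios to the per-mil delta
notation against atmospheric N~2~; `adjust_delta15N()` subtracts each
site's plant-litter value so positions are comparable across sites;
`assign_trophic_levels()` bins the adjusted values into integer levels of
width 3.4 permil.

Bins are anchored at the observed minimum, because the canonical
worked example — an adjusted range of −0.25 to 16.79 permil — yields
exactly five levels only under range-anchored binning, with the 0.04
permil overshoot at the top absorbed by a near-boundary tolerance of
`0.05 * bin_width`. Two consequences are worth knowing:

* the number of levels is data-driven (`ceiling((range − tol)/width)`),
  so noise in the extremes can add a sparsely populated top level; when
  the food-web depth is known (as for the synthetic generator's ground
  truth), pass `max_levels` explicitly;
* the anchor is a sample minimum. In small datasets it is poorly
  determined and all bin boundaries shift with it; recovery of known
  levels is reliable at the sample sizes of the emulated design
  (hundreds of faunal samples) but degrades in small subsets. Values
  beyond the top bin clamp to `max_levels` rather than opening new
  levels.

Trophic-gradient relationships (`regress_vs_trophic()`) use the
continuous adjusted delta-15N as predictor — integer levels are for
grouped summaries only.

## Diversity and its additive partition

`shannon_index()` uses natural logarithms by default; the base is a
parameter because conventions differ across toolchains and the choice
rescales, but never reorders, every comparison in the package.

`additive_partition()` decomposes gamma (Shannon of the pooled
community) into mean within-sample alpha plus one beta per hierarchy
level, each beta being the difference between mean pooled Shannon at
consecutive levels. Additivity is exact by construction (telescoping
sums), and the suite asserts it at 1e-9.

Significance uses sample-to-group label permutation: the hierarchy
columns are reshuffled jointly across samples, preserving group sizes,
and each beta is recomputed (`p = (1 + #{beta* >= beta})/(1 + n_perm)`).
This is the assumption-light null consistent with the individual-based
framing; it is *not* a count-matrix randomization, which answers a
different question (randomizing reads rather than individuals). Alpha is
invariant under label permutation, so no p-value is reported for it.

## Phylogenetic beta diversity, PCoA, PERMANOVA

`unweighted_unifrac()` and `weighted_unifrac()` work on a tip x edge
incidence of the rooted OTU tree: the unweighted form is the fraction of
branch length unique to one sample's occupied tip set; the weighted form
sums `length * |A − B|` over branches, where A and B are the fractions of
reads descending from the branch. The weighted default is the normalized
variant (divided by `sum(length * (A + B))`, bounded in [0, 1]) because
the bounded form is comparable across sample pairs of different depth
profiles; the raw form is a flag away. Both implementations are checked
against independent per-branch brute-force oracles and against a second
independent implementation at 1e-12.

`pcoa_classic()` is classical scaling: eigendecomposition of the
double-centered squared distances. Negative eigenvalues (non-Euclidean
distances) are reported but excluded from the explained-variance
denominator and never corrected silently.

`permanova()` implements the one-way pseudo-F from total and within-group
sums of squared distances, with seeded label permutation. It matches
`vegan::adonis2` on the statistic and an exhaustive enumeration of all
relabelings on small instances. `pairwise_permanova()` adjusts per-pair
p-values (Benjamini-Hochberg by default; configurable) and assigns a
compact letter display by the insert-and-absorb algorithm.

## Enterotyping

Within each host group — never across groups — genus-level relative
abundance profiles (`genus_profiles()`; OTUs with unidentified genus pool
under `unclassified_<deepest resolved rank>`) are compared by the
Jensen-Shannon distance (`jsd_matrix()`, log base 2, square root, so
distances lie in [0, 1]) and clustered by PAM (`cluster::pam`,
BUILD + SWAP, deterministic). The cluster number maximizes the
Calinski-Harabasz index computed from the distance matrix over k = 2..10
(`choose_k()`), the criterion of the classic enterotyping protocol; mean
silhouette width is reported alongside for inspection. Groups too small
to populate all their clusters can legitimately return a smaller k.

## Neutral community model

The Sloan model predicts an OTU's occurrence frequency across samples
from its mean relative abundance p, assuming a source pool, equivalent
migration m into local communities of size N (reads per sample after
rarefaction, so `Nm = depth * m`), and equivalent birth/death. The
stationary local abundance is Beta(Nm·p, Nm·(1−p)).

`fit_sloan()` fits m by bounded 1-D least squares of predicted to
observed occurrence. Two prediction conventions are provided:

* **exact** (default): occupancy is one minus the beta-binomial
  probability of zero reads, `1 − B(a, b+N)/B(a, b)` — the exact
  detection probability when counts are multinomial draws from the beta
  stationary abundance;
* **threshold**: `1 − BetaCDF(d; a, b)` with detection limit `d = 1/N`,
  the convention of the widely used occurrence-fit implementations.

The threshold form under-predicts detection (a taxon just below 1/N is
still detected with probability about 1 − 1/e), which inflates fitted m
by roughly 20–30 percent on data whose sampling layer is multinomial; on
communities generated by `simulate_neutral_community()` the exact form
recovers Nm to within a few percent while the threshold form misses by
about a quarter. The exact form is therefore the default; the threshold
form remains available for comparability with the published convention.

OTUs are classified against a 95 percent Wilson score band (stable at
extreme frequencies) around the fitted prediction: `above`, `within`,
`below`. Note the band's nominal coverage is consumed partly by
estimation error in p (estimated from the same samples), so even on
perfectly neutral data the `within` fraction sits around 0.8–0.9 rather
than 0.95. Model adequacy is summarized by `AIC = n·log(SSE/n) + 2k`
with k = 1 against a binomial random-sampling null
(`f = 1 − (1 − p)^N`, k = 0); SSE is floored at 1e-12 so a perfect fit
stays finite. Each group is fitted on its own samples only.

## Host-unique taxa and dominance filters

`unique_otus()` applies an absolute soil-exclusion rule: an OTU is unique
to a faunal group if it is detected in at least one of the group's
samples and in **no** soil sample, all sites pooled. One soil read
anywhere disqualifies the OTU. `prevalence_abundance_filter()` applies
the dominance thresholds (maximum per-sample relative abundance and
detection prevalence, both strict `>`, per the conventions the thresholds
quote, e.g. "> 0.3 % and found in more than 70 % of samples"); the two
conditions commute. `shared_otu_counts()` produces Venn-region counts for
2–6 detected-OTU sets, and `unique_counts_by_level()` tests the
unique-count-vs-trophic-level trend by Spearman rank correlation.

## Dark-matter network analysis

Labels matching the unknown-marker set (`UNKNOWN_TAXON_MARKERS`:
"unknown", "unassigned", "ambiguous taxa", "uncultured", "uncultured
bacterium", "NA"; case-insensitive, underscores equal spaces) flag a
taxon as microbial dark matter at that rank. When aggregating to a rank
(`aggregate_to_rank()`), unknown taxa are keyed by their deepest
identified ancestor (`unknown_<family>` etc.), so distinct dark-matter
lineages remain distinct network nodes instead of collapsing into a
single "uncultured" node — collapsing would destroy exactly the
hub-structure questions the analysis asks.

`build_network()` estimates associations on centered-log-ratio
transformed counts (pseudocount 0.5 on zeros) with Pearson correlation
and a fixed |r| >= 0.35 edge threshold, after a 20 percent prevalence
filter. The estimator sits behind a pluggable interface (any function
from a count matrix to an association matrix), because the downstream
perturbation comparison is estimator-agnostic; a sparse inverse
covariance estimator can be swapped in without touching the rest.

Centralities are computed on the binarized graph: degree, shortest-path
betweenness, and **harmonic** closeness normalized by n − 1 — harmonic
because node deletion disconnects graphs and classical closeness is
undefined there. Hub scores are the principal eigenvector of the
adjacency (power iteration on A + I, which has the same eigenvectors but
cannot oscillate on bipartite components; tolerance 1e-10), scaled to a
maximum of 1.

`perturb_and_compare()` contrasts three ensembles: Original,
Without-Unknown (all flagged nodes deleted), and Bootstrap (B replicates
deleting the same number of uniformly random nodes). Two kinds of
p-values are reported:

* pooled two-sided Wilcoxon rank-sum tests between each pair of node-value
  distributions per metric, with the direction of the mean shift — the
  comparison style of the methodology this module follows;
* a replicate-rank p per metric: the Without-Unknown mean node value
  ranked among the B bootstrap replicate means,
  `p = 2·min(r, B+1−r)/(B+1)`. Under random flags the Without-Unknown
  network is one more draw from the bootstrap ensemble, so this p is
  uniform by construction. The pooled Wilcoxon is not calibratable
  against the Original network (a node-deleted network differs from the
  full one by construction, and pooling B correlated replicates inflates
  the rank-sum sample size), so calibration claims use the
  replicate-rank test; the mean is used as the summary statistic because
  medians of centrality distributions tie easily (e.g. at zero
  betweenness), which would void the rank test.

## The synthetic-data generator

`simulate_foodweb_dataset()` produces a complete study — counts,
taxonomy, metadata, tree, delta-15N — with every planted feature returned
as ground truth. Its defaults are the emulated design: 6 sites x
{farmland, forest}, per-group sample sizes close to the field design
(about 730 samples), read depth 13,551, and per-group Nm set to the
ordering reported for these hosts (collembolan 4026 > predatory mite
2103 > earthworm 1802 > oribatid mite 1369 > potworm 999 > nematode 667).

Key constructions:

* **Source pool**: lognormal rank-abundance (sdlog 1.5) mixed with a 10
  percent uniform floor. The floor keeps every pool member abundant
  enough (>= ~1e-4) that 60 soil samples at full depth detect it with
  near certainty — without it, rare pool taxa undetected in soil would
  masquerade as host-unique and exact ground-truth recovery would be
  impossible by construction rather than by method failure.
* **Neutral assembly**: per sample, latent relative abundances are drawn
  from Dirichlet(Nm x pool) and counts from a multinomial — exactly the
  distributional assumption under which the Sloan beta prediction is
  correct, which makes parameter recovery a fair test rather than a
  tautology or an unfair one.
* **Host filtering**: each group's pool is tilted by a fixed lognormal
  factor (sd 0.6), planting determinism the neutral fit should flag when
  environments are mixed.
* **Unique taxa**: each group's unique OTUs receive a fixed 15 percent
  read share in that group's samples and exactly zero probability in
  soil — soil exclusion is a hard guarantee. Counts are nondecreasing in
  trophic level (20..80), so the uniqueness-vs-trophic-level regression
  has a known positive sign.
* **Enterotypes**: within each group, samples are assigned to k clusters
  (2 or 3, as reported per group) and one driver genus per cluster
  receives a 35 percent read share — separation strong enough that
  JSD + PAM recovers the planted partition (ARI >= 0.9 at study scale).
* **delta-15N**: adjusted value = (TL − 1) x 3.4 + Gaussian noise
  (sd 0.8 permil — small against the 3.4 bin so planted levels are
  recoverable, but large enough that boundary misassignment occurs);
  raw values add back a per-site litter signature.
* **Dark matter**: a configurable fraction (default 30 percent) of OTUs
  get unknown markers at the class and genus ranks.
* **Tree**: a seeded birth–death phylogeny (`ape::rphylo`, birth 1,
  death 0.4) over all OTUs with random tip assignment.

What the generator does **not** emulate: sequencing error, chimeras, PCR
and copy-number bias, compositional correlations between planted
features, seasonal or spatial autocorrelation, and phylogenetic signal
in group association (tips are assigned at random, so UniFrac structure
reflects abundance, not planted phylogeny). Passing the recovery suites
therefore demonstrates that the implementations answer correctly when
their assumptions hold; it does not certify performance on real
sequencing data.

## Problem sizes and runtime choices

The analysis scripts under `analysis/` run the generator at its
study-scale defaults (about 730 samples, 1075 OTUs, depth 13,551;
rarefaction at 13,000 so the min-count filter leaves room) and complete
in about a minute on one CPU. The test suite uses scaled-down studies
(2 sites, 200 shared OTUs, depth 2,000) for module tests, and the
study-scale generator where a property depends on the design's sample
sizes (trophic-level recovery, exact unique recovery). Calibration
properties use 200 null replicates with 19 permutations (PERMANOVA) or
B = 39 bootstrap replicates (networks), the smallest sizes at which a
0.05-level rejection is expressible exactly. Permutation defaults in the
user-facing functions are 999.

## Known limitations

* The neutral fit's above/within/below classification inherits the
  band-coverage caveat above; its fractions are descriptive, not exact
  error rates.
* Range-anchored trophic binning is sensitive to the sample minimum in
  small datasets (see above).
* The CLR + Pearson network is a deliberately simple association
  estimator; edge-level inference (sparsity selection, confidence) is
  out of scope, and conclusions should rest on the perturbation
  comparison, which is estimator-agnostic.
* Enterotype cluster labels (group initial + driver-genus initial) are
  mnemonic, not stable identifiers across reruns with different seeds.
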