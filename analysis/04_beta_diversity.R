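#!/usr/bin/env Rscript
# Community structure between samples: weighted and unweighted UniFrac,
# PCoA ordination, PERMANOVA across host groups and pairwise group
# comparisons with a compact letter display.

suppressMessages(library(trophoweb))

counts <- read_otu_table("results/rarefied_table.tsv")
meta <- read_sample_metadata("results/study/metadata.tsv")
tree <- read_otu_tree("results/study/tree.nwk")
groups <- meta$sample_type[match(rownames(counts), meta$sample_id)]

for (metric in c("weighted", "unweighted")) {
  d <- if (metric == "weighted") {
    weighted_unifrac(counts, tree)
  } else {
    unweighted_unifrac(counts, tree)
  }
  pc <- pcoa_classic(d)
  pv <- permanova(d, groups, n_perm = 999, seed = 4)
  cat(sprintf(
    "%s UniFrac: PCo1 %.1f%%, PCo2 %.1f%%; PERMANOVA F_%d,%d = %.1f, R2 = %.2f, p = %.3g\n",
    metric, 100 * pc$explained[1], 100 * pc$explained[2],
    pv$df[1], pv$df[2], pv$f, pv$r_squared, pv$p_value
  ))
  coords <- data.frame(
    sample_id = rownames(counts), group = groups,
    pc$coordinates[, 1:2]
  )
  write.table(coords, sprintf("results/pcoa_%s_unifrac.tsv", metric),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

pw <- pairwise_permanova(weighted_unifrac(counts, tree), groups,
  n_perm = 199, seed = 5
)
write.table(pw$pairs, "results/pairwise_permanova.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat("Group letters (groups sharing a letter are not distinguishable):\n")
print(pw$letters)
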