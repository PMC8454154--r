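#!/usr/bin/env Rscript
# Global filtering: drop OTUs with fewer than 100 reads across all
# samples, then rarefy every sample to a common depth, discarding samples
# that fall short (the same two rules the field applies before analysis).

suppressMessages(library(trophoweb))

counts <- read_otu_table("results/study/otu_table.tsv")
# just under the simulated read depth: the min-count OTU filter removes a
# few reads from every sample, so the depth must sit below the post-filter
# totals for samples to survive
depth <- 13000

filtered <- filter_low_count_otus(counts, min_total = 100)
rar <- rarefy_table(filtered, depth = depth, seed = 2)
write_otu_table(rar$table, "results/rarefied_table.tsv")

cat(sprintf(
  "Min-count filter: %d -> %d OTUs; rarefied to %d reads, %d of %d samples kept\n",
  ncol(counts), ncol(filtered), depth, nrow(rar$table), nrow(counts)
))
if (length(rar$discarded_sample_ids) > 0) {
  cat("  discarded:", paste(rar$discarded_sample_ids, collapse = ", "), "\n")
}
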