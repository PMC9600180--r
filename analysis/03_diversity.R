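#!/usr/bin/env Rscript
# Per-group Shannon diversity and pairwise log response ratios against the
# initial samples, with t-test contrasts between taxon groups per treatment.
library(rarestab)

tab <- read_otu_table("results/data/otu_counts.tsv",
                      "results/data/metadata.tsv")
div_all <- NULL
for (soil in c("NCF", "NOF")) {
  sub <- subset_samples(tab, tab$metadata$soil == soil)
  rel <- relative_abundance(sub)
  a <- classify_taxa(subset_samples(rel, rel$metadata$timepoint == "initial"),
                     soil = soil)
  for (g in c("abundant", "common", "rare"))
    div_all <- rbind(div_all, shannon(sub, a, g))
}
write.table(div_all, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

lrr <- do.call(rbind, lapply(split(div_all, div_all$group),
                             log_response_ratio))
rownames(lrr) <- NULL
write.table(lrr, "results/lrr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# rare-vs-abundant LRR contrast per treatment (unpaired t test)
for (tr in c("DR", "FL", "FR", "HE")) {
  x <- lrr$lrr[lrr$treatment == tr & lrr$group == "rare"]
  y <- lrr$lrr[lrr$treatment == tr & lrr$group == "abundant"]
  tt <- t.test(x, y)
  message(sprintf("%s: mean LRR rare %+0.3f vs abundant %+0.3f (t test p = %.2g)",
                  tr, mean(x), mean(y), tt$p.value))
}
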