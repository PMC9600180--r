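#!/usr/bin/env Rscript
# Generate the synthetic mesocosm data set used by the downstream analyses:
# two fertilization-regime soils (NCF, NOF), five disturbance treatments,
# initial + four recovery timepoints, four replicates per cell.
library(rarestab)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- community_config(seed = 11)
ini <- generate_initial_community(cfg)
tab <- simulate_disturbance_series(ini, default_scenarios(), cfg)

write_otu_table(tab, file.path(out_dir, "otu_counts.tsv"),
                file.path(out_dir, "metadata.tsv"))

message(sprintf("simulated %d OTUs x %d samples at depth %d (seed %d)",
                nrow(tab$counts), ncol(tab$counts), cfg$depth, cfg$seed))
message(sprintf("%d invading OTU ids injected by FL/HE scenarios",
                sum(grepl("^NEW_", rownames(tab$counts)))))
message("wrote ", out_dir, "/otu_counts.tsv and metadata.tsv")
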