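#!/usr/bin/env Rscript
# Stage 3: lysogenic / lytic classification from marker annotations and
# per-sample lifestyle proportions (RPKM-weighted and count-weighted).

suppressPackageStartupMessages(library(soilvirome))

features <- read.delim("results/sim/features.tsv", stringsAsFactors = FALSE)
markers <- read.delim("results/sim/markers.tsv", stringsAsFactors = FALSE)
counts_df <- read.delim("results/sim/counts.tsv", check.names = FALSE,
                        stringsAsFactors = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$contig_id

calls <- classify_lifestyle(features$contig_id, markers)
lengths <- setNames(features$length, features$contig_id)
ab <- rpkm(counts, lengths)
prop_ab <- lifestyle_proportions(calls, ab, weighting = "abundance")
prop_ct <- lifestyle_proportions(calls, ab, weighting = "count")

write.table(calls, "results/lifestyle.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(prop_ab, "results/lifestyle_proportions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("lifestyle: %d lysogenic, %d potential lytic (%.1f%% lytic by count)\n",
            sum(calls$call == "lysogenic"), sum(calls$call == "lytic"),
            100 * mean(calls$call == "lytic")))
cat(sprintf("abundance-weighted lytic share across samples: %.1f-%.1f%%\n",
            100 * min(prop_ab$frac_lytic), 100 * max(prop_ab$frac_lytic)))
cat(sprintf("count-weighted lysogenic fraction: %.3f\n",
            mean(prop_ct$frac_lysogenic)))
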