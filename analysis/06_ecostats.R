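#!/usr/bin/env Rscript
# Stage 6: community and microcosm statistics. RPKM abundances, Shannon
# diversity, Bray-Curtis distances, ANOSIM over treatments, a Mantel test,
# the chemistry correlation network, cumulative CO2 and qCO2 with group
# comparisons. Optional argument: an integer seed (default 1) controlling
# the permutation streams.

suppressPackageStartupMessages(library(soilvirome))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

features <- read.delim("results/sim/features.tsv", stringsAsFactors = FALSE)
metadata <- read.delim("results/sim/metadata.tsv", stringsAsFactors = FALSE)
counts_df <- read.delim("results/sim/counts.tsv", check.names = FALSE,
                        stringsAsFactors = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$contig_id

ab <- rpkm(counts, setNames(features$length, features$contig_id))
alpha <- shannon_diversity(ab)
bc <- bray_curtis(ab)
groups <- metadata$treatment[match(colnames(ab), metadata$sample_id)]

an <- anosim_test(bc, groups, nperm = 999, seed = seed)
mt <- mantel_test(bc, bray_curtis(counts), nperm = 999, seed = seed + 1L)

write.table(data.frame(contig_id = rownames(ab), round(ab, 6),
                       check.names = FALSE),
            "results/rpkm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(alpha, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
bm <- as.matrix(bc)
write.table(data.frame(sample_id = rownames(bm), round(bm, 10),
                       check.names = FALSE),
            "results/braycurtis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(anosim = list(R = an$statistic, p = an$p.value),
                          mantel = list(r = mt$statistic, p = mt$p.value)),
                     "results/permutation_tests.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("alpha diversity: Shannon %.3f-%.3f across %d samples\n",
            min(alpha$shannon), max(alpha$shannon), nrow(alpha)))
cat(sprintf("ANOSIM over treatments: R = %.3f, p = %.3g (999 perms)\n",
            an$statistic, an$p.value))
cat(sprintf("Mantel RPKM vs counts: r = %.3f, p = %.3g\n",
            mt$statistic, mt$p.value))

## microcosm: cumulative CO2, qCO2, virus-addition effects
series <- read.delim("results/sim/microcosm.tsv", stringsAsFactors = FALSE)
endpoint <- read.delim("results/sim/microcosm_endpoint.tsv",
                       stringsAsFactors = FALSE)
summ <- do.call(rbind, lapply(split(series, series$microcosm_id), function(s) {
  s <- s[order(s$day), ]
  traj <- cumulative_co2(s$co2_interval, s$day)
  data.frame(microcosm_id = s$microcosm_id[1],
             cumulative_total = traj[length(traj)],
             duration = max(s$day), stringsAsFactors = FALSE)
}))
idx <- match(summ$microcosm_id, endpoint$microcosm_id)
summ$virus <- endpoint$virus[idx]
summ$treatment <- endpoint$treatment[idx]
summ$mbc <- endpoint$mbc[idx]
summ$qco2 <- qco2(summ$cumulative_total, summ$mbc, summ$duration)
write.table(summ, "results/microcosm_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

an_q <- group_compare(summ$qco2, summ$treatment)
cat(sprintf("qCO2 ANOVA across treatments: F = %.2f, p = %.3g; letters: %s\n",
            an_q$statistic, an_q$p.value,
            paste(names(an_q$letters), an_q$letters, sep = "=",
                  collapse = " ")))
for (tr in c("T1", "T2", "T3", "T4")) {
  sel <- summ$treatment == tr
  tt <- group_compare(summ$qco2[sel], summ$virus[sel], method = "ttest")
  cat(sprintf("  %s virus addition vs none: t = %.2f, p = %.3f\n",
              tr, tt$statistic, tt$p.value))
}

chem <- endpoint[, c("mbc", "doc", "suva254", "bg", "nag")]
chem$qco2 <- summ$qco2[match(endpoint$microcosm_id, summ$microcosm_id)]
net <- corr_network(as.matrix(chem), r_threshold = 0.7, q_threshold = 0.01)
write.table(net$edges, "results/chemistry_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("chemistry network: %d of %d pairs kept (|r| > 0.7, BH q < 0.01)\n",
            nrow(net$edges), nrow(net$all_pairs)))
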