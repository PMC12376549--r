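#!/usr/bin/env Rscript
# Stage 5: auxiliary metabolic genes. Applies the score/flag retention rule,
# categorizes retained AMGs into KEGG level-2 and CAZyme classes, and
# Z-score-normalizes abundances across treatments.

suppressPackageStartupMessages(library(soilvirome))

amgs <- read.delim("results/sim/amgs.tsv", stringsAsFactors = FALSE,
                   na.strings = "")
amgs$flags[is.na(amgs$flags)] <- ""
amgs$cazyme_family[is.na(amgs$cazyme_family)] <- ""
amgs$kegg_level2[is.na(amgs$kegg_level2)] <- ""

retained <- filter_amgs(amgs)
cats <- categorize_amgs(retained)
ab_cols <- grep("^abundance_", names(retained), value = TRUE)
z <- zscore_by_treatment(as.matrix(retained[, ab_cols]))
rownames(z) <- retained$gene_id

write.table(retained, "results/amgs_retained.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cats, "results/amg_categories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = rownames(z), round(z, 6),
                       check.names = FALSE),
            "results/amg_zscores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("AMGs: %d candidates -> %d retained (score 1-3, M/F flag, no disqualifier)\n",
            nrow(amgs), nrow(retained)))
caz <- cats[cats$scheme == "cazyme", ]
if (nrow(caz)) {
  cat("CAZyme classes:",
      paste(sprintf("%s=%d", caz$category, caz$n_genes), collapse = ", "),
      "\n")
}
cat(sprintf("Z-scores: %d genes x %d treatments (row means %.1e)\n",
            nrow(z), ncol(z), max(abs(rowMeans(z)))))
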