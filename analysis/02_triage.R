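#!/usr/bin/env Rscript
# Stage 2: viral-contig triage. Reads the simulated feature table and
# contigs, applies the primary screen, the tripartite criteria, the > 5 kb
# rule and 95%-identity clustering, and writes verdicts plus the retained
# representative contigs.

suppressPackageStartupMessages(library(soilvirome))

features <- read.delim("results/sim/features.tsv", stringsAsFactors = FALSE)
seqs <- read_fasta("results/sim/contigs.fna")

verdicts <- run_triage(features, seqs)
write.table(verdicts, "results/verdicts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(seqs[verdicts$contig_id[verdicts$retained]],
            "results/retained.fna")

cat(sprintf("screened %d contigs: %d passed primary, %d passed criteria 1+2,",
            nrow(verdicts), sum(verdicts$passed_primary),
            sum(verdicts$passed_criterion1 & verdicts$passed_criterion2)))
cat(sprintf(" %d advanced (with >5 kb rule)\n", sum(verdicts$advanced)))
cat(sprintf("clustering: %d clusters, %d representatives retained\n",
            length(unique(na.omit(verdicts$cluster_id))),
            sum(verdicts$retained)))
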