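#!/usr/bin/env Rscript
# Stage 4: virus-host prediction by the three evidence channels (CRISPR
# spacers, tRNA matches, genomic homology), merged with per-virus host-range
# classes.

suppressPackageStartupMessages(library(soilvirome))

features <- read.delim("results/sim/features.tsv", stringsAsFactors = FALSE)
seqs <- read_fasta("results/sim/contigs.fna")
viral <- seqs[features$contig_id]
spacers <- read.delim("results/sim/spacers.tsv", stringsAsFactors = FALSE)
trnas <- read.delim("results/sim/trnas.tsv", stringsAsFactors = FALSE)
o6 <- read_outfmt6("results/sim/homhits.tsv")

sp <- match_spacers(spacers, viral)
tr <- match_trnas(trnas, viral)
hom <- filter_homology_hits(
  outfmt6_to_hits(o6, setNames(features$length, features$contig_id)))
merged <- merge_links(list(sp, tr, hom))

write.table(rbind(sp, tr, hom), "results/links_by_channel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(merged$links, "results/links.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(merged$host_range, "results/host_range.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("links: %d spacer, %d tRNA, %d homology -> %d unique virus-host pairs\n",
            nrow(sp), nrow(tr), nrow(hom), nrow(merged$links)))
cat(sprintf("host range: %d specialist, %d generalist viruses\n",
            sum(merged$host_range$range_class == "specialist"),
            sum(merged$host_range$range_class == "generalist")))
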