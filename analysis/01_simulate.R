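#!/usr/bin/env Rscript
# Stage 1: generate the synthetic soil-virome community and its microcosm
# incubation, with planted ground truth, and write all flat files under
# results/sim/. Optional argument: an integer seed (default 1).

suppressPackageStartupMessages(library(soilvirome))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- synth_config(seed = seed)
sim <- generate_community(cfg)
counts <- generate_counts(sim$truth, depth = cfg$read_depth, seed = seed)
write_community(sim, "results/sim", counts = counts)

micro <- generate_microcosm(cfg)
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
write.table(micro$series, "results/sim/microcosm.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(micro$endpoint, "results/sim/microcosm_endpoint.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- sim$truth$contigs
cat(sprintf("community: %d viral candidates (%d planted to survive triage),",
            cfg$n_viral_contigs, sum(tr$should_advance)),
    sprintf("%d hosts\n", cfg$n_host_contigs))
cat(sprintf("planted: %d lysogenic contigs, %d link plants (%d should pass),",
            sum(tr$is_lysogenic), nrow(sim$truth$links),
            sum(sim$truth$links$should_pass)),
    sprintf("%d AMG candidates (%d retainable)\n",
            nrow(sim$amgs), sum(sim$truth$amgs$retained)))
cat(sprintf("samples: %d in %d treatments at depth %g; microcosms: %d\n",
            cfg$n_samples, cfg$n_treatments, cfg$read_depth,
            length(unique(micro$series$microcosm_id))))
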