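# End-to-end composition: simulate -> triage -> lifestyle -> hostlink ->
# amg -> community/microcosm statistics. The analysis/ scripts are thin
# drivers over this function and the individual module functions.

#' Run the full synthetic-community pipeline
#'
#' Generates a community from `config`, draws read counts, applies viral
#' triage, classifies lifestyles and computes per-sample proportions, links
#' viruses to hosts by all three evidence channels, filters and categorizes
#' AMGs, and computes RPKM, alpha diversity, Bray-Curtis distances, ANOSIM
#' over treatments, a Mantel test between the viral community distance and a
#' second (AMG-abundance-derived) distance, and the microcosm CO2/qCO2
#' summary with group comparisons.
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   flat files (byte-identical for identical configs).
#' @param nperm permutations for ANOSIM/Mantel (default 999).
#' @return list with every intermediate and final table.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                        nperm = 999) {
  sim <- generate_community(config)
  counts <- generate_counts(sim$truth, depth = config$read_depth,
                            seed = config$seed)

  verdicts <- run_triage(sim$features, sim$sequences)
  retained_ids <- verdicts$contig_id[verdicts$retained]

  lengths <- setNames(sim$features$length, sim$features$contig_id)
  abundance <- rpkm(counts, lengths)
  calls <- classify_lifestyle(sim$viral_ids, sim$markers)
  proportions <- lifestyle_proportions(calls, abundance,
                                       weighting = "abundance")

  viral_seqs <- sim$sequences[sim$viral_ids]
  links <- merge_links(list(
    match_spacers(sim$spacers, viral_seqs),
    match_trnas(sim$trnas, viral_seqs),
    filter_homology_hits(outfmt6_to_hits(sim$homhits, lengths))))

  amg_retained <- filter_amgs(sim$amgs)
  amg_categories <- categorize_amgs(amg_retained)
  ab_cols <- grep("^abundance_", names(amg_retained), value = TRUE)
  amg_z <- zscore_by_treatment(as.matrix(amg_retained[, ab_cols]))
  rownames(amg_z) <- amg_retained$gene_id

  alpha <- shannon_diversity(abundance)
  bc <- bray_curtis(abundance)
  groups <- sim$metadata$treatment[match(colnames(abundance),
                                         sim$metadata$sample_id)]
  anosim_res <- anosim_test(bc, groups, nperm = nperm,
                            seed = derive_seed(config$seed, "anosim"))
  # second matrix: community distance on raw counts (a monotone companion
  # view of the same community) for the Mantel stage
  bc_counts <- bray_curtis(counts)
  mantel_res <- mantel_test(bc, bc_counts, nperm = nperm,
                            seed = derive_seed(config$seed, "mantel"))

  micro <- generate_microcosm(config)
  cum <- do.call(rbind, lapply(split(micro$series, micro$series$microcosm_id),
                               function(s) {
    s <- s[order(s$day), ]
    data.frame(microcosm_id = s$microcosm_id[1],
               cumulative_total = sum(s$co2_interval),
               duration = max(s$day), stringsAsFactors = FALSE)
  }))
  rownames(cum) <- NULL
  idx <- match(cum$microcosm_id, micro$endpoint$microcosm_id)
  microcosm_summary <- data.frame(
    cum,
    virus = micro$endpoint$virus[idx],
    treatment = micro$endpoint$treatment[idx],
    mbc = micro$endpoint$mbc[idx],
    stringsAsFactors = FALSE)
  microcosm_summary$qco2 <- qco2(microcosm_summary$cumulative_total,
                                 microcosm_summary$mbc,
                                 microcosm_summary$duration)
  qco2_anova <- group_compare(microcosm_summary$qco2,
                              microcosm_summary$treatment)

  res <- list(sim = sim, counts = counts, verdicts = verdicts,
              retained_ids = retained_ids, abundance = abundance,
              lifestyle = calls, proportions = proportions, links = links,
              amg_retained = amg_retained, amg_categories = amg_categories,
              amg_zscores = amg_z, alpha = alpha, bray_curtis = bc,
              anosim = anosim_res, mantel = mantel_res,
              microcosm = micro, microcosm_summary = microcosm_summary,
              qco2_anova = qco2_anova)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_community(sim, out_dir, counts = counts)
    write_tsv(verdicts, file.path(out_dir, "verdicts.tsv"))
    write_fasta(sim$sequences[retained_ids],
                file.path(out_dir, "retained.fna"))
    write_tsv(calls, file.path(out_dir, "lifestyle.tsv"))
    write_tsv(proportions, file.path(out_dir, "lifestyle_proportions.tsv"))
    write_tsv(links$links, file.path(out_dir, "links.tsv"))
    write_tsv(links$host_range, file.path(out_dir, "host_range.tsv"))
    write_tsv(amg_retained, file.path(out_dir, "amgs_retained.tsv"))
    write_tsv(amg_categories, file.path(out_dir, "amg_categories.tsv"))
    write_tsv(data.frame(gene_id = rownames(amg_z), round(amg_z, 10),
                         check.names = FALSE),
              file.path(out_dir, "amg_zscores.tsv"))
    write_tsv(data.frame(contig_id = rownames(abundance),
                         round(abundance, 6), check.names = FALSE),
              file.path(out_dir, "rpkm.tsv"))
    write_tsv(alpha, file.path(out_dir, "diversity.tsv"))
    bm <- as.matrix(bc)
    write_tsv(data.frame(sample_id = rownames(bm), round(bm, 10),
                         check.names = FALSE),
              file.path(out_dir, "braycurtis.tsv"))
    jsonlite::write_json(
      list(anosim = list(R = anosim_res$statistic,
                         p = anosim_res$p.value, nperm = nperm),
           mantel = list(r = mantel_res$statistic,
                         p = mantel_res$p.value, nperm = nperm)),
      file.path(out_dir, "permutation_tests.json"),
      auto_unbox = TRUE, digits = NA)
    write_tsv(microcosm_summary, file.path(out_dir, "microcosm_summary.tsv"))
  }
  invisible(res)
}
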