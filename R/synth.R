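# Synthetic soil-virome communities with planted, machine-readable ground
# truth: contig sequences, annotation-count features spanning every decision
# boundary, lysogeny markers, CRISPR protospacers with controlled mismatch
# counts, tRNA matches, genomic-homology blocks, AMG candidates, per-sample
# abundances with (optional) treatment structure, read counts, and microcosm
# CO2 series.
#
# All randomness derives from one global seed via fixed sub-stream labels,
# so identical configs give bit-identical outputs and adding one planted
# table never shifts another's draws.

#' Configuration for the synthetic community generator
#'
#' Defaults define the study conditions emulated throughout the test suite:
#' 120 candidate viral contigs of which 40% survive every triage rule, a
#' planted lysogenic fraction of 0.21 (the low end of temperate prevalence
#' in arable-soil viromes), protospacers with 0-3 planted mismatches on
#' random strands, and 12 virome samples in 4 treatments of 3 replicates.
#'
#' @param seed integer global seed.
#' @param n_viral_contigs number of candidate viral contigs.
#' @param n_host_contigs number of putative host contigs.
#' @param length_range bp range for viral contig lengths.
#' @param frac_true_viral fraction of viral contigs planted to pass every
#'   triage rule.
#' @param frac_lysogenic fraction of viral contigs planted with lysogeny
#'   markers.
#' @param n_spacers number of planted CRISPR spacers.
#' @param spacer_len_range nt range of spacer lengths.
#' @param spacer_mismatch_plan planted Hamming distances, cycled over
#'   spacers.
#' @param n_trna_links number of planted tRNA matches.
#' @param trna_len_range nt range of tRNA lengths.
#' @param trna_mismatch_plan planted tRNA mismatch counts, cycled.
#' @param n_homology_links number of planted homologous blocks / hit rows.
#' @param homology_block_len nominal maximum homologous block length (bp).
#' @param n_duplicate_pairs near-duplicate contig pairs planted for the
#'   clustering stage.
#' @param n_amg_candidates number of AMG candidate genes.
#' @param amg_flag_plan data frame with `auxiliary_score` and `flags`
#'   (comma-separated) cycled over candidates; the default spans scores 1-5
#'   against flag sets M, F, M+V, none, and V.
#' @param n_samples number of virome samples.
#' @param n_treatments number of treatment groups (samples split evenly).
#' @param read_depth reads per sample for [generate_counts()].
#' @param group_effect log-scale abundance shift distinguishing treatments
#'   (0 = null communities, exchangeable across samples).
#' @param frac_responsive fraction of contigs whose abundance responds to
#'   treatment when `group_effect > 0`.
#' @param plant_boundaries plant the fixed grid of rule-boundary feature
#'   profiles as the first contigs.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_viral_contigs = 120L,
                         n_host_contigs = 40L,
                         length_range = c(3000L, 12000L),
                         frac_true_viral = 0.4,
                         frac_lysogenic = 0.21,
                         n_spacers = 24L,
                         spacer_len_range = c(25L, 45L),
                         spacer_mismatch_plan = c(0L, 1L, 2L, 3L),
                         n_trna_links = 8L,
                         trna_len_range = c(60L, 100L),
                         trna_mismatch_plan = c(0L, 2L, 3L, 4L),
                         n_homology_links = 12L,
                         homology_block_len = 3000L,
                         n_duplicate_pairs = 6L,
                         n_amg_candidates = 60L,
                         amg_flag_plan = NULL,
                         n_samples = 12L,
                         n_treatments = 4L,
                         read_depth = 1e5,
                         group_effect = 1,
                         frac_responsive = 0.3,
                         plant_boundaries = TRUE) {
  cfg <- as.list(environment())
  if (is.null(cfg$amg_flag_plan)) {
    cfg$amg_flag_plan <- expand.grid(auxiliary_score = 1:5,
                                     flags = c("M", "F", "M,V", "", "V"),
                                     stringsAsFactors = FALSE)
  }
  for (f in c("frac_true_viral", "frac_lysogenic", "frac_responsive")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$length_range[1] <= 0) stop("length_range min must be > 0",
                                     call. = FALSE)
  if (max(cfg$spacer_mismatch_plan) > min(cfg$spacer_len_range) - 2L) {
    stop("infeasible spacer mismatch plan for the spacer length range",
         call. = FALSE)
  }
  if (max(cfg$spacer_len_range) > cfg$length_range[1]) {
    stop("spacer length can exceed the shortest contig", call. = FALSE)
  }
  if (cfg$read_depth <= 0) stop("read_depth must be positive", call. = FALSE)
  if (cfg$n_samples %% cfg$n_treatments != 0) {
    stop("n_samples must be a multiple of n_treatments", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Fixed grid of feature profiles straddling each triage decision boundary:
# detector score 0.49/0.50, completeness 49.9/50, KEGG 19.9/20%, Pfam
# 40/40.1%, VPF count 4/5, VPF fraction 59/60%, length 5000/5001 bp.
boundary_profiles <- function() {
  p <- function(length, n, vpf, kegg, pfam, score, comp, cont) {
    data.frame(length = length, n_genes = n, n_vpf_hit_genes = vpf,
               n_kegg_genes = kegg, n_pfam_genes = pfam,
               detector_score = score, completeness = comp,
               contamination = cont)
  }
  rbind(p(6000L, 20L, 15L, 1L, 5L, 0.50, 80, 2),    # score boundary pass
        p(6000L, 20L, 15L, 1L, 5L, 0.49, 80, 2),    # score fail
        p(6000L, 20L, 15L, 1L, 5L, 0.90, 50.0, 2),  # completeness pass
        p(6000L, 20L, 15L, 1L, 5L, 0.90, 49.9, 2),  # completeness fail
        p(6000L, 1000L, 600L, 199L, 300L, 0.90, 80, 2),  # KEGG 19.9% pass
        p(6000L, 1000L, 600L, 200L, 300L, 0.90, 80, 2),  # KEGG 20% fail
        p(6000L, 1000L, 600L, 100L, 400L, 0.90, 80, 2),  # Pfam 40% pass
        p(6000L, 1000L, 600L, 100L, 401L, 0.90, 80, 2),  # Pfam 40.1% fail
        p(6000L, 8L, 5L, 1L, 3L, 0.90, 80, 2),      # VPF 5 pass
        p(6000L, 8L, 4L, 1L, 3L, 0.90, 80, 2),      # VPF 4 fail
        p(6000L, 100L, 60L, 10L, 40L, 0.90, 80, 2), # VPF 60% pass
        p(6000L, 100L, 59L, 10L, 40L, 0.90, 80, 2), # VPF 59% fail
        p(5001L, 20L, 15L, 1L, 5L, 0.90, 80, 2),    # length 5001 pass
        p(5000L, 20L, 15L, 1L, 5L, 0.90, 80, 2))    # length 5000 fail
}

# One feature profile passing every rule (length supplied by caller).
passing_profile <- function(length) {
  n <- sample(15:40, 1L)
  vpf <- sample(max(5L, ceiling(0.6 * n)):n, 1L)
  kegg <- sample(0:(ceiling(0.2 * n) - 1L), 1L)
  pfam <- sample(0:min(floor(0.4 * n), vpf), 1L)
  data.frame(length = as.integer(length), n_genes = n, n_vpf_hit_genes = vpf,
             n_kegg_genes = kegg, n_pfam_genes = pfam,
             detector_score = round(stats::runif(1, 0.5, 1), 3),
             completeness = round(stats::runif(1, 50, 100), 1),
             contamination = round(stats::runif(1, 0, 10), 1))
}

# One profile broken on a chosen rule (others kept passing where possible).
failing_profile <- function(length, mode) {
  f <- passing_profile(length)
  n <- f$n_genes
  switch(mode,
         score = f$detector_score <- round(stats::runif(1, 0, 0.49), 3),
         completeness = f$completeness <- round(stats::runif(1, 0, 49.8), 1),
         contamination = f$contamination <-
           round(stats::runif(1, 10.1, 30), 1),
         vpf = f$n_vpf_hit_genes <- sample(0:4, 1L),
         kegg = f$n_kegg_genes <- sample(ceiling(0.2 * n):n, 1L),
         pfam = {
           f$n_vpf_hit_genes <- n
           f$n_pfam_genes <- sample((floor(0.4 * n) + 1L):n, 1L)
         },
         vpffrac = f$n_vpf_hit_genes <-
           sample(5:max(5L, ceiling(0.6 * n) - 1L), 1L),
         length = f$length <- sample(1500:5000, 1L),
         stop("unknown failing mode: ", mode))
  f
}

# Generation-side application of the triage inequalities (bookkeeping for the
# truth table; the test suite re-derives these with an independent checker).
apply_triage_rules <- function(f) {
  n <- f$n_genes
  prim <- f$detector_score >= 0.5 & f$completeness >= 50 &
    f$contamination <= 10
  c1 <- n > 0 & f$n_vpf_hit_genes >= 5 & (f$n_kegg_genes / n) < 0.20 &
    (f$n_pfam_genes / n) <= 0.40
  c2 <- n > 0 & f$n_vpf_hit_genes >= f$n_pfam_genes &
    (f$n_vpf_hit_genes / n) >= 0.60
  len <- f$length > 5000
  data.frame(passes_primary = prim, passes_criterion1 = c1,
             passes_criterion2 = c2, passes_length = len,
             should_advance = prim & c1 & c2 & len)
}

# Mutate exactly d interior positions (never the first or last) of an
# A/C/G/T string; substitutions only.
mutate_string <- function(s, d, interior_only = TRUE) {
  if (d == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  pool <- if (interior_only) 2:(L - 1L) else seq_len(L)
  if (d > length(pool)) stop("more mismatches than mutable positions",
                             call. = FALSE)
  pos <- sample(pool, d)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic viral/host community with planted ground truth
#'
#' @param config a [synth_config()].
#' @return list of class `synth_community` with `sequences` (named character,
#'   viral then host), `features`, `markers`, `spacers`, `trnas`, `homhits`
#'   (12-column tabular homology dialect), `amgs`, `metadata`, and `truth`
#'   (per-contig flags, per-link records with `should_pass`, per-gene AMG
#'   retention, per-sample planted abundances).
#' @export
generate_community <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  nv <- cfg$n_viral_contigs
  nh <- cfg$n_host_contigs
  viral_ids <- sprintf("vOTU_%04d", seq_len(nv))
  host_ids <- sprintf("host_%04d", seq_len(nh))

  ## ---- features (with pass/fail allocation) --------------------------------
  n_boundary <- if (cfg$plant_boundaries) 14L else 0L
  n_dup <- 2L * cfg$n_duplicate_pairs
  n_hom <- cfg$n_homology_links
  if (nv < n_boundary + n_dup + n_hom) {
    stop("n_viral_contigs too small for the planted boundary/duplicate/",
         "homology sets", call. = FALSE)
  }
  n_pass_target <- round(cfg$frac_true_viral * nv)
  n_pass_fixed <- (if (n_boundary) 7L else 0L) + n_dup
  if (n_pass_target < n_pass_fixed) {
    stop("frac_true_viral too low for the planted passing sets",
         call. = FALSE)
  }

  lmin <- max(cfg$length_range[1], 5200L)
  lmax <- max(cfg$length_range[2], lmin + 1000L)
  hom_plan_all <- data.frame(
    cov = c(0.90, 0.85, 0.80, 0.76, 0.60, 0.90, 0.90, 0.80),
    ident = c(96, 80, 74, 68, 96, 90, 90, 95),
    evalue = c(rep(1e-30, 5), 1e-2, 1e-30, 1e-30),
    low_bits = c(rep(FALSE, 6), TRUE, FALSE),
    short_block = c(rep(FALSE, 7), TRUE))

  features <- with_sub_seed(cfg$seed, "features", {
    rows <- vector("list", nv)
    i <- 1L
    if (n_boundary) {
      bp <- boundary_profiles()
      for (k in seq_len(n_boundary)) {
        rows[[i]] <- bp[k, , drop = FALSE]
        i <- i + 1L
      }
    }
    dup_src_idx <- integer(0)
    dup_idx <- integer(0)
    for (k in seq_len(cfg$n_duplicate_pairs)) {
      src_len <- sample(7000:lmax, 1L)
      src <- passing_profile(src_len)
      dup <- passing_profile(src_len - sample(300:800, 1L))
      rows[[i]] <- src; dup_src_idx <- c(dup_src_idx, i); i <- i + 1L
      rows[[i]] <- dup; dup_idx <- c(dup_idx, i); i <- i + 1L
    }
    hom_idx <- integer(0)
    for (k in seq_len(n_hom)) {
      plan <- hom_plan_all[(k - 1L) %% nrow(hom_plan_all) + 1L, ]
      len_v <- if (plan$short_block) 3000L else sample(3000:3300, 1L)
      rows[[i]] <- failing_profile(len_v, "length")
      rows[[i]]$length <- len_v
      hom_idx <- c(hom_idx, i); i <- i + 1L
    }
    n_pass_left <- n_pass_target - n_pass_fixed
    fail_modes <- c("score", "completeness", "contamination", "vpf", "kegg",
                    "pfam", "vpffrac", "length")
    while (i <= nv) {
      if (n_pass_left > 0L) {
        rows[[i]] <- passing_profile(sample(lmin:lmax, 1L))
        n_pass_left <- n_pass_left - 1L
      } else {
        rows[[i]] <- failing_profile(sample(lmin:lmax, 1L),
                                     sample(fail_modes, 1L))
      }
      i <- i + 1L
    }
    f <- do.call(rbind, rows)
    f <- cbind(contig_id = viral_ids, f, stringsAsFactors = FALSE)
    attr(f, "dup_src_idx") <- dup_src_idx
    attr(f, "dup_idx") <- dup_idx
    attr(f, "hom_idx") <- hom_idx
    f
  })
  dup_src_idx <- attr(features, "dup_src_idx")
  dup_idx <- attr(features, "dup_idx")
  hom_idx <- attr(features, "hom_idx")
  attr(features, "dup_src_idx") <- NULL
  attr(features, "dup_idx") <- NULL
  attr(features, "hom_idx") <- NULL
  rownames(features) <- NULL

  rules <- apply_triage_rules(features)

  ## ---- sequences -----------------------------------------------------------
  host_lengths <- NULL
  sequences <- with_sub_seed(cfg$seed, "sequences", {
    viral_seq <- random_dna(features$length)
    names(viral_seq) <- viral_ids
    # near-duplicates: truncated copies of their source at ~98% identity
    for (k in seq_along(dup_idx)) {
      src <- viral_seq[[dup_src_idx[k]]]
      dlen <- features$length[dup_idx[k]]
      copy <- substr(src, 1L, dlen)
      viral_seq[[dup_idx[k]]] <- mutate_string(copy, round(0.02 * dlen),
                                               interior_only = FALSE)
    }
    host_lengths <- sample(6000:12000, nh, replace = TRUE)
    host_seq <- random_dna(host_lengths)
    names(host_seq) <- host_ids
    c(viral_seq, host_seq)
  })

  ## ---- genomic homology blocks (planted before spacer/tRNA extraction) ----
  hom <- with_sub_seed(cfg$seed, "homology", {
    rows <- vector("list", n_hom)
    truth <- vector("list", n_hom)
    for (k in seq_len(n_hom)) {
      plan <- hom_plan_all[(k - 1L) %% nrow(hom_plan_all) + 1L, ]
      v <- viral_ids[hom_idx[k]]
      len_v <- features$length[hom_idx[k]]
      L <- if (plan$short_block) 2400L else
        min(round(plan$cov * len_v), cfg$homology_block_len)
      h_ok <- which(host_lengths >= L + 2L)
      h_i <- sample(h_ok, 1L)
      h <- host_ids[h_i]
      ss <- sample.int(host_lengths[h_i] - L + 1L, 1L)
      block <- substr(sequences[[h]], ss, ss + L - 1L)
      d <- round((1 - plan$ident / 100) * L)
      block_mut <- mutate_string(block, d, interior_only = FALSE)
      qs <- sample.int(len_v - L + 1L, 1L)
      sequences[[v]] <- paste0(substr(sequences[[v]], 1L, qs - 1L),
                               block_mut,
                               substr(sequences[[v]], qs + L,
                                      len_v))
      pident <- round((1 - d / L) * 100, 2)
      bits <- if (plan$low_bits) 30 else round(1.8 * L * pident / 100)
      qcov <- (L / len_v) * 100
      rows[[k]] <- data.frame(qseqid = v, sseqid = h, pident = pident,
                              length = L, mismatch = d, gapopen = 0L,
                              qstart = qs, qend = qs + L - 1L,
                              sstart = ss, send = ss + L - 1L,
                              evalue = plan$evalue, bitscore = bits,
                              stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        virus_id = v, host_id = h, channel = "homology",
        query_id = NA_character_, length = L, mismatches = d,
        identity = pident, strand = NA_character_,
        start = qs - 1L, end = qs - 1L + L,
        query_cov = qcov, evalue = plan$evalue, bitscore = bits,
        should_pass = pident >= 70 & qcov >= 75 & plan$evalue <= 1e-3 &
          bits >= 50 & L >= 2500,
        stringsAsFactors = FALSE)
    }
    list(hits = do.call(rbind, rows), truth = do.call(rbind, truth))
  })

  ## ---- lysogeny markers ----------------------------------------------------
  lys <- with_sub_seed(cfg$seed, "lysogeny", {
    n_lys <- round(cfg$frac_lysogenic * nv)
    lys_ids <- sort(sample(viral_ids, n_lys))
    rows <- lapply(lys_ids, function(id) {
      nm <- sample(1:2, 1L)
      data.frame(contig_id = id,
                 gene_id = sprintf("%s_g%02d", id, seq_len(nm)),
                 marker_class = sample(lysogeny_marker_lexicon(), nm,
                                       replace = TRUE),
                 source = "domain-table", stringsAsFactors = FALSE)
    })
    # non-lysogeny domain rows on other contigs; must never trigger a call
    others <- sample(setdiff(viral_ids, lys_ids), min(5L, nv - n_lys))
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = others,
      gene_id = sprintf("%s_gx", others),
      marker_class = "other", source = "domain-table",
      stringsAsFactors = FALSE)
    list(markers = do.call(rbind, rows), lys_ids = lys_ids)
  })

  ## ---- CRISPR spacers ------------------------------------------------------
  clean_pool <- setdiff(viral_ids,
                        viral_ids[c(dup_src_idx, dup_idx, hom_idx)])
  spac <- with_sub_seed(cfg$seed, "spacers", {
    rows <- vector("list", cfg$n_spacers)
    truth <- vector("list", cfg$n_spacers)
    for (k in seq_len(cfg$n_spacers)) {
      d <- cfg$spacer_mismatch_plan[
        (k - 1L) %% length(cfg$spacer_mismatch_plan) + 1L]
      L <- sample(cfg$spacer_len_range[1]:cfg$spacer_len_range[2], 1L)
      v <- sample(clean_pool, 1L)
      vlen <- features$length[match(v, viral_ids)]
      if (L > vlen) stop("spacer longer than target contig", call. = FALSE)
      start <- sample.int(vlen - L + 1L, 1L)
      window <- substr(sequences[[v]], start, start + L - 1L)
      sp <- mutate_string(window, d, interior_only = TRUE)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") sp <- revcomp(sp)
      h <- sample(host_ids, 1L)
      sp_id <- sprintf("spacer_%03d", k)
      rows[[k]] <- data.frame(host_contig_id = h, spacer_id = sp_id,
                              sequence = sp, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        virus_id = v, host_id = h, channel = "spacer", query_id = sp_id,
        length = L, mismatches = d, identity = (L - d) / L * 100,
        strand = strand, start = start - 1L, end = start - 1L + L,
        query_cov = NA_real_, evalue = NA_real_, bitscore = NA_real_,
        should_pass = d <= min(2, floor(0.05 * L + 1e-9)),
        stringsAsFactors = FALSE)
    }
    list(spacers = do.call(rbind, rows), truth = do.call(rbind, truth))
  })

  ## ---- tRNA links ----------------------------------------------------------
  trn <- with_sub_seed(cfg$seed, "trnas", {
    rows <- vector("list", cfg$n_trna_links)
    truth <- vector("list", cfg$n_trna_links)
    for (k in seq_len(cfg$n_trna_links)) {
      d <- cfg$trna_mismatch_plan[
        (k - 1L) %% length(cfg$trna_mismatch_plan) + 1L]
      L <- sample(cfg$trna_len_range[1]:cfg$trna_len_range[2], 1L)
      v <- sample(clean_pool, 1L)
      vlen <- features$length[match(v, viral_ids)]
      start <- sample.int(vlen - L + 1L, 1L)
      window <- substr(sequences[[v]], start, start + L - 1L)
      tr <- mutate_string(window, d, interior_only = TRUE)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") tr <- revcomp(tr)
      h <- sample(host_ids, 1L)
      tr_id <- sprintf("trna_%03d", k)
      rows[[k]] <- data.frame(host_contig_id = h, trna_id = tr_id,
                              sequence = tr, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        virus_id = v, host_id = h, channel = "trna", query_id = tr_id,
        length = L, mismatches = d, identity = (L - d) / L * 100,
        strand = strand, start = start - 1L, end = start - 1L + L,
        query_cov = NA_real_, evalue = NA_real_, bitscore = NA_real_,
        should_pass = d <= floor(0.05 * L + 1e-9),
        stringsAsFactors = FALSE)
    }
    list(trnas = do.call(rbind, rows), truth = do.call(rbind, truth))
  })

  ## ---- AMG candidates ------------------------------------------------------
  amgs <- with_sub_seed(cfg$seed, "amgs", {
    n_amg <- cfg$n_amg_candidates
    plan <- cfg$amg_flag_plan[
      (seq_len(n_amg) - 1L) %% nrow(cfg$amg_flag_plan) + 1L, ]
    caz_pool <- c("GH13", "GT2", "PL1", "CE4", "GH5", "GT4", "CE1", "PL9")
    kegg2_pool <- c("Carbohydrate metabolism", "Energy metabolism",
                    "Amino acid metabolism",
                    "Metabolism of cofactors and vitamins")
    has_caz <- stats::runif(n_amg) < 0.6
    has_ko <- stats::runif(n_amg) < 0.75
    ab <- matrix(stats::rlnorm(n_amg * cfg$n_treatments, 2, 0.8),
                 nrow = n_amg)
    colnames(ab) <- sprintf("abundance_T%d", seq_len(cfg$n_treatments))
    df <- data.frame(
      gene_id = sprintf("amg_%04d", seq_len(n_amg)),
      contig_id = sample(viral_ids, n_amg, replace = TRUE),
      ko_id = ifelse(has_ko,
                     sprintf("K%05d", sample.int(20000, n_amg,
                                                 replace = TRUE)), ""),
      auxiliary_score = plan$auxiliary_score,
      flags = plan$flags,
      cazyme_family = ifelse(has_caz,
                             sample(caz_pool, n_amg, replace = TRUE), ""),
      kegg_level2 = ifelse(has_ko,
                           sample(kegg2_pool, n_amg, replace = TRUE), ""),
      stringsAsFactors = FALSE)
    cbind(df, round(ab, 4))
  })
  fl <- parse_flags(amgs$flags)
  amg_truth <- data.frame(
    gene_id = amgs$gene_id,
    retained = amgs$auxiliary_score %in% 1:3 &
      vapply(fl, function(f) any(f %in% c("M", "F")), logical(1)) &
      vapply(fl, function(f) !any(f %in% c("V", "A", "P", "T", "B")),
             logical(1)),
    stringsAsFactors = FALSE)

  ## ---- per-sample planted abundances --------------------------------------
  abund <- with_sub_seed(cfg$seed, "abundance", {
    base <- stats::rlnorm(nv, 0, 1.2)
    treat <- sprintf("T%d", seq_len(cfg$n_treatments))
    per_treat <- rep(cfg$n_samples / cfg$n_treatments, cfg$n_treatments)
    sample_treat <- rep(treat, per_treat)
    responsive <- if (cfg$group_effect > 0) {
      sample.int(nv, round(cfg$frac_responsive * nv))
    } else integer(0)
    p <- matrix(0, nv, cfg$n_samples)
    shift <- matrix(0, nv, cfg$n_treatments)
    if (length(responsive)) {
      shift[responsive, ] <- stats::rnorm(
        length(responsive) * cfg$n_treatments, 0, cfg$group_effect)
    }
    for (s in seq_len(cfg$n_samples)) {
      t_i <- match(sample_treat[s], treat)
      w <- base * exp(shift[, t_i])
      p[, s] <- w / sum(w)
    }
    dimnames(p) <- list(viral_ids, sprintf("S%02d", seq_len(cfg$n_samples)))
    list(p = p, sample_treat = sample_treat)
  })

  metadata <- data.frame(sample_id = colnames(abund$p),
                         treatment = abund$sample_treat,
                         stringsAsFactors = FALSE)

  truth <- list(
    contigs = cbind(
      data.frame(contig_id = viral_ids, stringsAsFactors = FALSE),
      rules,
      data.frame(
        is_viral = rules$should_advance,
        is_lysogenic = viral_ids %in% lys$lys_ids,
        dup_of = {
          d <- rep(NA_character_, nv)
          d[dup_idx] <- viral_ids[dup_src_idx]
          d
        },
        stringsAsFactors = FALSE)),
    links = rbind(spac$truth, trn$truth, hom$truth),
    amgs = amg_truth,
    samples = data.frame(sample_id = metadata$sample_id,
                         group = metadata$treatment,
                         stringsAsFactors = FALSE),
    abundance = abund$p,
    frac_lysogenic = cfg$frac_lysogenic)
  rownames(truth$links) <- NULL

  structure(list(config = cfg,
                 sequences = sequences,
                 viral_ids = viral_ids,
                 host_ids = host_ids,
                 features = features,
                 markers = lys$markers,
                 spacers = spac$spacers,
                 trnas = trn$trnas,
                 homhits = hom$hits,
                 amgs = amgs,
                 metadata = metadata,
                 truth = truth),
            class = "synth_community")
}

#' Draw read counts from planted per-sample abundances
#'
#' Each sample's column is a multinomial draw of `depth` reads over the
#' planted relative abundances, so column sums equal the depth exactly.
#'
#' @param truth the `truth` element of a [generate_community()] result (or
#'   any list with an `abundance` matrix of per-sample proportions).
#' @param depth reads per sample (> 0).
#' @param seed integer seed.
#' @return integer matrix, contigs x samples.
#' @export
generate_counts <- function(truth, depth, seed) {
  p <- truth$abundance
  stopifnot(is.matrix(p))
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (any(abs(colSums(p) - 1) > 1e-8)) {
    stop("planted per-sample abundances must sum to 1", call. = FALSE)
  }
  with_sub_seed(seed, "counts", {
    counts <- vapply(seq_len(ncol(p)), function(s) {
      as.integer(stats::rmultinom(1L, size = depth, prob = p[, s]))
    }, integer(nrow(p)))
    dimnames(counts) <- dimnames(p)
    counts
  })
}

#' Null (exchangeable) community counts for permutation-test calibration
#'
#' One set of taxon proportions is drawn, then every sample is an
#' independent multinomial draw from it: samples are exchangeable, with no
#' group structure.
#'
#' @param n_taxa,n_samples community dimensions.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return integer matrix, taxa x samples.
#' @export
generate_null_counts <- function(n_taxa, n_samples, depth, seed) {
  with_sub_seed(seed, "null-counts", {
    w <- stats::rlnorm(n_taxa, 0, 1)
    p <- w / sum(w)
    counts <- vapply(seq_len(n_samples), function(s) {
      as.integer(stats::rmultinom(1L, size = depth, prob = p))
    }, integer(n_taxa))
    dimnames(counts) <- list(sprintf("t%03d", seq_len(n_taxa)),
                             sprintf("S%02d", seq_len(n_samples)))
    counts
  })
}

#' Generate a microcosm incubation series with known CO2 and qCO2 truth
#'
#' Emulates a 35-day incubation sampled by alkali traps on days
#' 1, 3, 5, 7, 14, 21, 28 and 35, under virus-addition (VS) vs sterile
#' (NS) treatments crossed with four straw/nitrogen treatments (T1-T4),
#' three replicates each. Virus addition is planted to raise MBC (and so
#' lower qCO2) in the straw-removal treatments T1 and T3, and to raise DOC,
#' SUVA254 and the BG/NAG enzyme activities throughout.
#'
#' @param config a [synth_config()] (only `seed` is used).
#' @param days strictly increasing sampling-day grid.
#' @return list with `series` (one row per microcosm x day:
#'   `microcosm_id`, `virus`, `treatment`, `rep`, `day`, `co2_interval` in
#'   mg CO2-C g^-1 soil per interval), `endpoint` (MBC, DOC, SUVA254, BG,
#'   NAG per microcosm), and `truth` (`cumulative_total`, `qco2`).
#' @export
generate_microcosm <- function(config = synth_config(),
                               days = c(1, 3, 5, 7, 14, 21, 28, 35)) {
  stopifnot(inherits(config, "synth_config"))
  if (any(diff(days) <= 0)) {
    stop("sampling days must be strictly increasing", call. = FALSE)
  }
  width <- diff(c(0, days))
  mid <- days - width / 2
  with_sub_seed(config$seed, "microcosm", {
    design <- expand.grid(rep = 1:3, treatment = sprintf("T%d", 1:4),
                          virus = c("NS", "VS"), stringsAsFactors = FALSE)
    design$microcosm_id <- sprintf("%s_%s_r%d", design$virus,
                                   design$treatment, design$rep)
    straw <- design$treatment %in% c("T2", "T4")
    nitro <- design$treatment %in% c("T3", "T4")
    rate <- 0.012 * ifelse(straw, 1.8, 1) * ifelse(nitro, 1.2, 1) *
      ifelse(design$virus == "VS" & !straw, 0.9, 1)
    series <- list()
    totals <- numeric(nrow(design))
    for (i in seq_len(nrow(design))) {
      amounts <- round(rate[i] * width * exp(-0.03 * mid) *
                         exp(stats::rnorm(length(days), 0, 0.1)), 6)
      totals[i] <- sum(amounts)
      series[[i]] <- data.frame(microcosm_id = design$microcosm_id[i],
                                virus = design$virus[i],
                                treatment = design$treatment[i],
                                rep = design$rep[i],
                                day = days,
                                co2_interval = amounts,
                                stringsAsFactors = FALSE)
    }
    series <- do.call(rbind, series)

    mbc <- 0.25 * ifelse(straw, 1.4, 1) * ifelse(nitro, 1.1, 1) *
      ifelse(design$virus == "VS" & !straw, 1.25, 1) *
      exp(stats::rnorm(nrow(design), 0, 0.08))
    doc <- 0.15 * ifelse(straw, 1.5, 1) *
      ifelse(design$virus == "VS", 1.15, 1) *
      exp(stats::rnorm(nrow(design), 0, 0.08))
    suva <- 2.0 * ifelse(design$virus == "VS", 1.10, 1) *
      exp(stats::rnorm(nrow(design), 0, 0.06))
    bg <- 1.2 * ifelse(straw, 1.3, 1) *
      ifelse(design$virus == "VS", 1.20, 1) *
      exp(stats::rnorm(nrow(design), 0, 0.10))
    nag <- 0.8 * ifelse(straw, 1.2, 1) *
      ifelse(design$virus == "VS", 1.20, 1) *
      exp(stats::rnorm(nrow(design), 0, 0.10))
    endpoint <- data.frame(microcosm_id = design$microcosm_id,
                           virus = design$virus,
                           treatment = design$treatment,
                           rep = design$rep,
                           mbc = round(mbc, 6), doc = round(doc, 6),
                           suva254 = round(suva, 6), bg = round(bg, 6),
                           nag = round(nag, 6), stringsAsFactors = FALSE)
    truth <- data.frame(microcosm_id = design$microcosm_id,
                        cumulative_total = totals,
                        qco2 = totals / (endpoint$mbc * max(days)),
                        stringsAsFactors = FALSE)
    list(series = series, endpoint = endpoint, truth = truth)
  })
}

#' Write a synthetic community to a directory of flat files
#'
#' Writes `contigs.fna`, `features.tsv`, `markers.tsv`, `spacers.tsv`,
#' `trnas.tsv`, `homhits.tsv` (headerless 12-column homology dialect),
#' `amgs.tsv`, `metadata.tsv`, optional `counts.tsv`, and `truth.json`.
#'
#' @param sim a `synth_community`.
#' @param dir output directory (created if needed).
#' @param counts optional counts matrix from [generate_counts()].
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir, counts = NULL) {
  stopifnot(inherits(sim, "synth_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$sequences, file.path(dir, "contigs.fna"))
  write_tsv(sim$features, file.path(dir, "features.tsv"))
  write_tsv(sim$markers, file.path(dir, "markers.tsv"))
  write_tsv(sim$spacers, file.path(dir, "spacers.tsv"))
  write_tsv(sim$trnas, file.path(dir, "trnas.tsv"))
  utils::write.table(sim$homhits, file.path(dir, "homhits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_tsv(sim$amgs, file.path(dir, "amgs.tsv"))
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(counts)) {
    write_tsv(data.frame(contig_id = rownames(counts), counts,
                         check.names = FALSE), file.path(dir, "counts.tsv"))
  }
  truth <- sim$truth
  truth$abundance <- as.data.frame(truth$abundance)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
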