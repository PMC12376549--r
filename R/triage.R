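# Viral-contig triage: primary screen, tripartite filtering criteria, greedy
# 95%-identity clustering with the longest sequence as representative, and the
# > 5 kb retention rule.
#
# Boundary semantics follow the printed inequality directions exactly:
# removal rules are strict ("< 50% completeness", "> 10% contamination"
# remove, so 50 / 10 survive) while retention rules are inclusive
# ("score >= 0.5", ">= 5 VPF hits") -- except the length rule, which retains
# strictly "> 5 kb", so a 5,000 bp contig drops.

.feature_cols <- c("contig_id", "length", "n_genes", "n_vpf_hit_genes",
                   "n_kegg_genes", "n_pfam_genes", "detector_score",
                   "completeness", "contamination")

#' Primary screen of candidate viral contigs
#'
#' Keeps contigs with detector score >= 0.5 that are not removed by the
#' quality rules (< 50% completeness or > 10% contamination removes, so the
#' boundary values 50 and 10 survive).
#'
#' @param features data frame of per-contig annotation counts with columns
#'   `contig_id`, `detector_score`, `completeness`, `contamination` (plus the
#'   gene-count columns used downstream).
#' @param score_min minimum detector score retained (default 0.5).
#' @param completeness_min completeness below which a contig is removed (50).
#' @param contamination_max contamination above which a contig is removed (10).
#' @return data frame with `contig_id`, logical `passed_primary`, and a
#'   `reasons` string listing failed rules (empty when passed).
#' @export
screen_primary <- function(features, score_min = 0.5, completeness_min = 50,
                           contamination_max = 10) {
  check_columns(features, c("contig_id", "detector_score", "completeness",
                            "contamination"), "features")
  fail_score <- features$detector_score < score_min
  fail_comp  <- features$completeness < completeness_min
  fail_cont  <- features$contamination > contamination_max
  reasons <- mapply(function(a, b, c) {
    paste(c("score", "completeness", "contamination")[c(a, b, c)],
          collapse = ",")
  }, fail_score, fail_comp, fail_cont)
  data.frame(contig_id = features$contig_id,
             passed_primary = !(fail_score | fail_comp | fail_cont),
             reasons = as.character(reasons),
             stringsAsFactors = FALSE)
}

#' Tripartite filtering criteria 1 and 2
#'
#' Criterion 1: >= 5 genes with viral-protein-family (VPF) hits, < 20% of
#' genes with KEGG Orthology annotations, and <= 40% of genes covered by
#' Pfams. Criterion 2: VPF gene count >= Pfam gene count and VPF genes
#' >= 60% of all genes. Gene counts are one vote per gene regardless of the
#' number of domain hits. Contigs with zero predicted genes fail (reason
#' "no genes") rather than erroring, so fragmentary contigs never abort a run.
#'
#' @param features data frame with `contig_id`, `n_genes`, `n_vpf_hit_genes`,
#'   `n_kegg_genes`, `n_pfam_genes`.
#' @return data frame with `contig_id`, `passed_criterion1`,
#'   `passed_criterion2`, `reasons`.
#' @export
tripartite_filter <- function(features) {
  check_columns(features, c("contig_id", "n_genes", "n_vpf_hit_genes",
                            "n_kegg_genes", "n_pfam_genes"), "features")
  n  <- features$n_genes
  vp <- features$n_vpf_hit_genes
  kg <- features$n_kegg_genes
  pf <- features$n_pfam_genes
  no_genes <- n <= 0
  nn <- ifelse(no_genes, NA_real_, n)

  c1_vpf  <- vp >= 5
  c1_kegg <- (kg / nn) < 0.20
  c1_pfam <- (pf / nn) <= 0.40
  c2_cnt  <- vp >= pf
  c2_frac <- (vp / nn) >= 0.60

  pass1 <- !no_genes & c1_vpf & c1_kegg & c1_pfam
  pass2 <- !no_genes & c2_cnt & c2_frac

  reasons <- vapply(seq_along(n), function(i) {
    if (no_genes[i]) return("no genes")
    paste(c("vpf<5", "kegg>=20%", "pfam>40%", "vpf<pfam", "vpf<60%")[
      c(!c1_vpf[i], !c1_kegg[i], !c1_pfam[i], !c2_cnt[i], !c2_frac[i])],
      collapse = ",")
  }, character(1))

  data.frame(contig_id = features$contig_id,
             passed_criterion1 = pass1,
             passed_criterion2 = pass2,
             reasons = reasons,
             stringsAsFactors = FALSE)
}

# Fraction of the shorter sequence's k-mers found in the longer sequence.
# Cheap prefilter before dynamic programming: at >= 95% identity over the
# whole shorter sequence the expected exact-k-mer survival is ~0.95^k
# (~0.54 at k = 12), while unrelated random sequences share essentially none.
kmer_share <- function(a, b, k = 12L) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(a) < k) return(if (grepl(a, b, fixed = TRUE)) 1 else 0)
  starts_a <- seq_len(nchar(a) - k + 1L)
  kmers_a <- unique(substring(a, starts_a, starts_a + k - 1L))
  starts_b <- seq_len(nchar(b) - k + 1L)
  kmers_b <- unique(substring(b, starts_b, starts_b + k - 1L))
  mean(kmers_a %in% kmers_b)
}

# Best gap-free end-to-end placement of the shorter sequence on the longer:
# max over offsets of (L - Hamming) / L. A lower bound on [seq_identity()].
ungapped_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  d <- hamming_windows(b, a)
  if (!length(d)) return(0)
  (nchar(a) - min(d)) / nchar(a)
}

#' Identity between two sequences under the clustering convention
#'
#' The shorter sequence is aligned end-to-end onto the best-matching window
#' of the longer (global-local dynamic programming); identity is matches
#' divided by alignment columns. Symmetric by construction.
#'
#' @param a,b nucleotide strings.
#' @return identity fraction in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (grepl(a, b, fixed = TRUE)) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Greedy identity clustering with longest-sequence representatives
#'
#' Contigs of length <= `min_len` are dropped first (the retention rule is
#' strictly > 5 kb). Remaining sequences are sorted by length descending
#' (ties broken by contig id) and each joins the first existing cluster whose
#' representative reaches `identity_threshold` under [seq_identity()]
#' (inclusive comparison), else founds a new cluster. The representative is
#' the longest member, i.e. the founder.
#'
#' @param sequences named character vector of contig sequences.
#' @param identity_threshold identity fraction in (0, 1\] (default 0.95).
#' @param min_len length cutoff in bp; contigs must exceed it (default 5000).
#' @param kmer_prefilter_min skip the alignment when the k-mer share is below
#'   this fraction (0 disables the prefilter).
#' @return data frame with `contig_id`, `length`, `cluster_id`,
#'   `is_representative`; zero rows for empty input.
#' @export
cluster_greedy <- function(sequences, identity_threshold = 0.95,
                           min_len = 5000, kmer_prefilter_min = 0.05) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  empty <- data.frame(contig_id = character(0), length = integer(0),
                      cluster_id = integer(0), is_representative = logical(0),
                      stringsAsFactors = FALSE)
  if (length(sequences) == 0L) return(empty)
  stopifnot(!is.null(names(sequences)))
  lens <- nchar(sequences)
  keep <- lens > min_len
  sequences <- sequences[keep]
  lens <- lens[keep]
  if (length(sequences) == 0L) return(empty)

  ord <- order(-lens, names(sequences))
  sequences <- sequences[ord]
  lens <- lens[ord]
  ids <- names(sequences)

  kmers <- if (kmer_prefilter_min > 0) {
    k <- 12L
    lapply(sequences, function(s) {
      starts <- seq_len(nchar(s) - k + 1L)
      unique(substring(s, starts, starts + k - 1L))
    })
  } else NULL

  cluster_of <- integer(length(ids))
  reps <- integer(0)  # indices of cluster representatives, in founding order
  for (i in seq_along(ids)) {
    assigned <- 0L
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      if (!is.null(kmers) &&
          mean(kmers[[i]] %in% kmers[[r]]) < kmer_prefilter_min) {
        next
      }
      # ungapped fast path: an end-to-end gap-free placement reaching the
      # threshold already witnesses identity >= threshold, so the full
      # dynamic program (which can only add matches) is skipped
      ident <- ungapped_identity(sequences[[i]], sequences[[r]])
      if (ident < identity_threshold) {
        ident <- seq_identity(sequences[[i]], sequences[[r]])
      }
      if (ident >= identity_threshold) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    cluster_of[i] <- assigned
  }
  data.frame(contig_id = ids,
             length = as.integer(lens),
             cluster_id = cluster_of,
             is_representative = seq_along(ids) %in% reps,
             stringsAsFactors = FALSE)
}

#' Run the full triage pipeline over a feature table and contig sequences
#'
#' Composes [screen_primary()], [tripartite_filter()] (conjunctive by
#' default), the > `min_len` rule and [cluster_greedy()]; retained contigs
#' are the cluster representatives.
#'
#' @param features per-contig annotation-count table (see
#'   [tripartite_filter()] and [screen_primary()] for required columns, plus
#'   `length`).
#' @param sequences named character vector covering every contig in
#'   `features`.
#' @param identity_threshold clustering identity (default 0.95).
#' @param min_len retention length cutoff, exclusive (default 5000).
#' @param admission `"all"` (criteria 1 and 2 conjunctive, the default) or
#'   `"any"` (either criterion admits).
#' @return data frame with one row per input contig: pass flags per rule,
#'   `advanced` (passed primary + criteria + length), `cluster_id`,
#'   `is_representative` and `retained` (representative of a cluster),
#'   and failure `reasons`.
#' @export
run_triage <- function(features, sequences, identity_threshold = 0.95,
                       min_len = 5000, admission = c("all", "any")) {
  admission <- match.arg(admission)
  check_columns(features, .feature_cols, "features")
  if (nrow(features) == 0L) {
    return(data.frame(contig_id = character(0), passed_primary = logical(0),
                      passed_criterion1 = logical(0),
                      passed_criterion2 = logical(0),
                      passed_length = logical(0), advanced = logical(0),
                      cluster_id = integer(0), is_representative = logical(0),
                      retained = logical(0), reasons = character(0),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(features$contig_id, names(sequences))
  if (length(missing)) {
    stop("contig(s) in features but absent from sequences: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prim <- screen_primary(features)
  trip <- tripartite_filter(features)
  passed_length <- features$length > min_len
  crit <- if (admission == "all") {
    trip$passed_criterion1 & trip$passed_criterion2
  } else {
    trip$passed_criterion1 | trip$passed_criterion2
  }
  advanced <- prim$passed_primary & crit & passed_length

  cl <- cluster_greedy(sequences[features$contig_id[advanced]],
                       identity_threshold = identity_threshold,
                       min_len = min_len)
  cluster_id <- rep(NA_integer_, nrow(features))
  is_rep <- rep(FALSE, nrow(features))
  idx <- match(cl$contig_id, features$contig_id)
  cluster_id[idx] <- cl$cluster_id
  is_rep[idx] <- cl$is_representative

  reasons <- mapply(function(p, t, l) {
    parts <- c(p, t, if (!l) "length<=5kb")
    paste(parts[nzchar(parts)], collapse = ",")
  }, prim$reasons, trip$reasons, passed_length, USE.NAMES = FALSE)

  data.frame(contig_id = features$contig_id,
             passed_primary = prim$passed_primary,
             passed_criterion1 = trip$passed_criterion1,
             passed_criterion2 = trip$passed_criterion2,
             passed_length = passed_length,
             advanced = advanced,
             cluster_id = cluster_id,
             is_representative = is_rep,
             retained = is_rep,
             reasons = as.character(reasons),
             stringsAsFactors = FALSE)
}
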