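# Boundary semantics of the screen and tripartite criteria, clustering
# behaviour, and equivalence of the composed pipeline with the brute-force
# rule oracle.

feat_row <- function(score = 0.9, comp = 80, cont = 2, genes = 10, vpf = 6,
                     kegg = 1, pfam = 2, len = 6000, id = "c1") {
  data.frame(contig_id = id, length = len, n_genes = genes,
             n_vpf_hit_genes = vpf, n_kegg_genes = kegg,
             n_pfam_genes = pfam, detector_score = score,
             completeness = comp, contamination = cont,
             stringsAsFactors = FALSE)
}

test_that("primary screen honours strict removal boundaries", {
  # removal rules are strict (< 50%, > 10%), so the printed boundaries pass
  expect_true(screen_primary(feat_row(score = 0.5, comp = 50,
                                      cont = 10))$passed_primary)
  r <- screen_primary(feat_row(score = 0.49, comp = 90, cont = 0))
  expect_false(r$passed_primary)
  expect_identical(r$reasons, "score")
  r <- screen_primary(feat_row(score = 0.9, comp = 49.9, cont = 0))
  expect_false(r$passed_primary)
  expect_identical(r$reasons, "completeness")
  r <- screen_primary(feat_row(cont = 10.1))
  expect_identical(r$reasons, "contamination")
  expect_error(screen_primary(data.frame(contig_id = "x")),
               "detector_score")
})

test_that("tripartite criteria follow the printed inequality directions", {
  v <- tripartite_filter(feat_row(genes = 10, vpf = 6, kegg = 1, pfam = 2))
  expect_true(v$passed_criterion1 && v$passed_criterion2)

  # KEGG fraction must be strictly below 20%
  v <- tripartite_filter(feat_row(genes = 10, vpf = 5, kegg = 2, pfam = 4))
  expect_false(v$passed_criterion1)
  expect_match(v$reasons, "kegg")

  # VPF count below Pfam count fails criterion 2
  v <- tripartite_filter(feat_row(genes = 10, vpf = 5, kegg = 0, pfam = 6))
  expect_false(v$passed_criterion2)

  # Pfam coverage of exactly 40% passes, VPF of exactly 60% passes
  v <- tripartite_filter(feat_row(genes = 10, vpf = 6, kegg = 1, pfam = 4))
  expect_true(v$passed_criterion1 && v$passed_criterion2)

  v <- tripartite_filter(feat_row(genes = 0, vpf = 0, kegg = 0, pfam = 0))
  expect_false(v$passed_criterion1 || v$passed_criterion2)
  expect_identical(v$reasons, "no genes")
})

test_that("monotonicity: more VPF hits never flips a pass to a fail", {
  f <- random_features(60, seed = 8)
  base <- tripartite_filter(f)
  f2 <- f
  f2$n_vpf_hit_genes <- pmin(f$n_vpf_hit_genes + 2L, f$n_genes)
  bumped <- tripartite_filter(f2)
  both <- base$passed_criterion1 & base$passed_criterion2
  both2 <- bumped$passed_criterion1 & bumped$passed_criterion2
  expect_true(all(both2[both]))
})

test_that("greedy clustering keeps the longest as representative", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
             collapse = "")
  seqs <- c(long = s, short = substr(s, 1, 5500))
  cl <- cluster_greedy(seqs)
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_identical(cl$contig_id[cl$is_representative], "long")

  # ~90% identity falls below the 95% threshold: two clusters
  ch <- strsplit(s, "")[[1]]
  idx <- seq(5, 5995, by = 10)
  ch[idx] <- vapply(ch[idx],
                    function(b) setdiff(c("A", "C", "G", "T"), b)[1], "x")
  seqs2 <- c(a = s, b = paste(ch, collapse = ""))
  cl2 <- cluster_greedy(seqs2, kmer_prefilter_min = 0)
  expect_identical(length(unique(cl2$cluster_id)), 2L)

  # the length rule is strictly > 5 kb
  cl3 <- cluster_greedy(c(x = substr(s, 1, 5000)))
  expect_identical(nrow(cl3), 0L)
  expect_identical(nrow(cluster_greedy(character(0))), 0L)
})

test_that("clustering identity is symmetric and detects containment", {
  set.seed(5)
  a <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
             collapse = "")
  b <- paste0(paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                    collapse = ""), substr(a, 1, 600))
  expect_equal(seq_identity(a, b), seq_identity(b, a))
  expect_equal(seq_identity(substr(a, 100, 500), a), 1)
})

test_that("composed triage equals the brute-force rule oracle", {
  sim <- generate_community(synth_config(seed = 23))
  v <- run_triage(sim$features, sim$sequences)
  expect_identical(v$advanced, oracle_triage_advance(sim$features))

  # permuting the input order changes no verdict
  perm <- sample(nrow(sim$features))
  v2 <- run_triage(sim$features[perm, ], sim$sequences)
  v2 <- v2[match(v$contig_id, v2$contig_id), ]
  expect_equal(v$retained, v2$retained, ignore_attr = TRUE)
  expect_equal(v$advanced, v2$advanced, ignore_attr = TRUE)

  # near-duplicate pairs collapse to their longer member
  dup <- sim$truth$contigs[!is.na(sim$truth$contigs$dup_of), ]
  expect_true(all(!v$retained[match(dup$contig_id, v$contig_id)]))
  expect_true(all(v$retained[match(dup$dup_of, v$contig_id)]))
})

test_that("triage handles degenerate inputs", {
  empty <- run_triage(feat_row()[0, ], character(0))
  expect_identical(nrow(empty), 0L)
  expect_error(run_triage(feat_row(id = "zzz"), c(other = "ACGT")),
               "zzz")
  f <- rbind(feat_row(id = "a"), feat_row(id = "b"), feat_row(id = "c"))
  s <- paste(rep("ACGT", 1600), collapse = "")
  v <- run_triage(f, c(a = s, b = s, c = s))
  expect_identical(sum(v$retained), 1L)
})
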