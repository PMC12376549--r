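# Spacer/tRNA scanning against a brute-force all-windows oracle, the
# conjunctive identity/mismatch rule, homology-hit filtering at its printed
# boundaries, and merge/dedup behaviour.

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant <- function(subject, pattern, at) {
  paste0(substr(subject, 1, at - 1), pattern,
         substr(subject, at + nchar(pattern), nchar(subject)))
}

test_that("spacer rule applies mismatch and identity thresholds conjunctively", {
  subj <- rand_seq(3000, 1)
  # build spacers carrying exactly 2 mismatches against the contig
  mk_mm <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  sp40 <- mk_mm(substr(subj, 101, 140), c(10, 20))   # 40 nt, d = 2 -> 95.0%
  sp30 <- mk_mm(substr(subj, 501, 530), c(10, 20))   # 30 nt, d = 2 -> 93.3%
  spacers <- data.frame(host_contig_id = "h1",
                        spacer_id = c("s40", "s30"),
                        sequence = c(sp40, sp30), stringsAsFactors = FALSE)
  links <- match_spacers(spacers, c(v1 = subj))
  expect_identical(links$query_id, "s40")
  expect_identical(links$mismatches, 2L)
  expect_equal(links$identity, 95)
  expect_identical(links$start, 100L)

  # union rule admits the short spacer through the 2-mismatch budget
  links_u <- match_spacers(spacers, c(v1 = subj), rule = "union")
  expect_setequal(links_u$query_id, c("s40", "s30"))
})

test_that("reverse-complement occurrences are found with minus strand", {
  subj <- rand_seq(2000, 2)
  probe <- substr(subj, 301, 335)
  spacers <- data.frame(host_contig_id = "h1", spacer_id = "s1",
                        sequence = revcomp(probe), stringsAsFactors = FALSE)
  links <- match_spacers(spacers, c(v1 = subj))
  expect_identical(nrow(links), 1L)
  expect_identical(links$strand, "-")
  expect_identical(links$start, 300L)
  expect_identical(links$end, 335L)
})

test_that("scanner equals the all-windows Hamming oracle", {
  seqs <- setNames(lapply(1:6, function(i) rand_seq(4000, i)),
                   sprintf("v%d", 1:6))
  seqs <- unlist(seqs)
  set.seed(77)
  spacers <- data.frame(
    host_contig_id = "h1",
    spacer_id = sprintf("s%02d", 1:8),
    sequence = vapply(1:8, function(i) {
      src <- sample(names(seqs), 1)
      at <- sample(3500, 1)
      w <- substr(seqs[[src]], at, at + sample(24:44, 1))
      ch <- strsplit(w, "")[[1]]
      d <- sample(0:2, 1)
      if (d > 0) {
        for (p in sample(2:(length(ch) - 1), d)) {
          ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
        }
      }
      out <- paste(ch, collapse = "")
      if (runif(1) < 0.5) revcomp(out) else out
    }, character(1)), stringsAsFactors = FALSE)
  links <- match_spacers(spacers, seqs)
  for (i in seq_len(nrow(spacers))) {
    L <- nchar(spacers$sequence[i])
    budget <- min(2, floor(0.05 * L + 1e-9))
    ora <- oracle_scan(spacers$sequence[i], seqs, budget)
    got <- links[links$query_id == spacers$spacer_id[i], ]
    expect_identical(nrow(got), nrow(ora))
    if (nrow(ora)) {
      key <- function(x) paste(x$virus_id, x$strand, x$start, x$mismatches)
      expect_setequal(key(got), key(ora))
    }
  }
})

test_that("strand symmetry: reverse-complementing a contig remaps positions", {
  subj <- rand_seq(1500, 9)
  probe <- substr(subj, 401, 430)
  spacers <- data.frame(host_contig_id = "h", spacer_id = "s",
                        sequence = probe, stringsAsFactors = FALSE)
  fwd <- match_spacers(spacers, c(v = subj))
  rev <- match_spacers(spacers, c(v = revcomp(subj)))
  expect_identical(nrow(fwd), nrow(rev))
  expect_identical(rev$strand, "-")
  expect_identical(rev$start, 1500L - fwd$end)
  expect_identical(rev$end, 1500L - fwd$start)
})

test_that("tRNA matching applies the 95% identity rule at full length", {
  subj <- rand_seq(3000, 4)
  base <- substr(subj, 1001, 1075)   # 75 nt
  mk_mm <- function(s, d) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(2:(length(ch) - 1), d)) {
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    paste(ch, collapse = "")
  }
  set.seed(11)
  trnas <- data.frame(host_contig_id = "h1",
                      trna_id = c("t0", "t3", "t4"),
                      sequence = c(base, mk_mm(base, 3), mk_mm(base, 4)),
                      stringsAsFactors = FALSE)
  links <- match_trnas(trnas, c(v1 = subj))
  expect_setequal(links$query_id, c("t0", "t3"))
  expect_equal(links$identity[links$query_id == "t0"], 100)
  expect_equal(links$identity[links$query_id == "t3"], 72 / 75 * 100)
})

test_that("homology filter keeps all printed boundaries inclusively", {
  mk <- function(identity, qcov, evalue, bits, len) {
    data.frame(virus_id = "v", host_id = "h", identity = identity,
               aln_length = len, mismatches = 0L, gapopens = 0L,
               query_cov = qcov, evalue = evalue, bitscore = bits,
               stringsAsFactors = FALSE)
  }
  expect_identical(nrow(filter_homology_hits(
    mk(70.0, 75.0, 1e-3, 50, 2500))), 1L)
  expect_identical(nrow(filter_homology_hits(
    mk(69.9, 99, 1e-10, 900, 5000))), 0L)
  expect_identical(nrow(filter_homology_hits(
    mk(85, 80, 1e-5, 100, 2499))), 0L)
  expect_identical(nrow(filter_homology_hits(
    mk(85, 74.9, 1e-5, 100, 5000))), 0L)
  expect_identical(nrow(filter_homology_hits(
    mk(85, 80, 2e-3, 100, 5000))), 0L)
  expect_identical(nrow(filter_homology_hits(
    mk(85, 80, 1e-5, 49.9, 5000))), 0L)
})

test_that("tabular homology input is validated and coverage derived", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hits.tsv")
  writeLines(c("v1\th1\t85.0\t3000\t450\t0\t101\t3100\t1\t3000\t1e-30\t4500",
               "v2\th2\t60.0\t3000\t1200\t0\t1\t3000\t1\t3000\t1e-30\t2000"),
             path)
  o6 <- read_outfmt6(path)
  hits <- outfmt6_to_hits(o6, c(v1 = 4000, v2 = 3000))
  expect_equal(hits$query_cov, c(3000 / 4000 * 100, 100))
  kept <- filter_homology_hits(hits)
  expect_identical(kept$virus_id, "v1")

  writeLines("v1\th1\tnot_a_number\t3000\t450\t0\t1\t3000\t1\t3000\t1e-30\t4500",
             path)
  expect_error(read_outfmt6(path), "line 1")
  expect_error(outfmt6_to_hits(o6, c(v1 = 4000)), "v2")
})

test_that("merge deduplicates, is idempotent, and classifies host range", {
  l1 <- data.frame(virus_id = c("v1", "v1"), host_id = c("h1", "h1"),
                   channel = c("spacer", "spacer"),
                   stringsAsFactors = FALSE)
  l2 <- data.frame(virus_id = c("v1", "v2", "v2"),
                   host_id = c("h1", "h2", "h3"),
                   channel = "homology", stringsAsFactors = FALSE)
  m <- merge_links(list(l1, l2))
  expect_identical(nrow(m$links), 3L)
  expect_identical(m$links$channels[m$links$virus_id == "v1"],
                   "homology,spacer")
  m2 <- merge_links(m$links)
  expect_identical(m2$links, m$links)

  tax <- data.frame(host_id = c("h1", "h2", "h3"),
                    phylum = c("Actinomycetota", "Pseudomonadota",
                               "Pseudomonadota"), stringsAsFactors = FALSE)
  hr <- merge_links(list(l1, l2), taxonomy = tax)$host_range
  expect_identical(hr$range_class[hr$virus_id == "v1"], "specialist")
  expect_identical(hr$range_class[hr$virus_id == "v2"], "specialist")
  hr2 <- merge_links(list(l1, l2))$host_range
  expect_identical(hr2$range_class[hr2$virus_id == "v2"], "generalist")
  expect_warning(merge_links(l2, taxonomy = tax[1:2, ]), "missing")
})

test_that("channels are independent: dropping one leaves the others unchanged", {
  sim <- generate_community(synth_config(seed = 15))
  vs <- sim$sequences[sim$viral_ids]
  lens <- setNames(sim$features$length, sim$features$contig_id)
  sp <- match_spacers(sim$spacers, vs)
  sp_again <- match_spacers(sim$spacers, vs)
  expect_identical(sp, sp_again)
  hom <- filter_homology_hits(outfmt6_to_hits(sim$homhits, lens))
  all3 <- merge_links(list(sp, match_trnas(sim$trnas, vs), hom))
  no_trna <- merge_links(list(sp, hom))
  spacer_pairs <- function(m) {
    k <- m$links[grepl("spacer", m$links$channels), ]
    sort(paste(k$virus_id, k$host_id))
  }
  expect_identical(spacer_pairs(all3), spacer_pairs(no_trna))
})
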