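# The generator must be deterministic, honour its planted fractions exactly,
# and produce truth tables consistent with the decision thresholds.

test_that("identical configs give bit-identical communities", {
  a <- generate_community(synth_config(seed = 11))
  b <- generate_community(synth_config(seed = 11))
  expect_identical(a, b)
  c <- generate_community(synth_config(seed = 12))
  expect_false(identical(a$sequences, c$sequences))
})

test_that("planted fractions are honoured exactly", {
  sim <- generate_community(synth_config(seed = 7, n_viral_contigs = 100,
                                         frac_lysogenic = 0.3))
  expect_identical(sum(sim$truth$contigs$is_lysogenic), 30L)
  expect_identical(sum(sim$truth$contigs$should_advance),
                   as.integer(round(0.4 * 100)))
})

test_that("planted protospacers sit in their contigs at the planned distance", {
  sim <- generate_community(synth_config(seed = 3))
  tr <- sim$truth$links[sim$truth$links$channel == "spacer", ]
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    sp <- sim$spacers$sequence[sim$spacers$spacer_id == row$query_id]
    window <- substr(sim$sequences[[row$virus_id]], row$start + 1, row$end)
    probe <- if (row$strand == "-") revcomp(sp) else sp
    d <- sum(utf8ToInt(window) != utf8ToInt(probe))
    expect_identical(d, as.integer(row$mismatches))
  }
  # 3-mismatch plants must be marked as failing the spacer channel
  expect_true(all(!tr$should_pass[tr$mismatches == 3]))
})

test_that("truth should_pass flags agree with literal threshold re-application", {
  sim <- generate_community(synth_config(seed = 19))
  lk <- sim$truth$links
  for (i in seq_len(nrow(lk))) {
    row <- lk[i, ]
    expected <- switch(row$channel,
      spacer = row$mismatches <= 2 && row$identity >= 95,
      trna = row$identity >= 95,
      homology = row$identity >= 70 && row$query_cov >= 75 &&
        row$evalue <= 1e-3 && row$bitscore >= 50 && row$length >= 2500)
    expect_identical(row$should_pass, expected,
                     info = paste(row$channel, i))
  }
  expect_identical(sim$truth$contigs$should_advance,
                   oracle_triage_advance(sim$features))
})

test_that("counts are multinomial at the requested depth", {
  # degenerate distribution puts every read on one contig
  truth <- list(abundance = matrix(c(1, 0), 2, 1,
                                   dimnames = list(c("a", "b"), "S1")))
  cts <- generate_counts(truth, depth = 1000, seed = 1)
  expect_equal(as.vector(cts), c(1000L, 0L))

  sim <- generate_community(synth_config(seed = 5))
  cts <- generate_counts(sim$truth, depth = 5e4, seed = 5)
  expect_true(all(colSums(cts) == 5e4))
  expect_identical(cts, generate_counts(sim$truth, depth = 5e4, seed = 5))
  expect_error(generate_counts(sim$truth, depth = 0, seed = 1), "positive")

  # at high depth the empirical proportions approach the planted ones:
  # every per-contig deviation within 4 SE, and on average well under 1 SE
  deep <- generate_counts(sim$truth, depth = 1e6, seed = 9)
  p <- sim$truth$abundance[, 1]
  phat <- deep[, 1] / 1e6
  se <- sqrt(p * (1 - p) / 1e6)
  expect_true(all(abs(phat - p) <= 4 * se + 1e-9))
  expect_lt(mean(abs(phat - p) / se), 1.5)
})

test_that("microcosm truth stores exact cumulative CO2 and qCO2", {
  micro <- generate_microcosm(synth_config(seed = 2))
  for (id in micro$truth$microcosm_id) {
    s <- micro$series[micro$series$microcosm_id == id, ]
    expect_equal(sum(s$co2_interval),
                 micro$truth$cumulative_total[
                   micro$truth$microcosm_id == id])
  }
  mbc <- micro$endpoint$mbc[match(micro$truth$microcosm_id,
                                  micro$endpoint$microcosm_id)]
  expect_equal(micro$truth$qco2, micro$truth$cumulative_total / (mbc * 35),
               tolerance = 1e-12)
  expect_error(generate_microcosm(synth_config(seed = 2),
                                  days = c(1, 3, 3, 7)),
               "strictly increasing")
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(frac_lysogenic = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(spacer_len_range = c(4L, 10L),
                            spacer_mismatch_plan = c(0L, 9L)),
               "infeasible")
  expect_error(synth_config(length_range = c(0L, 500L)), "length_range")
  expect_error(synth_config(read_depth = 0), "read_depth")
})

test_that("null communities are exchangeable by construction", {
  cts <- generate_null_counts(40, 12, 5000, seed = 21)
  expect_true(all(colSums(cts) == 5000))
  expect_identical(cts, generate_null_counts(40, 12, 5000, seed = 21))
})

test_that("written community files round-trip", {
  dir <- withr::local_tempdir()
  sim <- generate_community(synth_config(seed = 13))
  cts <- generate_counts(sim$truth, 1e4, seed = 13)
  write_community(sim, dir, counts = cts)
  seqs <- read_fasta(file.path(dir, "contigs.fna"))
  expect_identical(seqs[sim$viral_ids], sim$sequences[sim$viral_ids])
  o6 <- read_outfmt6(file.path(dir, "homhits.tsv"))
  expect_equal(o6$pident, sim$homhits$pident)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
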