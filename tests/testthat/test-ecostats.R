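# Closed-form checks for the abundance and diversity formulas, agreement
# with the independent ecology toolkit, permutation-test behaviour, and the
# Duncan letter display.

test_that("RPKM matches its closed form and conservation identity", {
  cts <- matrix(10, 1, 1, dimnames = list("c1", "S1"))
  expect_equal(rpkm(cts, lengths = 2000, totals = 1e6)[1, 1], 5.0)
  expect_equal(rpkm(matrix(0, 1, 1), lengths = 500, totals = 1000)[1, 1], 0)

  set.seed(3)
  cts <- matrix(rpois(60, 40), 10, 6,
                dimnames = list(sprintf("c%d", 1:10), sprintf("S%d", 1:6)))
  lens <- sample(1000:9000, 10)
  tot <- colSums(cts) + sample(100:500, 6)
  r <- rpkm(cts, lens, tot)
  # sum_i rpkm * (len/1e3) == 1e6 * colsum/total
  expect_equal(colSums(r * (lens / 1e3)), 1e6 * colSums(cts) / tot)
  expect_error(rpkm(cts, lens, c(tot[-6], 0)), "S6")
})

test_that("Shannon and Bray-Curtis match hand-computed values and vegan", {
  m <- matrix(c(1, 1, 1, 1), 4, 1, dimnames = list(NULL, "S1"))
  expect_equal(shannon_diversity(m)$shannon, log(4))

  two <- matrix(c(1, 1, 1, 3), 2, 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(as.vector(bray_curtis(two)), 1 - 4 / 6)

  same <- matrix(c(2, 5, 2, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.vector(bray_curtis(same)), 0)
  disj <- matrix(c(3, 0, 0, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.vector(bray_curtis(disj)), 1)

  set.seed(10)
  cm <- matrix(rpois(80, 15), 16, 5,
               dimnames = list(NULL, sprintf("S%d", 1:5)))
  expect_equal(shannon_diversity(cm)$shannon,
               unname(vegan::diversity(t(cm), index = "shannon")))
  expect_equal(as.vector(bray_curtis(cm)),
               as.vector(vegan::vegdist(t(cm), method = "bray")))

  zz <- cbind(cm, S6 = 0)
  expect_warning(d <- bray_curtis(zz), "all-zero")
  expect_true(all(as.matrix(d)["S6", -6] == 1))
})

test_that("ANOSIM statistic matches vegan and hits the extreme case", {
  # two tight groups far apart: every between-distance beats every
  # within-distance, so R = 1
  x <- rbind(matrix(rnorm(12, 0, 0.01), 3), matrix(rnorm(12, 10, 0.01), 3))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g, nperm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_true(res$p.value >= 1 / 100 && res$p.value <= 1)

  set.seed(77)
  y <- matrix(rnorm(40), 8, 5)
  dy <- dist(y)
  gy <- rep(c("a", "b"), each = 4)
  expect_equal(anosim_test(dy, gy, nperm = 9, seed = 1)$statistic,
               unname(vegan::anosim(dy, gy, permutations = 9)$statistic))
  expect_equal(anosim_test(dy, gy, nperm = 9, seed = 1)$statistic,
               oracle_anosim_R(dy, gy))

  # rank-based: invariant under strictly monotone distance transforms
  expect_equal(anosim_test(dy^2, gy, nperm = 9, seed = 1)$statistic,
               anosim_test(dy, gy, nperm = 9, seed = 1)$statistic)

  expect_error(anosim_test(dy, rep("a", 8)), "two groups")
  expect_error(anosim_test(dy, c("a", rep("b", 7))), "two samples")
})

test_that("ANOSIM permutation p approaches the exact enumeration value", {
  set.seed(123)
  x <- matrix(rnorm(18), 6, 3)
  x[4:6, ] <- x[4:6, ] + 0.8
  d <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  p_exact <- oracle_anosim_exact_p(d, g)
  res <- anosim_test(d, g, nperm = 999, seed = 42)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p.value - p_exact), 3 * se + 2 / 999)
})

test_that("Mantel r behaves as a rank correlation of distance triangles", {
  set.seed(5)
  x <- matrix(rnorm(30), 6, 5)
  d1 <- dist(x)
  expect_equal(mantel_test(d1, d1, nperm = 9, seed = 1)$statistic, 1)
  expect_equal(mantel_test(d1, d1^3, nperm = 9, seed = 1)$statistic, 1)

  d2 <- dist(matrix(rnorm(30), 6, 5))
  expect_equal(mantel_test(d1, d2, nperm = 19, seed = 1)$statistic,
               unname(vegan::mantel(d1, d2, method = "spearman",
                                    permutations = 19)$statistic))
  expect_warning(res <- mantel_test(d1, dist(matrix(1, 6, 2))), "constant")
  expect_true(is.na(res$statistic))
})

test_that("correlation network applies strict thresholds over BH-adjusted p", {
  set.seed(21)
  n <- 12
  base <- rnorm(n)
  x <- cbind(f1 = base, f2 = base,            # exact copy: r = 1
             f3 = rnorm(n), f4 = rnorm(n))
  net <- corr_network(x)
  expect_true(any(net$edges$feature1 == "f1" & net$edges$feature2 == "f2"))

  # |r| equal to the threshold is excluded (strict >)
  expect_identical(nrow(corr_network(x, r_threshold = 1)$edges), 0L)

  cst <- cbind(x, f5 = 1)
  expect_warning(corr_network(cst), "constant")

  # brute-force equality on a block-correlated panel
  set.seed(9)
  z <- rnorm(n)
  panel <- cbind(a = z + rnorm(n, 0, 0.05), b = z + rnorm(n, 0, 0.05),
                 c = -z + rnorm(n, 0, 0.05), d = rnorm(n), e = rnorm(n))
  got <- corr_network(panel)$edges
  ora <- oracle_network_edges(panel)
  key <- function(df) paste(df$feature1, df$feature2)
  expect_setequal(key(got), key(ora))
})

test_that("cumulative CO2 is a prefix sum and qCO2 its closed form", {
  expect_equal(cumulative_co2(c(1, 2, 3)), c(1, 3, 6))
  expect_equal(cumulative_co2(rep(0, 5)), rep(0, 5))
  expect_error(cumulative_co2(c(1, -0.1)), "negative")
  expect_error(cumulative_co2(c(1, 2), days = c(3, 3)), "strictly")

  expect_equal(qco2(2, 0.1, 35), 2 / (0.1 * 35))
  expect_equal(qco2(2, 0.2, 35), qco2(2, 0.1, 35) / 2)
  expect_warning(res <- qco2(2, 0, 35), "MBC")
  expect_true(is.na(res))

  micro <- generate_microcosm(synth_config(seed = 4))
  s1 <- micro$series[micro$series$microcosm_id ==
                       micro$truth$microcosm_id[1], ]
  cum <- cumulative_co2(s1$co2_interval, s1$day)
  expect_equal(cum[length(cum)], micro$truth$cumulative_total[1],
               tolerance = 1e-12)
  mbc1 <- micro$endpoint$mbc[micro$endpoint$microcosm_id ==
                               micro$truth$microcosm_id[1]]
  expect_equal(qco2(cum[length(cum)], mbc1, 35), micro$truth$qco2[1],
               tolerance = 1e-12)
})

test_that("Duncan letters separate what the range test separates", {
  set.seed(14)
  vals <- c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1), rnorm(5, 10, 0.1))
  grp <- rep(c("lo", "mid", "hi"), each = 5)
  res <- group_compare(vals, grp)
  expect_identical(length(unique(res$letters)), 3L)
  expect_lt(res$p.value, 1e-6)

  # pairwise oracle: every pair's separation decision matches the letters
  means <- res$means
  ordm <- sort(means, decreasing = TRUE)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      span <- j - i + 1
      sep <- unname(oracle_duncan_separated(ordm[i], ordm[j], span, res$mse,
                                            5, 12))
      share <- any(strsplit(res$letters[names(ordm)[i]], "")[[1]] %in%
                     strsplit(res$letters[names(ordm)[j]], "")[[1]])
      expect_identical(sep, !share)
    }
  }

  same <- c(rnorm(6, 1, 0.5), rnorm(6, 1, 0.5))
  res2 <- group_compare(same, rep(c("a", "b"), each = 6))
  expect_identical(unname(res2$letters), c("a", "a"))

  tt <- group_compare(c(rnorm(6), rnorm(6, 3)), rep(c("x", "y"), each = 6),
                      method = "ttest")
  expect_lt(tt$p.value, 0.01)
  expect_match(tt$method, "Welch")
  expect_error(group_compare(rnorm(9), rep(c("a", "b", "c"), 3),
                             method = "ttest"), "two groups")
})
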