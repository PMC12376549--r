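# Community and microcosm statistics: RPKM, alpha diversity, Bray-Curtis,
# ANOSIM and Mantel permutation tests, Spearman correlation networks with
# FDR edge filtering, cumulative CO2, the microbial metabolic quotient qCO2,
# and group comparisons (one-way ANOVA with Duncan letters, t-tests).

#' Reads per kilobase per million mapped reads
#'
#' rpkm\[i, s\] = counts\[i, s\] / (length\[i\]/1e3) / (total\[s\]/1e6).
#'
#' @param counts numeric matrix, contigs (rows) x samples (columns).
#' @param lengths contig lengths in bp, recycled by row; named vectors are
#'   matched to row names.
#' @param totals per-sample mapped-read totals; defaults to column sums.
#' @return RPKM matrix with the dimnames of `counts`.
#' @export
rpkm <- function(counts, lengths, totals = colSums(counts)) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            length(totals) == ncol(counts))
  zero <- totals <= 0
  if (any(zero)) {
    stop("zero mapped-read total for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(counts / (lengths / 1e3), 2L, totals / 1e6, "/")
}

#' Shannon diversity and richness per sample
#'
#' H = -sum p_i ln p_i over nonzero proportions; natural log. All-zero
#' samples get missing H with a warning.
#'
#' @param m nonnegative matrix, taxa (rows) x samples (columns).
#' @return data frame with `sample_id`, `richness`, `shannon`.
#' @export
shannon_diversity <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("all-zero sample(s), Shannon undefined: ",
            paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  H <- vapply(seq_len(ncol(m)), function(s) {
    if (tot[s] == 0) return(NA_real_)
    p <- m[, s] / tot[s]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  data.frame(sample_id = colnames(m),
             richness = colSums(m > 0),
             shannon = H,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(u, v) = 1 - 2 sum min(u_i, v_i) / sum (u_i + v_i). Pairs involving an
#' all-zero sample are set to 1 by convention (warned).
#'
#' @param m nonnegative matrix, taxa (rows) x samples (columns).
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  n <- ncol(m)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("all-zero sample(s), distances set to 1: ",
            paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      den <- tot[i] + tot[j]
      d <- if (tot[i] == 0 || tot[j] == 0) 1 else
        1 - 2 * sum(pmin(m[, i], m[, j])) / den
      D[i, j] <- D[j, i] <- d
    }
  }
  stats::as.dist(D)
}

# Lower-triangle pair indices in the storage order of a dist vector.
.pair_index <- function(n) {
  j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2), with
#' ranks over all pairwise distances and M = n(n-1)/2. The p-value is
#' (1 + #\{R* >= R_obs\}) / (1 + nperm) over label permutations (add-one
#' rule, so p is never exactly 0).
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param groups group labels, one per sample; >= 2 groups of >= 2 samples.
#' @param nperm number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list with `statistic` (R), `p.value`, `nperm`, `perm_stats`.
#' @export
anosim_test <- function(d, groups, nperm = 999, seed = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  stopifnot(length(groups) == n)
  tab <- table(droplevels(groups))
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  r <- rank(as.vector(d))
  M <- n * (n - 1) / 2
  ij <- .pair_index(n)
  stat_for <- function(g) {
    within <- g[ij[, 1L]] == g[ij[, 2L]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- stat_for(groups)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(nperm), function(k) stat_for(sample(groups)),
                 numeric(1))
  list(statistic = R_obs,
       p.value = (1 + sum(perm >= R_obs)) / (1 + nperm),
       nperm = nperm,
       perm_stats = perm)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) of the two lower triangles; the p-value
#' permutes one matrix's sample order, one-sided (r* >= r_obs), add-one rule.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples
#'   (matched by name when both are named).
#' @param nperm permutations (default 999).
#' @param method correlation method (default `"spearman"`).
#' @param seed optional integer seed.
#' @return list with `statistic` (r), `p.value`, `nperm`, `perm_stats`;
#'   `statistic` is `NA` when a triangle is constant.
#' @export
mantel_test <- function(d1, d2, nperm = 999, method = "spearman",
                        seed = NULL) {
  m1 <- as.matrix(stats::as.dist(d1))
  m2 <- as.matrix(stats::as.dist(d2))
  stopifnot(nrow(m1) == nrow(m2))
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    stopifnot(setequal(rownames(m1), rownames(m2)))
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (stats::sd(v1) == 0 || stats::sd(m2[lt]) == 0) {
    warning("constant distance triangle, Mantel r undefined", call. = FALSE)
    return(list(statistic = NA_real_, p.value = NA_real_, nperm = nperm,
                perm_stats = numeric(0)))
  }
  r_obs <- stats::cor(v1, m2[lt], method = method)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(nperm), function(k) {
    p <- sample.int(n)
    stats::cor(v1, m2[p, p][lt], method = method)
  }, numeric(1))
  list(statistic = r_obs,
       p.value = (1 + sum(perm >= r_obs)) / (1 + nperm),
       nperm = nperm,
       perm_stats = perm)
}

#' Spearman co-occurrence network with FDR-thresholded edges
#'
#' All pairwise Spearman correlations between features (columns); p-values
#' from the t approximation on rho (as the usual correlation-matrix tools),
#' Benjamini-Hochberg adjusted across the full pairwise family. An edge is
#' kept iff |r| > `r_threshold` AND adjusted p < `q_threshold` (both strict,
#' as printed). Constant features are dropped with a warning.
#'
#' @param x numeric matrix, samples (rows) x features (columns); >= 4 rows.
#' @param r_threshold correlation magnitude threshold (default 0.7).
#' @param q_threshold adjusted-p threshold (default 0.01).
#' @return list with `edges` (feature1, feature2, r, p, q of kept edges) and
#'   `all_pairs` (the full pair table).
#' @export
corr_network <- function(x, r_threshold = 0.7, q_threshold = 0.01) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 4L)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  cst <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(cst)) {
    warning("constant feature(s) dropped: ",
            paste(colnames(x)[cst], collapse = ", "), call. = FALSE)
    x <- x[, !cst, drop = FALSE]
  }
  p_feat <- ncol(x)
  if (p_feat < 2L) stop("need at least two non-constant features",
                        call. = FALSE)
  n <- nrow(x)
  rho <- stats::cor(x, method = "spearman")
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[upper.tri(rho)]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  all_pairs <- data.frame(feature1 = colnames(x)[iu[, 1L]],
                          feature2 = colnames(x)[iu[, 2L]],
                          r = r, p = p, q = q,
                          stringsAsFactors = FALSE)
  keep <- abs(all_pairs$r) > r_threshold & all_pairs$q < q_threshold
  edges <- all_pairs[keep, , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, all_pairs = all_pairs)
}

#' Cumulative CO2-C from interval trap amounts
#'
#' Alkali traps integrate respiration over each sampling interval, so the
#' cumulative trajectory is the prefix sum of the interval amounts (no
#' interpolation).
#'
#' @param intervals nonnegative interval-trapped CO2-C amounts.
#' @param days optional strictly increasing sampling-day grid.
#' @return numeric cumulative trajectory (same length as `intervals`).
#' @export
cumulative_co2 <- function(intervals, days = NULL) {
  if (any(intervals < 0)) stop("negative interval amount", call. = FALSE)
  if (!is.null(days)) {
    stopifnot(length(days) == length(intervals))
    if (any(diff(days) <= 0)) {
      stop("sampling days must be strictly increasing", call. = FALSE)
    }
  }
  cumsum(intervals)
}

#' Microbial metabolic quotient qCO2
#'
#' qCO2 = cumulative CO2-C / (MBC x duration), in mg CO2-C per mg microbial
#' biomass C per day. Non-positive MBC yields missing values with a warning.
#'
#' @param cumulative cumulative CO2-C (mg per unit soil).
#' @param mbc microbial biomass C (same soil basis).
#' @param duration incubation length in days.
#' @return numeric vector of quotients.
#' @export
qco2 <- function(cumulative, mbc, duration) {
  stopifnot(all(duration > 0))
  bad <- !is.na(mbc) & mbc <= 0
  if (any(bad)) {
    warning("non-positive MBC, qCO2 undefined for ", sum(bad), " value(s)",
            call. = FALSE)
  }
  ifelse(!is.na(mbc) & mbc > 0, cumulative / (mbc * duration), NA_real_)
}

#' Duncan's multiple range test letters
#'
#' Critical ranges use studentized-range quantiles at the stepwise
#' protection levels 1 - (1 - alpha)^(p - 1) for a span of p ordered means,
#' with the error mean square and degrees of freedom from a one-way ANOVA
#' and the harmonic mean of the group sizes. A range contained in a
#' non-significant wider range is never declared significant. Groups sharing
#' a letter are not separated.
#'
#' @param means named vector of group means.
#' @param n_per_group group sizes (same order as `means`).
#' @param mse ANOVA error mean square.
#' @param df_error error degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @param method `"duncan"` (default) or `"tukey"` (single HSD critical
#'   range at level alpha).
#' @return named character vector of compact letters.
#' @export
duncan_letters <- function(means, n_per_group, mse, df_error, alpha = 0.05,
                           method = c("duncan", "tukey")) {
  method <- match.arg(method)
  k <- length(means)
  stopifnot(k >= 2L, length(n_per_group) == k)
  nh <- k / sum(1 / n_per_group)
  se <- sqrt(mse / nh)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  crit <- vapply(2:k, function(p) {
    lvl <- if (method == "duncan") (1 - alpha)^(p - 1) else 1 - alpha
    nm <- if (method == "duncan") p else k
    stats::qtukey(lvl, nm, df_error) * se
  }, numeric(1))

  # Significance of each ordered range, with containment protection: spans
  # are processed widest first and a subrange of a non-significant range is
  # forced non-significant.
  sig <- matrix(FALSE, k, k)
  nonsig_cover <- matrix(FALSE, k, k)  # inside a non-significant wider range
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      s <- (m[i] - m[j]) > crit[span - 1L] && !nonsig_cover[i, j]
      sig[i, j] <- s
      if (!s) {
        nonsig_cover[i:j, i:j][upper.tri(matrix(TRUE, span, span))] <- TRUE
      }
    }
  }

  # Letters from maximal non-significant intervals of the ordered means.
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !sig[i, j + 1L]) j <- j + 1L
    intervals[[i]] <- c(i, j)
  }
  intervals <- unique(intervals)
  maximal <- Filter(function(iv) {
    !any(vapply(intervals, function(o) {
      (o[1] <= iv[1] && iv[2] <= o[2]) && !identical(o, iv)
    }, logical(1)))
  }, intervals)
  maximal <- maximal[order(vapply(maximal, `[`, numeric(1), 1L))]

  letters_out <- rep("", k)
  for (li in seq_along(maximal)) {
    iv <- maximal[[li]]
    idx <- iv[1]:iv[2]
    letters_out[idx] <- paste0(letters_out[idx], letters[li])
  }
  res <- setNames(rep("", k), names(means))
  res[ord] <- letters_out
  res
}

#' Group comparison: one-way ANOVA with Duncan letters, or a t-test
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param method `"anova_duncan"` (default) or `"ttest"` (two groups).
#' @param alpha significance level for the letter display (default 0.05).
#' @param var_equal pooled (`TRUE`) or Welch (`FALSE`, default) t-test.
#' @param letters_method passed to [duncan_letters()].
#' @return list; for ANOVA: `method`, `statistic` (F), `p.value`, `df`,
#'   `means`, `letters`; for the t-test: `method`, `statistic`, `p.value`,
#'   `means`.
#' @export
group_compare <- function(values, groups, method = c("anova_duncan", "ttest"),
                          alpha = 0.05, var_equal = FALSE,
                          letters_method = "duncan") {
  method <- match.arg(method)
  g <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(g))
  means <- tapply(values, g, mean)
  if (method == "ttest") {
    if (nlevels(g) != 2L) stop("t-test needs exactly two groups",
                               call. = FALSE)
    tt <- stats::t.test(values ~ g, var.equal = var_equal)
    return(list(method = if (var_equal) "t-test (pooled)" else
                  "t-test (Welch)",
                statistic = unname(tt$statistic),
                p.value = tt$p.value,
                means = means))
  }
  if (nlevels(g) < 2L) stop("ANOVA needs at least two groups", call. = FALSE)
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2L]
  dfe <- an[["Df"]][2L]
  lt <- if (mse > 0) {
    duncan_letters(means, as.vector(table(g)), mse, dfe, alpha = alpha,
                   method = letters_method)
  } else {
    # zero within-group variance everywhere: separated iff means differ
    if (length(unique(means)) == 1L) setNames(rep("a", nlevels(g)),
                                              levels(g))
    else setNames(letters[rank(-means, ties.method = "min")], levels(g))
  }
  list(method = "one-way ANOVA + Duncan",
       statistic = an[["F value"]][1L],
       p.value = an[["Pr(>F)"]][1L],
       df = an[["Df"]],
       means = means,
       mse = mse,
       letters = lt)
}
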