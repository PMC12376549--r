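# Independent brute-force oracles. These re-state the decision rules in the
# most literal possible form, separate from the package implementations, so
# that agreement is evidence and not tautology.

# Triage: direct evaluation of every printed inequality, one contig at a
# time, plain arithmetic.
oracle_triage_advance <- function(features) {
  vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    primary <- (f$detector_score >= 0.5) &&
      !(f$completeness < 50) && !(f$contamination > 10)
    if (f$n_genes <= 0) return(FALSE)
    c1 <- (f$n_vpf_hit_genes >= 5) &&
      (f$n_kegg_genes / f$n_genes < 0.20) &&
      (f$n_pfam_genes / f$n_genes <= 0.40)
    c2 <- (f$n_vpf_hit_genes >= f$n_pfam_genes) &&
      (f$n_vpf_hit_genes / f$n_genes >= 0.60)
    primary && c1 && c2 && (f$length > 5000)
  }, logical(1))
}

# Spacer/tRNA scan: every window x both strands x per-window Hamming count,
# with an explicit per-position loop over a pre-encoded subject.
oracle_scan <- function(pattern, sequences, budget) {
  rc_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  rows <- list()
  for (sid in names(sequences)) {
    s <- utf8ToInt(sequences[[sid]])
    for (strand in c("+", "-")) {
      p <- utf8ToInt(if (strand == "+") pattern else rc_chr(pattern))
      L <- length(p)
      if (L > length(s)) next
      for (st in seq_len(length(s) - L + 1L)) {
        d <- sum(s[st:(st + L - 1L)] != p)
        if (d <= budget) {
          rows[[length(rows) + 1L]] <- data.frame(
            virus_id = sid, strand = strand, start = st - 1L,
            end = st - 1L + L, mismatches = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(virus_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# ANOSIM R computed from first principles for a given labelling.
oracle_anosim_R <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  pairs <- t(combn(n, 2))
  dist_vals <- m[pairs]
  r <- rank(dist_vals)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(r[!within]) - mean(r[within])) / (length(r) / 2)
}

# Exact ANOSIM permutation p for two groups: enumerate every distinct
# assignment of the labels to positions.
oracle_anosim_exact_p <- function(d, groups) {
  n <- length(groups)
  g1 <- sum(groups == unique(groups)[1])
  obs <- oracle_anosim_R(d, groups)
  assignments <- combn(n, g1)
  stats <- apply(assignments, 2, function(idx) {
    g <- rep("B", n)
    g[idx] <- "A"
    oracle_anosim_R(d, g)
  })
  mean(stats >= obs - 1e-12)
}

# Duncan's range decision for a single pair in a k-group balanced design,
# computed directly from the definition (no letter algorithm).
oracle_duncan_separated <- function(mi, mj, span, mse, n_per, df_error,
                                    alpha = 0.05) {
  crit <- qtukey((1 - alpha)^(span - 1), span, df_error) * sqrt(mse / n_per)
  abs(mi - mj) > crit
}

# Edge set of the correlation network by literal threshold re-evaluation.
oracle_network_edges <- function(x, r_thr = 0.7, q_thr = 0.01) {
  nms <- colnames(x)
  n <- nrow(x)
  combos <- t(combn(ncol(x), 2))
  r <- apply(combos, 1, function(ij) {
    cor(x[, ij[1]], x[, ij[2]], method = "spearman")
  })
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  q <- p.adjust(p, "BH")
  keep <- abs(r) > r_thr & q < q_thr
  data.frame(feature1 = nms[combos[keep, 1]], feature2 = nms[combos[keep, 2]],
             stringsAsFactors = FALSE)
}

# Small random feature table spanning typical (non-boundary) values.
random_features <- function(n, seed = 42) {
  local_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  local_seed({
    ng <- sample(5:40, n, replace = TRUE)
    data.frame(
      contig_id = sprintf("c%03d", seq_len(n)),
      length = sample(2000:12000, n, replace = TRUE),
      n_genes = ng,
      n_vpf_hit_genes = vapply(ng, function(k) sample(0:k, 1), integer(1)),
      n_kegg_genes = vapply(ng, function(k) sample(0:k, 1), integer(1)),
      n_pfam_genes = vapply(ng, function(k) sample(0:k, 1), integer(1)),
      detector_score = round(runif(n), 2),
      completeness = round(runif(n, 0, 100), 1),
      contamination = round(runif(n, 0, 20), 1),
      stringsAsFactors = FALSE)
  })
}
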