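# Virus-host linking by three evidence channels: CRISPR spacer matching
# (native ungapped scan), tRNA matching, and filtering of tabular genomic
# homology hits; plus merging/deduplication and host-range summary.
#
# Spacer and tRNA matching are ungapped (Hamming) on both strands; the
# printed "two SNPs" reads as substitutions. BLAST-style e-values are not
# reproduced for these short-query channels: the e-value cutoff is subsumed
# by the identity/mismatch rule at these query lengths.

# All (including overlapping) exact occurrence starts of `chunk` in
# `subject`. gregexpr skips overlaps, so positions within chunk length of a
# reported match are re-checked explicitly; every overlapped occurrence
# starts within chunk length of a reported one, so this is exhaustive.
find_all_occurrences <- function(subject, chunk) {
  m <- gregexpr(chunk, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  cl <- nchar(chunk)
  cand <- unique(as.vector(outer(as.integer(m), 0:(cl - 1L), "+")))
  cand <- cand[cand + cl - 1L <= nchar(subject)]
  sort(cand[substring(subject, cand, cand + cl - 1L) == chunk])
}

# Scan one pattern over sequences on both strands under a mismatch budget by
# seed-and-verify: a window with <= budget mismatches must contain one of
# budget+1 pattern chunks exactly (pigeonhole), so candidate starts come from
# exact chunk search and only those windows are Hamming-verified.
# Coordinates are 0-based half-open on the forward strand.
scan_pattern <- function(pattern, sequences, seq_ints, budget) {
  L <- nchar(pattern)
  budget <- min(budget, L - 1L)
  pats <- c("+" = pattern, "-" = revcomp(pattern))
  n_chunk <- as.integer(budget) + 1L
  bounds <- as.integer(floor(seq(0L, L, length.out = n_chunk + 1L)))
  out <- vector("list", 2L * length(sequences))
  k <- 0L
  for (sid in names(sequences)) {
    subj <- sequences[[sid]]
    subj_int <- seq_ints[[sid]]
    n_win <- length(subj_int) - L + 1L
    if (n_win < 1L) next
    for (strand in c("+", "-")) {
      pat <- pats[[strand]]
      pat_int <- utf8ToInt(pat)
      cand <- unlist(lapply(seq_len(n_chunk), function(ci) {
        off <- bounds[ci]
        chunk <- substr(pat, off + 1L, bounds[ci + 1L])
        find_all_occurrences(subj, chunk) - off
      }))
      cand <- unique(cand[cand >= 1L & cand <= n_win])
      if (!length(cand)) next
      d <- vapply(cand, function(s0) {
        sum(subj_int[s0:(s0 + L - 1L)] != pat_int)
      }, numeric(1))
      hit <- d <= budget
      if (any(hit)) {
        k <- k + 1L
        ord <- order(cand[hit])
        out[[k]] <- data.frame(virus_id = sid,
                               strand = strand,
                               start = cand[hit][ord] - 1L,
                               end = cand[hit][ord] - 1L + L,
                               mismatches = as.integer(d[hit][ord]),
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

check_alphabet <- function(x, what) {
  bad <- grepl("[^ACGT]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s with invalid alphabet (A/C/G/T only): %s", what,
                 paste(utils::head(which(bad)), collapse = ", ")),
         call. = FALSE)
  }
}

.empty_links <- function() {
  data.frame(virus_id = character(0), host_id = character(0),
             channel = character(0), query_id = character(0),
             identity = numeric(0), mismatches = integer(0),
             strand = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Match CRISPR spacers against viral contigs
#'
#' Every viral contig is scanned on both strands for ungapped windows of
#' spacer length. Under the default conjunctive rule a window qualifies when
#' its Hamming distance d satisfies both d <= `max_mismatch` and identity
#' (L - d)/L >= `min_identity`, i.e. an effective budget of
#' min(`max_mismatch`, floor((1 - `min_identity`) L)). The two printed
#' thresholds are in tension for short spacers (2 mismatches in a 30-nt
#' spacer is only 93.3% identity); `rule = "union"` applies either threshold
#' alone.
#'
#' @param spacers data frame with `host_contig_id`, `spacer_id`, `sequence`
#'   (A/C/G/T, >= 20 nt).
#' @param sequences named character vector of viral contigs.
#' @param max_mismatch maximum substitutions (default 2).
#' @param min_identity minimum identity fraction (default 0.95).
#' @param rule `"intersect"` (default) or `"union"` of the two thresholds.
#' @return link table: `virus_id`, `host_id`, `channel = "spacer"`,
#'   `query_id`, `identity` (percent), `mismatches`, `strand`, `start`,
#'   `end` (0-based half-open, forward strand).
#' @export
match_spacers <- function(spacers, sequences, max_mismatch = 2,
                          min_identity = 0.95,
                          rule = c("intersect", "union")) {
  rule <- match.arg(rule)
  check_columns(spacers, c("host_contig_id", "spacer_id", "sequence"),
                "spacers")
  check_alphabet(spacers$sequence, "spacer sequence(s)")
  sequences <- setNames(toupper(sequences), names(sequences))
  seq_ints <- lapply(sequences, utf8ToInt)
  out <- vector("list", nrow(spacers))
  for (i in seq_len(nrow(spacers))) {
    seq_i <- toupper(spacers$sequence[i])
    L <- nchar(seq_i)
    ident_budget <- floor((1 - min_identity) * L + 1e-9)
    budget <- if (rule == "intersect") min(max_mismatch, ident_budget) else
      max(max_mismatch, ident_budget)
    hits <- scan_pattern(seq_i, sequences, seq_ints, budget)
    if (!is.null(hits)) {
      hits$host_id <- spacers$host_contig_id[i]
      hits$query_id <- spacers$spacer_id[i]
      hits$channel <- "spacer"
      hits$identity <- (L - hits$mismatches) / L * 100
      out[[i]] <- hits
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_links())
  res <- do.call(rbind, out)
  res[, names(.empty_links())]
}

#' Match tRNA sequences against viral contigs
#'
#' Full-length ungapped windows on either strand at identity >=
#' `min_identity`.
#'
#' @param trnas data frame with `host_contig_id`, `trna_id`, `sequence`.
#' @param sequences named character vector of viral contigs.
#' @param min_identity minimum identity fraction (default 0.95).
#' @return link table as in [match_spacers()], `channel = "trna"`.
#' @export
match_trnas <- function(trnas, sequences, min_identity = 0.95) {
  check_columns(trnas, c("host_contig_id", "trna_id", "sequence"), "trnas")
  check_alphabet(trnas$sequence, "tRNA sequence(s)")
  sequences <- setNames(toupper(sequences), names(sequences))
  seq_ints <- lapply(sequences, utf8ToInt)
  out <- vector("list", nrow(trnas))
  for (i in seq_len(nrow(trnas))) {
    seq_i <- toupper(trnas$sequence[i])
    L <- nchar(seq_i)
    budget <- floor((1 - min_identity) * L + 1e-9)
    hits <- scan_pattern(seq_i, sequences, seq_ints, budget)
    if (!is.null(hits)) {
      hits$host_id <- trnas$host_contig_id[i]
      hits$query_id <- trnas$trna_id[i]
      hits$channel <- "trna"
      hits$identity <- (L - hits$mismatches) / L * 100
      out[[i]] <- hits
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_links())
  res <- do.call(rbind, out)
  res[, names(.empty_links())]
}

#' Read 12-column tabular homology hits (BLAST outfmt-6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Malformed rows raise an error naming the line.
#'
#' @param path TSV file without header.
#' @return data frame with the standard column names.
#' @export
read_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(x), call. = FALSE)
  }
  names(x) <- cols
  num <- cols[-(1:2)]
  for (cc in num) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    if (anyNA(v) && !anyNA(x[[cc]])) {
      stop(sprintf("malformed value in column %s, line %d", cc,
                   which(is.na(v))[1]), call. = FALSE)
    }
    x[[cc]] <- v
  }
  x
}

#' Convert tabular homology hits to the filterable hit form
#'
#' Adds query coverage ((qend - qstart + 1) / query length, percent) using
#' the supplied query (virus) lengths.
#'
#' @param o6 data frame from [read_outfmt6()].
#' @param query_lengths named integer vector of virus contig lengths.
#' @return data frame with `virus_id`, `host_id`, `identity`, `aln_length`,
#'   `mismatches`, `gapopens`, `query_cov`, `evalue`, `bitscore`.
#' @export
outfmt6_to_hits <- function(o6, query_lengths) {
  missing <- setdiff(unique(o6$qseqid), names(query_lengths))
  if (length(missing)) {
    stop("no query length for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  qlen <- query_lengths[o6$qseqid]
  data.frame(virus_id = o6$qseqid, host_id = o6$sseqid,
             identity = o6$pident, aln_length = o6$length,
             mismatches = o6$mismatch, gapopens = o6$gapopen,
             query_cov = (abs(o6$qend - o6$qstart) + 1) / qlen * 100,
             evalue = o6$evalue, bitscore = o6$bitscore,
             stringsAsFactors = FALSE)
}

#' Filter genomic homology hits into host links
#'
#' Keeps hits with identity >= 70%, query coverage >= 75%, e-value <= 1e-3,
#' bit score >= 50 and alignment length >= 2500 bp; all bounds inclusive as
#' printed.
#'
#' @param hits data frame from [outfmt6_to_hits()] (columns `virus_id`,
#'   `host_id`, `identity`, `query_cov`, `evalue`, `bitscore`, `aln_length`).
#' @param min_identity,min_query_cov,max_evalue,min_bitscore,min_aln_length
#'   the five thresholds.
#' @return link table with `channel = "homology"` and the hit statistics.
#' @export
filter_homology_hits <- function(hits, min_identity = 70, min_query_cov = 75,
                                 max_evalue = 1e-3, min_bitscore = 50,
                                 min_aln_length = 2500) {
  check_columns(hits, c("virus_id", "host_id", "identity", "query_cov",
                        "evalue", "bitscore", "aln_length"), "hits")
  keep <- hits$identity >= min_identity &
    hits$query_cov >= min_query_cov &
    hits$evalue <= max_evalue &
    hits$bitscore >= min_bitscore &
    hits$aln_length >= min_aln_length
  kept <- hits[keep, , drop = FALSE]
  if (!nrow(kept)) return(.empty_links())
  data.frame(virus_id = kept$virus_id, host_id = kept$host_id,
             channel = "homology",
             query_id = NA_character_,
             identity = kept$identity,
             mismatches = as.integer(kept$mismatches),
             strand = NA_character_,
             start = NA_integer_, end = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Merge host links across channels and summarize host range
#'
#' Deduplicates to one row per (virus, host) pair with the sorted set of
#' supporting channels; idempotent (merging a merged table is a no-op).
#' Host range per virus is computed at the chosen taxonomic rank when a
#' taxonomy is supplied, else at host-contig level (with a warning if a
#' taxonomy was supplied but misses hosts).
#'
#' @param links one link table or a list of link tables (from the channel
#'   matchers, or a previously merged table with a `channels` column).
#' @param taxonomy optional data frame with `host_id` and a rank column.
#' @param rank column of `taxonomy` to summarize host range at.
#' @return list with `links` (virus_id, host_id, channels, n_channels) and
#'   `host_range` (virus_id, n_hosts, range_class
#'   specialist/generalist).
#' @export
merge_links <- function(links, taxonomy = NULL, rank = "phylum") {
  if (is.data.frame(links)) links <- list(links)
  norm <- lapply(links, function(x) {
    if (!nrow(x)) return(NULL)
    if ("channels" %in% names(x)) {
      ch <- strsplit(x$channels, ",", fixed = TRUE)
      data.frame(virus_id = rep(x$virus_id, lengths(ch)),
                 host_id = rep(x$host_id, lengths(ch)),
                 channel = unlist(ch), stringsAsFactors = FALSE)
    } else {
      check_columns(x, c("virus_id", "host_id", "channel"), "links")
      x[, c("virus_id", "host_id", "channel")]
    }
  })
  norm <- do.call(rbind, norm)
  if (is.null(norm) || !nrow(norm)) {
    merged <- data.frame(virus_id = character(0), host_id = character(0),
                         channels = character(0), n_channels = integer(0),
                         stringsAsFactors = FALSE)
    hr <- data.frame(virus_id = character(0), n_hosts = integer(0),
                     range_class = character(0), stringsAsFactors = FALSE)
    return(list(links = merged, host_range = hr))
  }
  key <- paste(norm$virus_id, norm$host_id, sep = "\r")
  ch <- vapply(split(norm$channel, key), function(v) {
    paste(sort(unique(v)), collapse = ",")
  }, character(1))
  uk <- strsplit(names(ch), "\r", fixed = TRUE)
  merged <- data.frame(virus_id = vapply(uk, `[`, character(1), 1L),
                       host_id = vapply(uk, `[`, character(1), 2L),
                       channels = unname(ch),
                       stringsAsFactors = FALSE)
  merged$n_channels <- lengths(strsplit(merged$channels, ",", fixed = TRUE))
  merged <- merged[order(merged$virus_id, merged$host_id), , drop = FALSE]
  rownames(merged) <- NULL

  host_taxon <- merged$host_id
  if (!is.null(taxonomy)) {
    check_columns(taxonomy, c("host_id", rank), "taxonomy")
    miss <- setdiff(unique(merged$host_id), taxonomy$host_id)
    if (length(miss)) {
      warning("taxonomy missing for host(s), host range at contig level: ",
              paste(miss, collapse = ", "), call. = FALSE)
    } else {
      host_taxon <- taxonomy[[rank]][match(merged$host_id,
                                           taxonomy$host_id)]
    }
  }
  n_hosts <- vapply(split(host_taxon, merged$virus_id),
                    function(v) length(unique(v)), integer(1))
  hr <- data.frame(virus_id = names(n_hosts),
                   n_hosts = unname(n_hosts),
                   range_class = ifelse(n_hosts == 1L, "specialist",
                                        "generalist"),
                   stringsAsFactors = FALSE)
  rownames(hr) <- NULL
  list(links = merged, host_range = hr)
}
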