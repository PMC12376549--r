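# Internal helpers: seeded sub-streams, nucleotide utilities, flat-file IO.

#' Derive a reproducible sub-stream seed from a global seed and a label
#'
#' All random draws in the synthetic-data generator come from sub-streams
#' keyed by fixed labels, so that e.g. adding a new planted table never
#' shifts the draws of an existing one.
#'
#' @param seed integer global seed.
#' @param label character stream label.
#' @return an integer seed < 2^31.
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(abs(seed) %% 2147483647)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a label-derived seed, restoring the caller's RNG state.
with_sub_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, label))
  expr
}

# Random A/C/G/T string(s); no ambiguity codes so Hamming semantics stay exact.
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of plain A/C/G/T strings
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Mismatch count of `pattern` against every window of `subject` (1-based
# starts). Vectorized over windows: L passes over a length-(N-L+1) vector.
hamming_windows <- function(subject, pattern) {
  hamming_windows_int(utf8ToInt(subject), utf8ToInt(pattern))
}

# Integer-codepoint variant so callers can pre-encode sequences once.
hamming_windows_int <- function(s, p) {
  N <- length(s)
  L <- length(p)
  if (L == 0L || L > N) return(integer(0))
  n_win <- N - L + 1L
  d <- integer(n_win)
  for (j in seq_len(L)) {
    d <- d + (s[j:(j + n_win - 1L)] != p[j])
  }
  d
}

# Plain TSV IO with fixed conventions (header, no quoting, NA as empty field).
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", ...)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences; names are the
#'   identifiers up to the first whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 70L)
  invisible(path)
}

# Stop with a message listing missing columns, naming the offending table.
check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(sprintf("%s is missing required field(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
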