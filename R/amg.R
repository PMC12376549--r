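# Auxiliary metabolic gene (AMG) retention, categorization into KEGG level-2
# and CAZyme classes, and Z-score normalization of abundances across
# treatments.
#
# Retention follows the annotator's convention: auxiliary score 1-3
# (confident genomic context) plus an M or F flag, excluding genes carrying
# any of the conventional disqualifying flags (V, A, P, T, B); both flag sets
# are configurable since flag semantics differ between annotator versions.

.known_flags <- c("M", "F", "V", "A", "P", "T", "B")

parse_flags <- function(flags) {
  parts <- strsplit(toupper(ifelse(is.na(flags), "", flags)), "[,;[:space:]]+")
  lapply(parts, function(p) p[nzchar(p)])
}

#' Filter AMG candidates by auxiliary score and flags
#'
#' Retains candidates with auxiliary score in `score_range` whose flag set
#' intersects `require_flags` and avoids `exclude_flags`; duplicate gene ids
#' are collapsed (first occurrence kept). Unknown flag letters are ignored
#' with a warning.
#'
#' @param candidates data frame with `gene_id`, `auxiliary_score`, `flags`
#'   (comma/semicolon-separated single letters), plus any annotation columns.
#' @param score_range retained auxiliary scores (default 1:3).
#' @param require_flags at least one must be present (default M, F).
#' @param exclude_flags none may be present (default V, A, P, T, B).
#' @return the retained subset of `candidates`.
#' @export
filter_amgs <- function(candidates, score_range = 1:3,
                        require_flags = c("M", "F"),
                        exclude_flags = c("V", "A", "P", "T", "B")) {
  check_columns(candidates, c("gene_id", "auxiliary_score", "flags"),
                "candidates")
  fl <- parse_flags(candidates$flags)
  known <- union(.known_flags, c(require_flags, exclude_flags))
  unknown <- setdiff(unique(unlist(fl)), known)
  if (length(unknown)) {
    warning("unknown AMG flag letter(s) ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    fl <- lapply(fl, intersect, known)
  }
  keep <- candidates$auxiliary_score %in% score_range &
    vapply(fl, function(f) length(intersect(f, require_flags)) > 0,
           logical(1)) &
    vapply(fl, function(f) length(intersect(f, exclude_flags)) == 0,
           logical(1))
  out <- candidates[keep, , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize retained AMGs by KEGG level-2 pathway and CAZyme class
#'
#' The CAZyme class is the leading-letter prefix of the family label
#' (GH/GT/PL/CE/AA/CBM); genes lacking both a KEGG level-2 label and a
#' parseable CAZyme family are counted as `"unclassified"`.
#'
#' @param retained data frame from [filter_amgs()] with optional
#'   `kegg_level2` and `cazyme_family` columns.
#' @return data frame with `scheme` (`"kegg_level2"`, `"cazyme"`,
#'   `"unclassified"`), `category`, `n_genes`.
#' @export
categorize_amgs <- function(retained) {
  check_columns(retained, "gene_id", "retained AMGs")
  kegg <- if ("kegg_level2" %in% names(retained)) retained$kegg_level2 else
    rep(NA_character_, nrow(retained))
  fam <- if ("cazyme_family" %in% names(retained)) retained$cazyme_family else
    rep(NA_character_, nrow(retained))
  kegg[!is.na(kegg) & !nzchar(kegg)] <- NA
  fam[!is.na(fam) & !nzchar(fam)] <- NA

  m <- regexpr("^(GH|GT|PL|CE|AA|CBM)", toupper(ifelse(is.na(fam), "", fam)))
  cls <- rep(NA_character_, length(fam))
  ok <- m == 1L
  cls[ok] <- substr(toupper(fam[ok]), 1L, attr(m, "match.length")[ok])
  bad <- !is.na(fam) & !ok
  if (any(bad)) {
    warning("unparseable CAZyme family label(s) treated as unclassified: ",
            paste(unique(fam[bad]), collapse = ", "), call. = FALSE)
  }

  rows <- list()
  if (any(!is.na(kegg))) {
    t1 <- table(kegg[!is.na(kegg)])
    rows[[length(rows) + 1L]] <- data.frame(scheme = "kegg_level2",
                                            category = names(t1),
                                            n_genes = as.integer(t1),
                                            stringsAsFactors = FALSE)
  }
  if (any(!is.na(cls))) {
    t2 <- table(cls[!is.na(cls)])
    rows[[length(rows) + 1L]] <- data.frame(scheme = "cazyme",
                                            category = names(t2),
                                            n_genes = as.integer(t2),
                                            stringsAsFactors = FALSE)
  }
  n_uncl <- sum(is.na(kegg) & is.na(cls))
  if (n_uncl > 0) {
    rows[[length(rows) + 1L]] <- data.frame(scheme = "unclassified",
                                            category = "unclassified",
                                            n_genes = n_uncl,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(scheme = character(0), category = character(0),
                      n_genes = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-score-normalize gene abundances across treatments
#'
#' Per gene (row): z = (x - mean) / sd with the sample standard deviation
#' (n - 1 denominator). Constant rows map to all zeros by convention.
#'
#' @param m numeric matrix, genes x treatments (>= 2 columns).
#' @return matrix of the same shape; non-constant rows have mean 0 and
#'   sample SD 1.
#' @export
zscore_by_treatment <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) {
    stop("Z-score normalization needs at least two treatments", call. = FALSE)
  }
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}
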