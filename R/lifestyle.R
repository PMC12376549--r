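# Lysogenic / lytic lifestyle classification from marker-protein annotations,
# optionally merged with an external per-contig lifestyle predictor, and
# per-sample lifestyle proportions.

#' Marker classes accepted as lysogeny evidence
#'
#' Integrases, transposases, invertases, recombinases and excisionases:
#' proteins mediating genome integration/excision, the hallmark of a
#' temperate (lysogenic) lifestyle.
#' @export
lysogeny_marker_lexicon <- function() {
  c("integrase", "transposase", "invertase", "recombinase", "excisionase")
}

#' Classify contigs as lysogenic or (potentially) lytic
#'
#' A contig is called lysogenic when it carries at least one marker
#' annotation from the lysogeny lexicon, or (under the default union merge)
#' when the external predictor calls it lysogenic. Everything else is a
#' potential lytic virus. Evidence can only add lysogeny calls, never remove
#' them.
#'
#' @param contig_ids character vector of contigs to classify (every one
#'   receives exactly one call).
#' @param markers data frame with `contig_id`, `gene_id`, `marker_class`;
#'   rows whose class is outside the lexicon are ignored. Marker rows must
#'   reference known contigs.
#' @param external optional data frame with `contig_id`, `prediction`
#'   (`"lysogenic"`/`"lytic"`); unknown contig ids are dropped with a warning.
#' @param merge `"union"` (marker OR external, default), `"markers-only"`,
#'   or `"external-only"`.
#' @return data frame with `contig_id`, `call` (`"lysogenic"`/`"lytic"`),
#'   and an `evidence` string.
#' @export
classify_lifestyle <- function(contig_ids, markers = NULL, external = NULL,
                               merge = c("union", "markers-only",
                                         "external-only")) {
  merge <- match.arg(merge)
  contig_ids <- as.character(contig_ids)
  marker_ev <- setNames(vector("list", length(contig_ids)), contig_ids)
  if (!is.null(markers) && nrow(markers)) {
    check_columns(markers, c("contig_id", "marker_class"), "markers")
    unknown <- setdiff(unique(markers$contig_id), contig_ids)
    if (length(unknown)) {
      stop("marker rows reference unknown contig(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mk <- markers[markers$marker_class %in% lysogeny_marker_lexicon(), ,
                  drop = FALSE]
    marker_ev <- split(mk$marker_class, factor(mk$contig_id,
                                               levels = contig_ids))
  }
  ext_lys <- character(0)
  if (!is.null(external) && nrow(external)) {
    check_columns(external, c("contig_id", "prediction"), "external")
    unknown <- setdiff(unique(external$contig_id), contig_ids)
    if (length(unknown)) {
      warning("external predictions for unknown contig(s) ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      external <- external[!external$contig_id %in% unknown, , drop = FALSE]
    }
    ext_lys <- unique(external$contig_id[external$prediction == "lysogenic"])
  }

  has_marker <- lengths(marker_ev) > 0
  has_ext <- contig_ids %in% ext_lys
  lys <- switch(merge,
                "union" = has_marker | has_ext,
                "markers-only" = has_marker,
                "external-only" = has_ext)
  evidence <- vapply(seq_along(contig_ids), function(i) {
    parts <- c(sort(unique(unlist(marker_ev[[i]]))),
               if (has_ext[i]) "external:lysogenic")
    paste(parts, collapse = ";")
  }, character(1))
  data.frame(contig_id = contig_ids,
             call = ifelse(lys, "lysogenic", "lytic"),
             evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Per-sample lysogenic and lytic proportions
#'
#' With `weighting = "abundance"` each contig contributes its abundance
#' (e.g. RPKM) share; with `"count"` each contig present in the sample
#' (abundance > 0) contributes equally. Samples with zero total abundance get
#' missing fractions with a warning.
#'
#' @param calls output of [classify_lifestyle()].
#' @param abundance numeric matrix, contigs (rows) x samples (columns); row
#'   names must be covered by `calls`.
#' @param weighting `"abundance"` (default) or `"count"`.
#' @return data frame with `sample_id`, `frac_lysogenic`, `frac_lytic`.
#' @export
lifestyle_proportions <- function(calls, abundance,
                                  weighting = c("abundance", "count")) {
  weighting <- match.arg(weighting)
  check_columns(calls, c("contig_id", "call"), "calls")
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)))
  uncovered <- setdiff(rownames(abundance), calls$contig_id)
  if (length(uncovered)) {
    stop("abundance rows without a lifestyle call: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  is_lys <- calls$call[match(rownames(abundance), calls$contig_id)] ==
    "lysogenic"
  w <- if (weighting == "count") (abundance > 0) * 1 else abundance
  tot <- colSums(w)
  if (any(tot == 0)) {
    warning("sample(s) with zero total abundance, fractions undefined: ",
            paste(colnames(abundance)[tot == 0], collapse = ", "),
            call. = FALSE)
  }
  frac_lys <- ifelse(tot > 0, colSums(w[is_lys, , drop = FALSE]) / tot,
                     NA_real_)
  data.frame(sample_id = colnames(abundance),
             frac_lysogenic = unname(frac_lys),
             frac_lytic = unname(ifelse(is.na(frac_lys), NA_real_,
                                        1 - frac_lys)),
             stringsAsFactors = FALSE)
}
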