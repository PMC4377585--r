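# The integrative step: combine the baseline call with the calls from every
# alternative annotation set into per-variant re-annotation deltas.
#
# A variant counts as re-annotated when the baseline places it intronic or
# intergenic and at least one alternative set places it in a promoter or any
# intragenic category — with one asymmetry: an alternative-set INTRONIC call
# qualifies only when the baseline call was INTERGENIC (an intron over an
# intron is not a re-annotation).

# does one alternative-set category qualify as a re-annotation of baseline?
reannotates_category <- function(alt_category, baseline_category) {
  alt_category %in% c("PROMOTER", "CDS", "UTR5", "UTR3", "SPLICE", "NCRNA_EXONIC") |
    (alt_category == "INTRONIC" & baseline_category == "INTERGENIC")
}

#' Compute re-annotation deltas
#'
#' @param variants Validated variant data.frame (the universe; every variant
#'   must have a call in the baseline and in every alternative set).
#' @param baseline_calls `snpreanno_calls` from the baseline set.
#' @param alt_calls List of `snpreanno_calls`, one per alternative set.
#' @return A `snpreanno_deltas` list: `deltas` — one row per variant with
#'   baseline_category, one `category_<set>` column per alternative set,
#'   is_reannotated and coding_support (number of alternative sets calling
#'   CDS); `per_set` — long provenance (variant_id, set_name, category,
#'   gene_ids, contributes).
#' @export
reannotate <- function(variants, baseline_calls, alt_calls) {
  stopifnot(inherits(baseline_calls, "snpreanno_calls"), is.list(alt_calls))
  if (!length(alt_calls)) stop("at least one alternative set is required")
  ids <- variants$variant_id
  fetch <- function(calls) {
    m <- match(ids, calls$calls$variant_id)
    if (anyNA(m))
      stop("variant '", ids[which(is.na(m))[1]],
           "' missing from calls of set '", calls$set_name, "'")
    calls$calls[m, , drop = FALSE]
  }
  base <- fetch(baseline_calls)
  alt_names <- vapply(alt_calls, `[[`, "", "set_name")
  if (anyDuplicated(alt_names)) stop("duplicate alternative set names")
  per_set_rows <- vector("list", length(alt_calls))
  cat_mat <- matrix(NA_character_, nrow = length(ids), ncol = length(alt_calls),
                    dimnames = list(NULL, alt_names))
  for (k in seq_along(alt_calls)) {
    a <- fetch(alt_calls[[k]])
    cat_mat[, k] <- a$category
    per_set_rows[[k]] <- data.frame(
      variant_id = ids, set_name = alt_names[k], category = a$category,
      gene_ids = a$gene_ids,
      contributes = reannotates_category(a$category, base$category) &
        base$category %in% c("INTRONIC", "INTERGENIC"),
      stringsAsFactors = FALSE)
  }
  qualifying <- vapply(seq_along(ids), function(i)
    any(reannotates_category(cat_mat[i, ], base$category[i])), TRUE)
  deltas <- data.frame(variant_id = ids,
                       baseline_category = base$category,
                       stringsAsFactors = FALSE)
  for (nm in alt_names) deltas[[paste0("category_", nm)]] <- cat_mat[, nm]
  deltas$is_reannotated <- base$category %in% c("INTRONIC", "INTERGENIC") & qualifying
  deltas$coding_support <- as.integer(rowSums(cat_mat == "CDS"))
  structure(list(deltas = deltas,
                 per_set = do.call(rbind, per_set_rows),
                 alt_set_names = alt_names),
            class = "snpreanno_deltas")
}

#' Coding support of one or all deltas
#'
#' Number of alternative sets whose top-level category for the variant is
#' CDS.
#'
#' @param deltas A `snpreanno_deltas`.
#' @param variant_id Optional single variant id; when omitted, a named
#'   integer vector over all variants is returned.
#' @return Integer (scalar or named vector).
#' @export
coding_support <- function(deltas, variant_id = NULL) {
  stopifnot(inherits(deltas, "snpreanno_deltas"))
  cs <- stats::setNames(deltas$deltas$coding_support, deltas$deltas$variant_id)
  if (is.null(variant_id)) cs else unname(cs[variant_id])
}

#' Per-kind breakdown of coding-reclassified variants
#'
#' Over the variants with coding support >= 1, tabulates the most severe
#' consequence kind across the supporting sets' transcripts. The counts sum
#' to the number of coding-reclassified variants.
#'
#' @param deltas A `snpreanno_deltas`.
#' @param consequences Data.frame of [call_consequence()] rows covering every
#'   CDS call of the alternative sets.
#' @return Named integer vector over [consequence_kinds()].
#' @export
consequence_breakdown <- function(deltas, consequences) {
  stopifnot(inherits(deltas, "snpreanno_deltas"))
  coding_ids <- deltas$deltas$variant_id[deltas$deltas$coding_support >= 1L]
  kinds <- vapply(coding_ids, function(id) {
    rows <- consequences[consequences$variant_id == id, , drop = FALSE]
    if (!nrow(rows))
      stop("no consequence rows for coding-reclassified variant '", id, "'")
    most_severe(rows)$kind
  }, "")
  counts <- table(factor(kinds, levels = consequence_kinds()))
  stats::setNames(as.integer(counts), consequence_kinds())
}

#' Union and per-set counts of re-annotated variants
#'
#' @param deltas A `snpreanno_deltas`.
#' @return List: `union_count` (distinct re-annotated variants, each counted
#'   once regardless of how many sets re-annotate it) and `per_set_count`
#'   (named vector: variants each alternative set re-annotates).
#' @export
reannotation_counts <- function(deltas) {
  stopifnot(inherits(deltas, "snpreanno_deltas"))
  ps <- deltas$per_set
  per_set <- vapply(deltas$alt_set_names, function(nm)
    sum(ps$contributes[ps$set_name == nm]), integer(1))
  list(union_count = sum(deltas$deltas$is_reannotated),
       per_set_count = per_set)
}

#' @export
print.snpreanno_deltas <- function(x, ...) {
  cat(sprintf("<re-annotation deltas: %d variants, %d alternative sets, %d re-annotated (%d coding)>\n",
              nrow(x$deltas), length(x$alt_set_names),
              sum(x$deltas$is_reannotated),
              sum(x$deltas$is_reannotated & x$deltas$coding_support >= 1)))
  invisible(x)
}
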