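# Per-annotation-set region classification. Each variant gets exactly one
# top-level category per set, collapsed from per-transcript categories by a
# fixed severity order (see region_categories()).

#' Build an interval index over an annotation set
#'
#' Indexes each transcript's extended span (exon footprint plus the
#' strand-aware promoter window) so that position queries are sublinear in
#' the number of transcripts.
#'
#' @param set A `snpreanno_set`.
#' @param t Thresholds (the promoter window enters the indexed span).
#' @return A `snpreanno_index`.
#' @export
build_index <- function(set, t = thresholds()) {
  stopifnot(inherits(set, "snpreanno_set"))
  tx <- set$transcripts
  if (!nrow(tx)) {
    gr <- GenomicRanges::GRanges()
  } else {
    prom <- promoter_interval(tss(tx), tx$strand, t$promoter_window_bp)
    span_start <- pmin(tx$tx_start, ifelse(is.na(prom$start), tx$tx_start, prom$start))
    span_end <- pmax(tx$tx_end, ifelse(is.na(prom$end), tx$tx_end, prom$end))
    gr <- GenomicRanges::GRanges(tx$contig,
                                 IRanges::IRanges(span_start, span_end),
                                 transcript_id = tx$transcript_id)
  }
  structure(list(set = set, gr = gr, t = t,
                 exons_by_tx = split(set$exons[, c("start", "end")],
                                     set$exons$transcript_id)),
            class = "snpreanno_index")
}

# transcription start site: 5'-most genomic coordinate on the strand
tss <- function(tx) {
  ifelse(tx$strand == "+", tx$tx_start, tx$tx_end)
}

#' Promoter interval upstream of a TSS
#'
#' On the plus strand the window is `[TSS - window, TSS - 1]`; on the minus
#' strand `[TSS + 1, TSS + window]`. The interval is clamped to
#' `[1, contig_length]`; a window entirely off-contig yields `NA` bounds.
#'
#' @param tss_pos TSS genomic coordinate(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @param window Window size in bp (>= 1).
#' @param contig_length Optional contig length for right clamping.
#' @return Data.frame with columns start, end (1-based inclusive, or NA).
#' @export
promoter_interval <- function(tss_pos, strand, window, contig_length = NULL) {
  stopifnot(window >= 1)
  start <- ifelse(strand == "+", tss_pos - window, tss_pos + 1)
  end <- ifelse(strand == "+", tss_pos - 1, tss_pos + window)
  start <- pmax(start, 1)
  if (!is.null(contig_length)) end <- pmin(end, contig_length)
  empty <- start > end
  data.frame(start = ifelse(empty, NA_integer_, as.integer(start)),
             end = ifelse(empty, NA_integer_, as.integer(end)))
}

# category of one position relative to one transcript, or NA if unrelated
transcript_category <- function(pos, ex, strand, cds_start, cds_end, t) {
  s <- ex$start; e <- ex$end
  if (pos >= s[1] && pos <= e[length(e)]) {
    hit <- which(pos >= s & pos <= e)
    if (length(hit)) {
      if (!is.na(cds_start)) {
        if (pos >= cds_start && pos <= cds_end) return("CDS")
        before <- pos < cds_start
        if ((strand == "+") == before) return("UTR5") else return("UTR3")
      }
      return("NCRNA_EXONIC")
    }
    # intronic: distance 1 means the first intronic base
    d <- min(pos - max(e[e < pos]), min(s[s > pos]) - pos)
    return(if (d <= t$splice_window_bp) "SPLICE" else "INTRONIC")
  }
  tss_pos <- if (strand == "+") s[1] else e[length(e)]
  pr <- promoter_interval(tss_pos, strand, t$promoter_window_bp)
  if (!is.na(pr$start) && pos >= pr$start && pos <= pr$end) return("PROMOTER")
  NA_character_
}

#' Classify variants against one annotation set
#'
#' Assigns each variant a per-transcript category for every transcript whose
#' extended span contains it, then collapses to a single top-level category
#' by severity (CDS > SPLICE > UTR5 > UTR3 > NCRNA_EXONIC > INTRONIC >
#' PROMOTER > INTERGENIC). A promoter hit is reported only when no
#' transcript's exon/intron footprint contains the position. `gene_ids`
#' lists, sorted and comma-separated, every gene contributing the top-level
#' category. Variants on contigs absent from the set are INTERGENIC (with
#' one warning).
#'
#' @param variants Validated variant data.frame.
#' @param set A `snpreanno_set` or prebuilt `snpreanno_index`.
#' @param t Thresholds.
#' @return A `snpreanno_calls` list: `calls` (variant_id, set_name,
#'   category, gene_ids) and `transcript_calls` (variant_id, set_name,
#'   transcript_id, gene_id, category).
#' @export
classify_variants <- function(variants, set, t = thresholds()) {
  idx <- if (inherits(set, "snpreanno_index")) set else build_index(set, t)
  set <- idx$set
  t <- idx$t
  tx <- set$transcripts
  n <- nrow(variants)
  categories <- rep("INTERGENIC", n)
  gene_ids <- rep("", n)
  tc_rows <- vector("list", n)
  if (n && nrow(tx)) {
    vgr <- GenomicRanges::GRanges(variants$contig,
                                  IRanges::IRanges(variants$position,
                                                   variants$position))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(vgr, idx$gr))
    if (length(setdiff(variants$contig, tx$contig)))
      warning("variant contig(s) absent from set '", set$name, "': ",
              paste(setdiff(variants$contig, tx$contig), collapse = ", "),
              " (classified INTERGENIC)")
    hits_by_v <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (vi in as.integer(names(hits_by_v))) {
      tids <- tx$transcript_id[hits_by_v[[as.character(vi)]]]
      rows <- match(tids, tx$transcript_id)
      cats <- vapply(seq_along(rows), function(j) {
        r <- rows[j]
        transcript_category(variants$position[vi], idx$exons_by_tx[[tids[j]]],
                            tx$strand[r], tx$cds_start[r], tx$cds_end[r], t)
      }, "")
      keep <- !is.na(cats)
      if (!any(keep)) next
      cats <- cats[keep]; rows <- rows[keep]; tids <- tids[keep]
      # intragenic beats upstream: drop PROMOTER if any footprint category
      tc_rows[[vi]] <- data.frame(variant_id = variants$variant_id[vi],
                                  set_name = set$name,
                                  transcript_id = tids,
                                  gene_id = tx$gene_id[rows],
                                  category = cats,
                                  stringsAsFactors = FALSE)
      top <- region_categories()[min(category_rank(cats))]
      categories[vi] <- top
      gene_ids[vi] <- paste(sort(unique(tx$gene_id[rows][cats == top])),
                            collapse = ",")
    }
  }
  calls <- data.frame(variant_id = variants$variant_id,
                      set_name = set$name,
                      category = categories,
                      gene_ids = gene_ids,
                      stringsAsFactors = FALSE)
  tcs <- do.call(rbind, tc_rows[!vapply(tc_rows, is.null, TRUE)])
  if (is.null(tcs))
    tcs <- data.frame(variant_id = character(), set_name = character(),
                      transcript_id = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE)
  structure(list(calls = calls, transcript_calls = tcs,
                 set_name = set$name), class = "snpreanno_calls")
}

#' Classify a single variant
#'
#' @param v One-row variant data.frame (or a row of one).
#' @inheritParams classify_variants
#' @return The one-row `calls` data.frame; transcript-level detail in
#'   attribute `"transcript_calls"`.
#' @export
classify_variant <- function(v, set, t = thresholds()) {
  res <- classify_variants(v[1, , drop = FALSE], set, t)
  out <- res$calls
  attr(out, "transcript_calls") <- res$transcript_calls
  out
}

#' Baseline noncoding filter
#'
#' Removes variants that the baseline annotation places in exonic regions of
#' protein-coding genes (CDS, 5' UTR, 3' UTR) or in the splice window of a
#' protein-coding gene; everything else (ncRNA-exonic, intronic, promoter,
#' intergenic) is retained. The partition is exact.
#'
#' @param variants Validated variant data.frame.
#' @param baseline Baseline `snpreanno_set` (role must be `"baseline"`).
#' @param t Thresholds.
#' @return List with `kept`, `removed` (variant subsets) and
#'   `baseline_calls` (the `snpreanno_calls` used).
#' @export
filter_noncoding <- function(variants, baseline, t = thresholds()) {
  stopifnot(inherits(baseline, "snpreanno_set"))
  if (baseline$role != "baseline")
    stop("filter_noncoding requires the baseline set (role = 'baseline')")
  res <- classify_variants(variants, baseline, t)
  cg <- coding_genes(baseline)
  exonic <- res$calls$category %in% c("CDS", "UTR5", "UTR3")
  splice_coding <- res$calls$category == "SPLICE" &
    vapply(strsplit(res$calls$gene_ids, ",", fixed = TRUE),
           function(g) any(g %in% cg), TRUE)
  removed <- exonic | splice_coding
  list(kept = variants[!removed, , drop = FALSE],
       removed = variants[removed, , drop = FALSE],
       baseline_calls = res)
}

#' Category counts per annotation set
#'
#' @param calls A `snpreanno_calls`, or a list of them (one per set).
#' @return Data.frame: one row per set, one column per region category, all
#'   eight categories always present; row sums equal the number of
#'   classified variants.
#' @export
category_counts <- function(calls) {
  if (inherits(calls, "snpreanno_calls")) calls <- list(calls)
  rows <- lapply(calls, function(cl) {
    counts <- table(factor(cl$calls$category, levels = region_categories()))
    cbind(data.frame(set_name = cl$set_name, stringsAsFactors = FALSE),
          as.data.frame(t(as.matrix(counts))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.snpreanno_calls <- function(x, ...) {
  cat(sprintf("<region calls for set '%s': %d variants>\n",
              x$set_name, nrow(x$calls)))
  print(table(factor(x$calls$category, levels = region_categories())))
  invisible(x)
}
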