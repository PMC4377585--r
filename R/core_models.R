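# Domain types shared by every stage: variants, transcript models grouped
# into annotation sets, the region-category enumeration with its severity
# order, and the three thresholds that parameterise the whole analysis.

#' Region categories, from most to least severe
#'
#' The per-variant functional category within one annotation set. The order
#' of the returned vector is the precedence used to collapse per-transcript
#' calls into one top-level call: coding sequence beats the splice window,
#' which beats the UTRs, non-coding exons, introns, the upstream promoter
#' window and finally intergenic space. An intragenic hit in one gene always
#' beats a promoter hit in another.
#'
#' @return Character vector of the eight category names in precedence order.
#' @export
region_categories <- function() {
  c("CDS", "SPLICE", "UTR5", "UTR3", "NCRNA_EXONIC",
    "INTRONIC", "PROMOTER", "INTERGENIC")
}

#' Coding-consequence kinds, from most to least severe
#'
#' Stop-gain and stop-loss are equally ranked (both disrupt the open reading
#' frame boundary), followed by non-synonymous, synonymous, and finally
#' unknown (alternative allele unavailable or variant in a trailing partial
#' codon).
#'
#' @return Character vector of kind names.
#' @export
consequence_kinds <- function() {
  c("STOPGAIN", "STOPLOSS", "NONSYNONYMOUS", "SYNONYMOUS", "UNKNOWN")
}

#' Regulatory feature classes
#'
#' The seven feature classes a regulatory track can be tagged with:
#' promoter/enhancer chromatin states, regulatory motifs, DNase footprints,
#' eQTLs, conserved elements, conserved transcription-factor binding sites,
#' and ChIP-seq-supported protein binding.
#'
#' @return Character vector of class names.
#' @export
regulatory_classes <- function() {
  c("PROMOTER_ENHANCER", "MOTIF", "DNASE_FOOTPRINT", "EQTL",
    "CONSERVED", "TFBS", "PROTEIN_BINDING")
}

#' Analysis thresholds
#'
#' @param splice_window_bp Intronic positions within this many bases of an
#'   exon/intron boundary are classified `SPLICE`. Default 2 bp.
#' @param promoter_window_bp Extent of the promoter window upstream of a
#'   transcription start site, on the transcript strand. Default 1000 bp.
#' @param expression_sd_max A gene is called expressed in a tissue when the
#'   posterior standard deviation of its expression estimate is strictly
#'   below this value. Default 1.5.
#' @return A `snpreanno_thresholds` list with the three fields.
#' @export
thresholds <- function(splice_window_bp = 2L,
                       promoter_window_bp = 1000L,
                       expression_sd_max = 1.5) {
  stopifnot(length(splice_window_bp) == 1L, splice_window_bp > 0,
            length(promoter_window_bp) == 1L, promoter_window_bp > 0,
            length(expression_sd_max) == 1L, expression_sd_max > 0)
  structure(
    list(splice_window_bp = as.integer(splice_window_bp),
         promoter_window_bp = as.integer(promoter_window_bp),
         expression_sd_max = as.numeric(expression_sd_max)),
    class = "snpreanno_thresholds")
}

#' Build a variant table
#'
#' Variants are single-nucleotide only: 1-based positions, single-base
#' reference/alternative alleles, either of which may be missing (`NA`) when
#' the original report did not state alleles. Indels are rejected.
#'
#' @param variant_id rsID-like identifiers.
#' @param contig Contig names.
#' @param position 1-based positions.
#' @param ref,alt Single-base alleles or `NA`.
#' @param trait Optional trait labels.
#' @return A validated data.frame with one row per variant.
#' @export
variant_table <- function(variant_id, contig, position,
                          ref = NA_character_, alt = NA_character_,
                          trait = NA_character_) {
  v <- data.frame(variant_id = as.character(variant_id),
                  contig = as.character(contig),
                  position = as.integer(position),
                  ref = as.character(ref),
                  alt = as.character(alt),
                  trait = as.character(trait),
                  stringsAsFactors = FALSE)
  validate_variants(v)
}

#' Validate a variant table
#'
#' Enforces the SNP invariants: non-empty identifiers, positions >= 1,
#' alleles (when present) single characters in A/C/G/T, and ref != alt when
#' both are present.
#'
#' @param v Data.frame with columns variant_id, contig, position, ref, alt
#'   (trait optional).
#' @return `v`, with alleles uppercased, invisibly unchanged otherwise.
#' @export
validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  needed <- c("variant_id", "contig", "position", "ref", "alt")
  missing_cols <- setdiff(needed, names(v))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!("trait" %in% names(v))) v$trait <- NA_character_
  bad_id <- is.na(v$variant_id) | !nzchar(trimws(v$variant_id))
  if (any(bad_id))
    stop("variant rows with missing/blank identifier: ", sum(bad_id))
  if (any(is.na(v$position) | v$position < 1L))
    stop("variant positions must be >= 1 (1-based): offending ids ",
         paste(utils::head(v$variant_id[is.na(v$position) | v$position < 1L], 3),
               collapse = ", "))
  for (col in c("ref", "alt")) {
    a <- toupper(v[[col]])
    a[!is.na(a) & !nzchar(a)] <- NA_character_
    ok <- is.na(a) | a %in% c("A", "C", "G", "T")
    if (!all(ok))
      stop("non-SNP or malformed ", col, " allele for: ",
           paste(utils::head(v$variant_id[!ok], 3), collapse = ", "))
    v[[col]] <- a
  }
  both <- !is.na(v$ref) & !is.na(v$alt)
  if (any(both & v$ref == v$alt))
    stop("ref and alt alleles identical for: ",
         paste(utils::head(v$variant_id[both & v$ref == v$alt], 3),
               collapse = ", "))
  v
}

#' Assemble an annotation set
#'
#' An annotation set is one named gene-annotation database (the baseline used
#' for the original noncoding call, or an alternative used for
#' re-annotation). Transcript structure is held as two tables: one row per
#' transcript and one row per exon.
#'
#' @param name Set name (e.g. `"baseline"`, `"altA"`).
#' @param role `"baseline"` or `"alternative"`.
#' @param transcripts Data.frame with columns transcript_id, gene_id, contig,
#'   strand (`"+"`/`"-"`), cds_start, cds_end (both `NA` for noncoding
#'   transcripts; 1-based inclusive genomic coordinates otherwise).
#' @param exons Data.frame with columns transcript_id, start, end (1-based
#'   inclusive), one row per exon.
#' @return A `snpreanno_set` list with elements name, role, transcripts,
#'   exons; transcripts gain tx_start/tx_end footprint columns and a
#'   `is_coding` flag, exons are sorted genomically ascending per transcript.
#' @export
annotation_set <- function(name, role = c("baseline", "alternative"),
                           transcripts, exons) {
  role <- match.arg(role)
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  tx_cols <- c("transcript_id", "gene_id", "contig", "strand",
               "cds_start", "cds_end")
  if (length(setdiff(tx_cols, names(transcripts))))
    stop("transcripts table lacks columns: ",
         paste(setdiff(tx_cols, names(transcripts)), collapse = ", "))
  if (length(setdiff(c("transcript_id", "start", "end"), names(exons))))
    stop("exons table lacks transcript_id/start/end columns")
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in set '", name, "': ",
         transcripts$transcript_id[duplicated(transcripts$transcript_id)][1])
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  if (any(exons$start > exons$end))
    stop("exon with start > end")
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tid in names(sp)) {
    idx <- sp[[tid]]
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] <= e[-length(e)]))
        stop("overlapping exons in transcript '", tid, "'")
    }
  }
  missing_ex <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(missing_ex))
    stop("transcripts without exons: ", paste(utils::head(missing_ex, 3), collapse = ", "))
  tx_start <- vapply(sp, function(i) min(exons$start[i]), numeric(1))
  tx_end <- vapply(sp, function(i) max(exons$end[i]), numeric(1))
  transcripts$tx_start <- as.integer(tx_start[transcripts$transcript_id])
  transcripts$tx_end <- as.integer(tx_end[transcripts$transcript_id])
  transcripts$is_coding <- !is.na(transcripts$cds_start) & !is.na(transcripts$cds_end)
  cod <- transcripts$is_coding
  if (any(cod)) {
    bad <- transcripts$cds_start[cod] > transcripts$cds_end[cod] |
      transcripts$cds_start[cod] < transcripts$tx_start[cod] |
      transcripts$cds_end[cod] > transcripts$tx_end[cod]
    if (any(bad))
      stop("cds_span outside exon footprint for: ",
           paste(utils::head(transcripts$transcript_id[cod][bad], 3), collapse = ", "))
    # every CDS endpoint must fall inside an exon, not an intron
    for (i in which(cod)) {
      ex <- exons[exons$transcript_id == transcripts$transcript_id[i], , drop = FALSE]
      for (p in c(transcripts$cds_start[i], transcripts$cds_end[i]))
        if (!any(p >= ex$start & p <= ex$end))
          stop("CDS endpoint ", p, " of '", transcripts$transcript_id[i],
               "' falls in an intron")
    }
  }
  structure(list(name = as.character(name), role = role,
                 transcripts = transcripts, exons = exons),
            class = "snpreanno_set")
}

#' Gene identifiers of protein-coding genes in a set
#'
#' A gene is protein-coding in a set when at least one of its transcripts in
#' that set carries a CDS.
#'
#' @param set A `snpreanno_set`.
#' @return Sorted character vector of gene ids.
#' @export
coding_genes <- function(set) {
  stopifnot(inherits(set, "snpreanno_set"))
  sort(unique(set$transcripts$gene_id[set$transcripts$is_coding]))
}

#' @export
print.snpreanno_set <- function(x, ...) {
  cat(sprintf("<annotation set '%s' (%s): %d transcripts, %d genes, %d exons>\n",
              x$name, x$role, nrow(x$transcripts),
              length(unique(x$transcripts$gene_id)), nrow(x$exons)))
  invisible(x)
}

#' @export
print.snpreanno_thresholds <- function(x, ...) {
  cat(sprintf("<thresholds: splice window %d bp, promoter window %d bp, expression SD < %g>\n",
              x$splice_window_bp, x$promoter_window_bp, x$expression_sd_max))
  invisible(x)
}

# internal: severity rank of a category vector (1 = most severe)
category_rank <- function(categories) {
  match(categories, region_categories())
}
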