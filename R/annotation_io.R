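# Readers and writers for every external format the tool touches: GTF and
# genePred gene models, VCF / TSV variant lists, BED regulatory tracks,
# expression tables, FASTA genomes, and the TSV/JSON result files.
#
# Coordinate conventions: everything in memory is 1-based inclusive. BED is
# 0-based half-open on disk, so internal_start = bed_start + 1 and
# internal_end = bed_end. VCF and GTF are already 1-based.

#' Parse gene models into an annotation set
#'
#' Reads a GTF (Ensembl-style, requiring `gene_id` and `transcript_id`
#' attributes) or a genePred file (UCSC-style, 10- or 15-column) and groups
#' exon/CDS records into transcript models. Transcripts without CDS records
#' are noncoding. Minus-strand transcripts keep genomically ascending exon
#' order.
#'
#' @param path Annotation file.
#' @param dialect `"gtf"` or `"genepred"`.
#' @param set_name Name for the resulting set.
#' @param role `"baseline"` or `"alternative"`.
#' @return A `snpreanno_set` (see [annotation_set()]).
#' @export
parse_gene_models <- function(path, dialect = c("gtf", "genepred"),
                              set_name, role = c("baseline", "alternative")) {
  dialect <- match.arg(dialect)
  role <- match.arg(role)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gtf") parse_gtf(path, set_name, role)
  else parse_genepred(path, set_name, role)
}

parse_gtf <- function(path, set_name, role) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(annotation_set(set_name, role,
      transcripts = data.frame(transcript_id = character(), gene_id = character(),
                               contig = character(), strand = character(),
                               cds_start = integer(), cds_end = integer()),
      exons = data.frame(transcript_id = character(), start = integer(),
                         end = integer())))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  known <- c("exon", "CDS")
  if (!all(as.character(gr$type) %in% known)) {
    skipped <- setdiff(unique(as.character(gr$type)), known)
    warning("skipping unknown GTF feature types: ",
            paste(skipped, collapse = ", "))
    gr <- gr[as.character(gr$type) %in% known]
  }
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("GTF records must carry gene_id and transcript_id attributes")
  build_set_from_records(
    set_name, role,
    data.frame(type = as.character(gr$type),
               contig = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               gene_id = gr$gene_id,
               transcript_id = gr$transcript_id,
               stringsAsFactors = FALSE))
}

# shared assembly of a snpreanno_set from flat exon/CDS records
build_set_from_records <- function(set_name, role, rec) {
  ex <- rec[rec$type == "exon", , drop = FALSE]
  cds <- rec[rec$type == "CDS", , drop = FALSE]
  tx <- unique(ex[, c("transcript_id", "gene_id", "contig", "strand")])
  if (anyDuplicated(tx$transcript_id))
    stop("transcript_id mapped to multiple genes/contigs/strands: ",
         tx$transcript_id[duplicated(tx$transcript_id)][1])
  if (nrow(cds)) {
    cds_start <- tapply(cds$start, cds$transcript_id, min)
    cds_end <- tapply(cds$end, cds$transcript_id, max)
    tx$cds_start <- as.integer(cds_start[tx$transcript_id])
    tx$cds_end <- as.integer(cds_end[tx$transcript_id])
  } else {
    tx$cds_start <- NA_integer_
    tx$cds_end <- NA_integer_
  }
  annotation_set(set_name, role, transcripts = tx,
                 exons = ex[, c("transcript_id", "start", "end")])
}

parse_genepred <- function(path, set_name, role) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(annotation_set(set_name, role,
      transcripts = data.frame(transcript_id = character(), gene_id = character(),
                               contig = character(), strand = character(),
                               cds_start = integer(), cds_end = integer()),
      exons = data.frame(transcript_id = character(), start = integer(),
                         end = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (!all(ncol %in% c(10L, 15L)))
    stop("genePred rows must have 10 or 15 tab-separated columns")
  rec_list <- lapply(fields, function(f) {
    n_exons <- as.integer(f[8])
    starts <- as.integer(strsplit(f[9], ",", fixed = TRUE)[[1]]) + 1L # 0-based
    ends <- as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]])
    if (length(starts) != n_exons || length(ends) != n_exons)
      stop("exon count mismatch for transcript '", f[1], "'")
    gene <- if (length(f) >= 12L && nzchar(f[12])) f[12] else f[1]
    cds_s <- as.integer(f[6]) + 1L
    cds_e <- as.integer(f[7])
    coding <- cds_s <= cds_e # cdsStart == cdsEnd marks noncoding
    list(tx = data.frame(transcript_id = f[1], gene_id = gene, contig = f[2],
                         strand = f[3],
                         cds_start = if (coding) cds_s else NA_integer_,
                         cds_end = if (coding) cds_e else NA_integer_,
                         stringsAsFactors = FALSE),
         ex = data.frame(transcript_id = f[1], start = starts, end = ends,
                         stringsAsFactors = FALSE))
  })
  annotation_set(set_name, role,
                 transcripts = do.call(rbind, lapply(rec_list, `[[`, "tx")),
                 exons = do.call(rbind, lapply(rec_list, `[[`, "ex")))
}

#' Read a variant list
#'
#' Reads SNPs from a sites-only VCF (positions taken as-is, already 1-based)
#' or a GWAS-catalog-like TSV. Rows without an identifier are rejected;
#' duplicated identifiers are dropped (first occurrence wins) with the count
#' reported via `message()`. Unparsable rows are skipped with a warning.
#'
#' @param path Input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @param columns For TSV: named character vector mapping the standard names
#'   (`variant_id`, `contig`, `position`, `ref`, `alt`, `trait`) to the
#'   file's header names. Defaults cover common GWAS-catalog-like spellings;
#'   auto-detection picks the first candidate present.
#' @return A validated variant data.frame (see [variant_table()]).
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv"), columns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file not found: ", path)
  v <- if (dialect == "vcf") read_variants_vcf(path) else
    read_variants_tsv(path, columns)
  dup <- duplicated(v$variant_id)
  if (any(dup)) {
    message(sum(dup), " duplicate variant id(s) dropped (first occurrence kept)")
    v <- v[!dup, , drop = FALSE]
  }
  rownames(v) <- NULL
  validate_variants(v)
}

read_variants_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(variant_id = character(), contig = character(),
                      position = integer(), ref = character(),
                      alt = character(), trait = character()))
  f <- strsplit(body, "\t", fixed = TRUE)
  keep <- vapply(f, length, 1L) >= 5L
  if (!all(keep)) {
    warning(sum(!keep), " unparsable VCF row(s) skipped")
    f <- f[keep]
  }
  norm <- function(x) ifelse(x %in% c(".", ""), NA_character_, toupper(x))
  v <- data.frame(
    variant_id = vapply(f, `[`, "", 3L),
    contig = vapply(f, `[`, "", 1L),
    position = as.integer(vapply(f, `[`, "", 2L)),
    ref = norm(vapply(f, `[`, "", 4L)),
    alt = norm(vapply(f, `[`, "", 5L)),
    trait = NA_character_,
    stringsAsFactors = FALSE)
  drop_id <- is.na(v$variant_id) | v$variant_id %in% c(".", "")
  if (any(drop_id)) {
    warning(sum(drop_id), " VCF row(s) without an identifier rejected")
    v <- v[!drop_id, , drop = FALSE]
  }
  v
}

.tsv_column_candidates <- list(
  variant_id = c("variant_id", "id", "rsid", "rs_id", "snp", "snps"),
  contig = c("contig", "chrom", "chr", "chr_id", "chromosome"),
  position = c("position", "pos", "chr_pos", "bp"),
  ref = c("ref", "ref_allele", "reference"),
  alt = c("alt", "alt_allele", "risk_allele", "effect_allele"),
  trait = c("trait", "disease_trait", "phenotype"))

read_variants_tsv <- function(path, columns = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  pick <- function(std) {
    if (!is.null(columns) && std %in% names(columns)) return(columns[[std]])
    cand <- .tsv_column_candidates[[std]]
    hit <- cand[cand %in% tolower(names(d))]
    if (length(hit)) names(d)[match(hit[1], tolower(names(d)))] else NA_character_
  }
  cols <- vapply(names(.tsv_column_candidates), pick, "")
  for (std in c("variant_id", "contig", "position"))
    if (is.na(cols[[std]]) || !(cols[[std]] %in% names(d)))
      stop("cannot locate a '", std, "' column in ", path,
           " (supply a 'columns' mapping)")
  get <- function(std, default = NA_character_) {
    cn <- cols[[std]]
    if (is.na(cn) || !(cn %in% names(d))) rep(default, nrow(d)) else as.character(d[[cn]])
  }
  blank_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, toupper(x))
  v <- data.frame(variant_id = get("variant_id"),
                  contig = get("contig"),
                  position = suppressWarnings(as.integer(get("position"))),
                  ref = blank_na(get("ref")),
                  alt = blank_na(get("alt")),
                  trait = get("trait"),
                  stringsAsFactors = FALSE)
  bad <- is.na(v$position)
  if (any(bad)) {
    warning(sum(bad), " TSV row(s) with unparsable position skipped")
    v <- v[!bad, , drop = FALSE]
  }
  drop_id <- is.na(v$variant_id) | !nzchar(trimws(v$variant_id))
  if (any(drop_id)) {
    warning(sum(drop_id), " TSV row(s) without an identifier rejected")
    v <- v[!drop_id, , drop = FALSE]
  }
  v
}

#' Read regulatory-feature tracks
#'
#' Each BED3+ file carries one regulatory feature class. BED's 0-based
#' half-open intervals are converted to internal 1-based inclusive
#' coordinates (`start + 1`, `end`). Rows with start >= end are rejected
#' with a warning.
#'
#' @param paths Character vector of BED paths.
#' @param classes Feature class per path (values of [regulatory_classes()]).
#' @return Data.frame with columns contig, start, end (1-based inclusive),
#'   feature_class, source_track, score (NA when the file has no column 5).
#' @export
read_tracks <- function(paths, classes) {
  stopifnot(length(paths) == length(classes))
  bad_cls <- setdiff(classes, regulatory_classes())
  if (length(bad_cls))
    stop("unknown regulatory class(es): ", paste(bad_cls, collapse = ", "))
  out <- lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[i])) stop("track file not found: ", paths[i])
    lines <- readLines(paths[i], warn = FALSE)
    lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
    if (!length(lines))
      return(data.frame(contig = character(), start = integer(),
                        end = integer(), feature_class = character(),
                        source_track = character(), score = numeric()))
    f <- strsplit(lines, "[ \t]+")
    if (any(lengths(f) < 3L)) stop("BED rows need >= 3 columns in ", paths[i])
    bed_start <- as.integer(vapply(f, `[`, "", 2L))
    bed_end <- as.integer(vapply(f, `[`, "", 3L))
    keep <- bed_start < bed_end
    if (!all(keep))
      warning(sum(!keep), " BED row(s) with start >= end rejected in ",
              basename(paths[i]))
    score <- vapply(f, function(x) if (length(x) >= 5L)
      suppressWarnings(as.numeric(x[5])) else NA_real_, numeric(1))
    data.frame(contig = vapply(f, `[`, "", 1L)[keep],
               start = bed_start[keep] + 1L,
               end = bed_end[keep],
               feature_class = classes[i],
               source_track = basename(paths[i]),
               score = score[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a gene-by-tissue expression table
#'
#' TSV with columns gene_id, tissue, estimate (FPKM-like point estimate) and
#' posterior_sd. Rows with negative estimate or SD are rejected with a
#' warning; duplicated (gene, tissue) pairs are an error.
#'
#' @param path TSV path.
#' @return Data.frame with one row per (gene, tissue).
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "tissue", "estimate", "posterior_sd")
  if (length(setdiff(need, names(d))))
    stop("expression table lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$estimate <- as.numeric(d$estimate)
  d$posterior_sd <- as.numeric(d$posterior_sd)
  bad <- is.na(d$estimate) | is.na(d$posterior_sd) |
    d$estimate < 0 | d$posterior_sd < 0
  if (any(bad)) {
    warning(sum(bad), " expression row(s) with negative/unparsable values rejected")
    d <- d[!bad, , drop = FALSE]
  }
  key <- paste(d$gene_id, d$tissue, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (gene, tissue) pair: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  rownames(d) <- NULL
  d[, need]
}

#' Open a genome FASTA for random access
#'
#' @param path FASTA path.
#' @return A `snpreanno_genome` wrapping a [Biostrings::DNAStringSet];
#'   contig names are truncated at the first whitespace and sequences are
#'   queried uppercased via [genome_base()] / [genome_slice()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(seqs = seqs), class = "snpreanno_genome")
}

#' @rdname read_genome
#' @param genome A `snpreanno_genome`.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @export
genome_base <- function(genome, contig, pos) {
  genome_slice(genome, contig, pos, pos)
}

#' @rdname read_genome
#' @param start,end 1-based inclusive bounds.
#' @export
genome_slice <- function(genome, contig, start, end) {
  stopifnot(inherits(genome, "snpreanno_genome"))
  if (!(contig %in% names(genome$seqs)))
    stop("contig '", contig, "' not in genome (have: ",
         paste(names(genome$seqs), collapse = ", "), ")")
  len <- Biostrings::width(genome$seqs[contig])
  if (start < 1L || end > len || start > end)
    stop("slice [", start, ",", end, "] out of range for contig '", contig,
         "' of length ", len)
  toupper(as.character(Biostrings::subseq(genome$seqs[[contig]], start, end)))
}

#' @rdname read_genome
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "snpreanno_genome"))
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' Write a result table
#'
#' Writes calls, deltas or profiles as TSV (column names and generation
#' parameters in leading `#` comment lines) or JSON (an object with `params`
#' and `rows` members). Rows are ordered deterministically by variant id and
#' then set name when those columns exist.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param params Optional named list recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "json"), params = list()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  ord <- intersect(c("variant_id", "set_name", "gene_id", "tissue"), names(x))
  if (length(ord)) x <- x[do.call(order, x[ord]), , drop = FALSE]
  rownames(x) <- NULL
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- c(sprintf("# columns: %s", paste(names(x), collapse = ", ")),
             if (length(params))
               sprintf("# param %s = %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","), "")))
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(x, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE, col.names = TRUE))
  } else {
    jsonlite::write_json(list(params = params, rows = x), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return The data.frame (header comments / params dropped).
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$rows)
  }
}
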