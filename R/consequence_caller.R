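# Codon-level consequence of a CDS-hitting SNP: strand-aware CDS assembly,
# translation with the standard genetic code, and a severity fold over
# transcripts.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Assemble the coding sequence of a transcript
#'
#' Concatenates the CDS bases 5' to 3' on the transcript strand
#' (reverse-complementing minus-strand transcripts) and returns, alongside
#' the sequence, the genomic position of every CDS base in transcript
#' order — a bijection between CDS genomic positions and 0-based CDS
#' offsets. The CDS span is taken to include the stop codon.
#'
#' @param set A `snpreanno_set`.
#' @param transcript_id Coding transcript id within `set`.
#' @param genome A `snpreanno_genome`.
#' @return List with `seq` (character), `positions` (integer vector,
#'   genomic coordinates in 5'->3' transcript order), `strand`, `contig`,
#'   `transcript_id`.
#' @export
assemble_cds <- function(set, transcript_id, genome) {
  stopifnot(inherits(set, "snpreanno_set"))
  r <- match(transcript_id, set$transcripts$transcript_id)
  if (is.na(r)) stop("transcript '", transcript_id, "' not in set '", set$name, "'")
  tx <- set$transcripts[r, ]
  if (!tx$is_coding) stop("transcript '", transcript_id, "' has no CDS")
  ex <- set$exons[set$exons$transcript_id == transcript_id, , drop = FALSE]
  cs <- pmax(ex$start, tx$cds_start)
  ce <- pmin(ex$end, tx$cds_end)
  keep <- cs <= ce
  if (!any(keep)) stop("CDS of '", transcript_id, "' has length 0")
  cs <- cs[keep]; ce <- ce[keep]
  positions <- unlist(mapply(seq.int, cs, ce, SIMPLIFY = FALSE))
  chunks <- mapply(function(s, e) genome_slice(genome, tx$contig, s, e), cs, ce)
  seq <- paste(chunks, collapse = "")
  if (tx$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    positions <- rev(positions)
  }
  list(seq = seq, positions = as.integer(positions), strand = tx$strand,
       contig = tx$contig, transcript_id = transcript_id)
}

# amino acid of one codon under the standard genetic code ("*" = stop)
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# kind from the two amino acids; stop-preserving changes count as synonymous
consequence_kind_from_aa <- function(ref_aa, alt_aa) {
  if (ref_aa != "*" && alt_aa == "*") "STOPGAIN"
  else if (ref_aa == "*" && alt_aa != "*") "STOPLOSS"
  else if (ref_aa == alt_aa) "SYNONYMOUS"
  else "NONSYNONYMOUS"
}

#' Call the coding consequence of a variant in one transcript
#'
#' The reference codon is read from the genome (a variant whose stated ref
#' allele disagrees with the genome base is still processed, with
#' `ref_mismatch = TRUE`); the alternative allele is complemented for
#' minus-strand transcripts before substitution. A missing alternative
#' allele, or a variant falling in a trailing partial codon of a CDS whose
#' length is not a multiple of 3, yields kind UNKNOWN.
#'
#' @param v One-row variant data.frame.
#' @param set A `snpreanno_set`.
#' @param transcript_id Coding transcript the variant falls in.
#' @param genome A `snpreanno_genome`.
#' @return One-row data.frame: variant_id, set_name, transcript_id, gene_id,
#'   kind, codon_index, ref_codon, alt_codon, ref_aa, alt_aa, ref_mismatch.
#' @export
call_consequence <- function(v, set, transcript_id, genome) {
  v <- v[1, , drop = FALSE]
  cds <- assemble_cds(set, transcript_id, genome)
  off <- match(v$position, cds$positions) - 1L
  if (is.na(off))
    stop("variant ", v$variant_id, " at ", v$contig, ":", v$position,
         " is outside the CDS of '", transcript_id, "'")
  tx <- set$transcripts[match(transcript_id, set$transcripts$transcript_id), ]
  genome_ref <- genome_base(genome, v$contig, v$position)
  ref_mismatch <- !is.na(v$ref) && v$ref != genome_ref
  codon_index <- off %/% 3L + 1L
  within <- off %% 3L + 1L
  res <- data.frame(variant_id = v$variant_id, set_name = set$name,
                    transcript_id = transcript_id, gene_id = tx$gene_id,
                    kind = "UNKNOWN", codon_index = codon_index,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    ref_mismatch = ref_mismatch, stringsAsFactors = FALSE)
  if (codon_index * 3L > nchar(cds$seq)) return(res) # trailing partial codon
  ref_codon <- substr(cds$seq, (codon_index - 1L) * 3L + 1L, codon_index * 3L)
  res$ref_codon <- ref_codon
  res$ref_aa <- codon_aa(ref_codon)
  if (is.na(v$alt)) return(res) # allele information unavailable
  alt_tx <- if (cds$strand == "-") COMPLEMENT[[v$alt]] else v$alt
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_tx
  res$alt_codon <- alt_codon
  res$alt_aa <- codon_aa(alt_codon)
  res$kind <- consequence_kind_from_aa(res$ref_aa, res$alt_aa)
  res
}

#' Most severe consequence across transcripts
#'
#' Severity: STOPGAIN = STOPLOSS > NONSYNONYMOUS > SYNONYMOUS > UNKNOWN;
#' ties are broken by transcript_id.
#'
#' @param consequences Data.frame of [call_consequence()] rows (>= 1).
#' @return The single most severe row.
#' @export
most_severe <- function(consequences) {
  stopifnot(is.data.frame(consequences))
  if (!nrow(consequences)) stop("most_severe() needs a non-empty consequence set")
  rank_map <- c(STOPGAIN = 1, STOPLOSS = 1, NONSYNONYMOUS = 2,
                SYNONYMOUS = 3, UNKNOWN = 4)
  ord <- order(rank_map[consequences$kind], consequences$transcript_id)
  consequences[ord[1], , drop = FALSE]
}
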