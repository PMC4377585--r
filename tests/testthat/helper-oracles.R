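# Independent brute-force oracles and small in-code fixtures. None of these
# share code with the package's classification / overlap / integration
# paths: plain loops and vector arithmetic only.

# write a named character vector of sequences as a FASTA and open it
make_test_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  read_genome(path)
}

# brute-force per-base classifier over one contig of length L:
# per-transcript category vectors built by direct interval arithmetic,
# reduced across transcripts by severity rank
brute_classify_all <- function(set, t, L) {
  cats <- region_categories()
  ranks <- rep(9L, L)
  for (i in seq_len(nrow(set$transcripts))) {
    tx <- set$transcripts[i, ]
    ex <- set$exons[set$exons$transcript_id == tx$transcript_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    tcat <- rep(NA_character_, L)
    if (tx$strand == "+") {
      ps <- max(1L, tx$tx_start - t$promoter_window_bp); pe <- tx$tx_start - 1L
    } else {
      ps <- tx$tx_end + 1L; pe <- min(L, tx$tx_end + t$promoter_window_bp)
    }
    if (ps <= pe) tcat[ps:pe] <- "PROMOTER"
    tcat[tx$tx_start:tx$tx_end] <- "INTRONIC"
    if (nrow(ex) > 1L) for (k in seq_len(nrow(ex) - 1L)) {
      istart <- ex$end[k] + 1L; iend <- ex$start[k + 1L] - 1L
      if (istart > iend) next
      ipos <- istart:iend
      d <- pmin(ipos - ex$end[k], ex$start[k + 1L] - ipos)
      tcat[ipos[d <= t$splice_window_bp]] <- "SPLICE"
    }
    for (k in seq_len(nrow(ex))) {
      epos <- ex$start[k]:ex$end[k]
      if (tx$is_coding) {
        utr5 <- if (tx$strand == "+") epos < tx$cds_start else epos > tx$cds_end
        utr3 <- if (tx$strand == "+") epos > tx$cds_end else epos < tx$cds_start
        tcat[epos[utr5]] <- "UTR5"
        tcat[epos[utr3]] <- "UTR3"
        tcat[epos[!utr5 & !utr3]] <- "CDS"
      } else {
        tcat[epos] <- "NCRNA_EXONIC"
      }
    }
    r <- match(tcat, cats)
    r[is.na(r)] <- 9L
    ranks <- pmin(ranks, r)
  }
  ifelse(ranks == 9L, "INTERGENIC", cats[pmin(ranks, 8L)])
}

# consequence-kind oracle: seqinr translation plus the kind rules applied
# directly to the two amino acids (stop-preserving changes are synonymous)
oracle_kind <- function(ref_codon, alt_codon) {
  ra <- seqinr::translate(tolower(strsplit(ref_codon, "")[[1]]))
  aa <- seqinr::translate(tolower(strsplit(alt_codon, "")[[1]]))
  if (ra != "*" && aa == "*") "STOPGAIN"
  else if (ra == "*" && aa != "*") "STOPLOSS"
  else if (ra == aa) "SYNONYMOUS"
  else "NONSYNONYMOUS"
}

# a tiny two-gene plus/minus-strand annotation set used across tests:
#   gplus: + strand, exons 101-150 / 201-260 / 301-350, CDS 121-330
#   gminus: - strand, exons 1101-1150 / 1201-1250, noncoding
tiny_set <- function(name = "tiny", role = "baseline") {
  annotation_set(
    name, role,
    transcripts = data.frame(
      transcript_id = c("tplus.1", "tminus.1"),
      gene_id = c("gplus", "gminus"),
      contig = "chrT", strand = c("+", "-"),
      cds_start = c(121L, NA), cds_end = c(330L, NA)),
    exons = data.frame(
      transcript_id = c("tplus.1", "tplus.1", "tplus.1", "tminus.1", "tminus.1"),
      start = c(101L, 201L, 301L, 1101L, 1201L),
      end = c(150L, 260L, 350L, 1150L, 1250L)))
}

# one-variant helper
v1 <- function(id, pos, ref = NA, alt = NA, contig = "chrT") {
  variant_table(id, contig, pos, ref, alt)
}

# reduced fixture used where every genomic position is checked exhaustively
small_fixture_spec <- function() {
  fixture_spec(contig_length = 20000L,
               n_shared_coding = 1L, n_shared_noncoding = 1L,
               n_missing_exon = 1L, n_absent_coding = 1L,
               n_absent_noncoding = 0L, n_cds_extent = 0L,
               coding_plan = data.frame(
                 kind = c("SYNONYMOUS", "STOPLOSS"),
                 host = c("missing_exon", "absent")),
               n_intergenic = 1L)
}

# run the 576-substitution enumeration; returns data.frame with the
# implementation's kind and the oracle's kind for every case
enumerate_codon_substitutions <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  # one long plus-strand CDS carrying every codon once: ATG <64 codons> TAA
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  genome_seq <- paste0(strrep("A", 50), cds, strrep("A", 50))
  genome <- make_test_genome(c(chrE = genome_seq))
  set <- annotation_set(
    "enum", "alternative",
    transcripts = data.frame(transcript_id = "te.1", gene_id = "ge",
                             contig = "chrE", strand = "+",
                             cds_start = 51L, cds_end = 50L + nchar(cds)),
    exons = data.frame(transcript_id = "te.1", start = 51L,
                       end = 50L + nchar(cds)))
  rows <- list()
  for (ci in seq_along(codons)) {
    codon <- codons[ci]
    codon_start <- 50L + 3L + (ci - 1L) * 3L # genomic, after the ATG
    for (within in 1:3) {
      pos <- codon_start + within
      ref <- substr(codon, within, within)
      for (alt in setdiff(bases, ref)) {
        got <- call_consequence(v1("e", pos, ref, alt, "chrE"), set, "te.1",
                                genome)
        alt_codon <- codon
        substr(alt_codon, within, within) <- alt
        rows[[length(rows) + 1L]] <- data.frame(
          codon = codon, within = within, alt = alt,
          impl = got$kind, oracle = oracle_kind(codon, alt_codon),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# mirror a variant table / annotation set through position L - p + 1 with
# strands flipped and alleles complemented (the plus strand of the mirrored
# genome is the reverse complement of the original)
mirror_positions <- function(p, L) L - p + 1L

mirror_variants <- function(v, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v$position <- mirror_positions(v$position, L)
  v$ref <- ifelse(is.na(v$ref), NA, unname(comp[v$ref]))
  v$alt <- ifelse(is.na(v$alt), NA, unname(comp[v$alt]))
  v
}

mirror_set <- function(set, L) {
  tx <- set$transcripts
  ex <- set$exons
  new_tx <- data.frame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    contig = tx$contig, strand = ifelse(tx$strand == "+", "-", "+"),
    cds_start = mirror_positions(tx$cds_end, L),
    cds_end = mirror_positions(tx$cds_start, L))
  new_ex <- data.frame(transcript_id = ex$transcript_id,
                       start = mirror_positions(ex$end, L),
                       end = mirror_positions(ex$start, L))
  annotation_set(set$name, set$role, new_tx, new_ex)
}

mirror_genome <- function(genome, contig) {
  seq <- genome_slice(genome, contig, 1L, unname(contig_lengths(genome)[contig]))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  make_test_genome(stats::setNames(list(rc), contig))
}

# run the whole pipeline on a generated fixture and compare every output to
# the generator's ground truth; returns a named logical vector
planted_truth_recovery <- function(seed, spec = fixture_spec()) {
  d <- file.path(tempdir(), paste0("fx_recovery_", seed))
  fx <- generate_fixture(spec, d, seed = seed)
  tv <- fx$truth$variants
  tg <- fx$truth$genes
  inp <- load_annotation_dir(d)
  res <- suppressMessages(suppressWarnings(
    run_pipeline(inp$variants, inp$baseline, inp$alt_sets, inp$genome,
                 inp$tracks, inp$expression)))
  out <- c()
  bc <- res$baseline_calls$calls
  m <- match(tv$variant_id, bc$variant_id)
  out["baseline_categories"] <- all(bc$category[m] == tv$baseline_category)
  out["filter_partition"] <-
    setequal(res$filter$removed$variant_id, tv$variant_id[tv$filter_removed]) &&
    nrow(res$filter$kept) + nrow(res$filter$removed) == nrow(tv)
  kept <- tv[!tv$filter_removed, , drop = FALSE]
  for (cl in res$alt_calls) {
    mm <- match(kept$variant_id, cl$calls$variant_id)
    out[paste0("categories_", cl$set_name)] <-
      all(cl$calls$category[mm] == kept[[paste0("category_", cl$set_name)]])
    out[paste0("genes_", cl$set_name)] <-
      all(cl$calls$gene_ids[mm] == kept[[paste0("gene_", cl$set_name)]])
  }
  dd <- res$deltas$deltas
  mm <- match(kept$variant_id, dd$variant_id)
  out["reannotated_flags"] <- all(dd$is_reannotated[mm] == kept$is_reannotated)
  out["coding_support"] <- all(dd$coding_support[mm] == kept$coding_support)
  ck <- kept[kept$coding_support >= 1 & kept$is_reannotated, , drop = FALSE]
  kinds <- vapply(ck$variant_id, function(id)
    most_severe(res$consequences[res$consequences$variant_id == id, ,
                                 drop = FALSE])$kind, "")
  out["consequence_kinds"] <- all(kinds == ck$consequence_kind)
  out["has_intronic_to_cds"] <-
    any(kept$baseline_category == "INTRONIC" & kept$coding_support >= 1)
  out["has_intergenic_to_cds"] <-
    any(kept$baseline_category == "INTERGENIC" & kept$coding_support >= 1)
  got <- split(res$profiles$pairs$feature_class, res$profiles$pairs$variant_id)
  exp_classes <- strsplit(kept$regulatory_classes, ",", fixed = TRUE)
  out["regulatory_classes"] <- all(vapply(seq_len(nrow(kept)), function(i)
    setequal(got[[kept$variant_id[i]]],
             exp_classes[[i]][nzchar(exp_classes[[i]])]), TRUE))
  out["expressed_genes"] <-
    setequal(res$expression_flags$genes, tg$gene_id[tg$expressed])
  out["tissue_specific"] <-
    setequal(res$tissue_specific, tg$gene_id[tg$tissue_specific])
  unlink(d, recursive = TRUE)
  out
}
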