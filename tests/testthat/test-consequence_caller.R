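# a one-gene genome used throughout: + strand CDS "ATG GCC TAA" at 101-109,
# with a UTR pad either side inside a single exon 91-119
cons_fixture <- function(strand = "+") {
  if (strand == "+") {
    seq <- paste0(strrep("T", 100), "ATGGCCTAA", strrep("T", 91))
    cds <- c(101L, 109L)
  } else {
    # reverse complement of ATGGCCTAA is TTAGGCCAT; transcript reads 5'->3'
    # from the genomic right
    seq <- paste0(strrep("T", 100), "TTAGGCCAT", strrep("T", 91))
    cds <- c(101L, 109L)
  }
  genome <- make_test_genome(c(chrC = seq))
  set <- annotation_set(
    "cons", "alternative",
    transcripts = data.frame(transcript_id = "tc.1", gene_id = "gc",
                             contig = "chrC", strand = strand,
                             cds_start = cds[1], cds_end = cds[2]),
    exons = data.frame(transcript_id = "tc.1", start = 91L, end = 119L))
  list(genome = genome, set = set)
}

test_that("CDS assembly is strand-aware and offset-exact", {
  fp <- cons_fixture("+")
  cds <- assemble_cds(fp$set, "tc.1", fp$genome)
  expect_identical(cds$seq, "ATGGCCTAA")
  expect_identical(cds$positions, 101:109)

  fm <- cons_fixture("-")
  cdsm <- assemble_cds(fm$set, "tc.1", fm$genome)
  expect_identical(cdsm$seq, "ATGGCCTAA")
  expect_identical(cdsm$positions, 109:101) # 5'->3' runs genomically right to left

  expect_error(assemble_cds(tiny_set(), "tminus.1", fp$genome), "no CDS")
})

test_that("a CDS split across an intron concatenates exonic bases only", {
  # exon1 31-36 (ATGGCA), intron, exon2 101-103 (TAA)
  g <- make_test_genome(c(chrC = paste0(strrep("C", 30), "ATGGCA",
                                        strrep("C", 64), "TAA",
                                        strrep("C", 30))))
  s <- annotation_set(
    "split", "alternative",
    transcripts = data.frame(transcript_id = "ts.1", gene_id = "gs",
                             contig = "chrC", strand = "+",
                             cds_start = 31L, cds_end = 103L),
    exons = data.frame(transcript_id = c("ts.1", "ts.1"),
                       start = c(31L, 101L), end = c(36L, 103L)))
  cds <- assemble_cds(s, "ts.1", g)
  expect_identical(cds$seq, "ATGGCATAA")
  # manual base-by-base walk of the expected offset map
  expect_identical(cds$positions, c(31:36, 101:103))
  # a variant in the second exon lands in codon 3
  got <- call_consequence(v1("rsx", 101, "T", "C", "chrC"), s, "ts.1", g)
  expect_identical(got$codon_index, 3L)
  expect_identical(got$ref_codon, "TAA")
})

test_that("codon-level kinds match the worked substitutions on both strands", {
  for (strand in c("+", "-")) {
    f <- cons_fixture(strand)
    # GCC -> GCA (Ala -> Ala): position = 3rd base of codon 2
    pos <- if (strand == "+") 106L else 104L
    ref <- if (strand == "+") "C" else "G"
    alt <- if (strand == "+") "A" else "T"
    got <- call_consequence(v1("syn", pos, ref, alt, "chrC"), f$set, "tc.1",
                            f$genome)
    expect_identical(got$kind, "SYNONYMOUS")
    expect_identical(got$ref_codon, "GCC")
    expect_identical(got$alt_codon, "GCA")
    expect_identical(got$codon_index, 2L)
    # terminal TAA -> CAA: stop loss
    pos <- if (strand == "+") 107L else 103L
    ref <- if (strand == "+") "T" else "A"
    alt <- if (strand == "+") "C" else "G"
    got <- call_consequence(v1("sl", pos, ref, alt, "chrC"), f$set, "tc.1",
                            f$genome)
    expect_identical(got$kind, "STOPLOSS")
  }
})

test_that("stop-gain, unknown-allele and partial-codon cases are handled", {
  # CDS ATG TGG TAA: TGG -> TGA at codon 2 position 3
  g <- make_test_genome(c(chrC = paste0(strrep("A", 100), "ATGTGGTAA")))
  s <- annotation_set(
    "sg", "alternative",
    transcripts = data.frame(transcript_id = "tg.1", gene_id = "gg",
                             contig = "chrC", strand = "+",
                             cds_start = 101L, cds_end = 109L),
    exons = data.frame(transcript_id = "tg.1", start = 101L, end = 109L))
  got <- call_consequence(v1("sg", 106, "G", "A", "chrC"), s, "tg.1", g)
  expect_identical(got$kind, "STOPGAIN")
  expect_identical(got$ref_aa, "W")
  expect_identical(got$alt_aa, "*")

  # missing alternative allele -> UNKNOWN, but frame still reported
  got <- call_consequence(v1("u", 106, "G", NA, "chrC"), s, "tg.1", g)
  expect_identical(got$kind, "UNKNOWN")
  expect_identical(got$codon_index, 2L)
  expect_identical(got$ref_codon, "TGG")
  expect_true(is.na(got$alt_codon))

  # CDS length not divisible by 3: variant in the trailing partial codon
  s2 <- annotation_set(
    "pc", "alternative",
    transcripts = data.frame(transcript_id = "tp.1", gene_id = "gp",
                             contig = "chrC", strand = "+",
                             cds_start = 101L, cds_end = 107L),
    exons = data.frame(transcript_id = "tp.1", start = 101L, end = 109L))
  got <- call_consequence(v1("p", 107, "T", "C", "chrC"), s2, "tp.1", g)
  expect_identical(got$kind, "UNKNOWN")

  # outside the CDS -> error, caller must route elsewhere
  expect_error(call_consequence(v1("o", 50, "A", "G", "chrC"), s, "tg.1", g),
               "outside the CDS")
})

test_that("ref mismatches are flagged and alt = ref degenerates to synonymous", {
  f <- cons_fixture("+")
  got <- call_consequence(v1("mm", 106, "G", "A", "chrC"), f$set, "tc.1",
                          f$genome) # genome has C at 106
  expect_true(got$ref_mismatch)
  expect_identical(got$ref_codon, "GCC") # genome defines the ref codon
  got2 <- call_consequence(v1("same", 106, NA, "C", "chrC"), f$set, "tc.1",
                           f$genome)
  expect_identical(got2$ref_codon, got2$alt_codon)
  expect_identical(got2$kind, "SYNONYMOUS")
})

test_that("all 576 codon substitutions agree with the independent oracle", {
  skip_if_not_installed("seqinr")
  enum <- enumerate_codon_substitutions()
  expect_identical(nrow(enum), 576L)
  expect_identical(enum$impl, enum$oracle)
  # per-kind totals also agree with the oracle's own tally
  expect_identical(c(table(enum$impl)), c(table(enum$oracle)))
  # kind depends only on (codon, position, alt base): every duplicate
  # context in the enumeration already collapsed to one row each
  expect_identical(anyDuplicated(enum[, c("codon", "within", "alt")]), 0L)
})

test_that("severity fold picks the worst consequence with deterministic ties", {
  df <- data.frame(
    variant_id = "rs1", set_name = "a",
    transcript_id = c("t2", "t1", "t3"),
    gene_id = "g", kind = c("SYNONYMOUS", "NONSYNONYMOUS", "UNKNOWN"),
    stringsAsFactors = FALSE)
  expect_identical(most_severe(df)$kind, "NONSYNONYMOUS")
  expect_identical(most_severe(df[df$kind == "UNKNOWN", ])$kind, "UNKNOWN")
  tie <- data.frame(variant_id = "rs1", set_name = "a",
                    transcript_id = c("tB", "tA"), gene_id = "g",
                    kind = "NONSYNONYMOUS", stringsAsFactors = FALSE)
  expect_identical(most_severe(tie)$transcript_id, "tA")
  both <- data.frame(variant_id = "rs1", set_name = "a",
                     transcript_id = c("t1", "t2"), gene_id = "g",
                     kind = c("STOPGAIN", "NONSYNONYMOUS"),
                     stringsAsFactors = FALSE)
  expect_identical(most_severe(both)$kind, "STOPGAIN")
  expect_error(most_severe(df[0, ]), "non-empty")
})
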