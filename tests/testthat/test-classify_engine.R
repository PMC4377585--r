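test_that("interval index agrees with a linear scan over transcripts", {
  d <- tempfile()
  generate_fixture(fixture_spec(), d, seed = 31L)
  set <- parse_gene_models(file.path(d, "altC.gtf"), "gtf", "altC", "alternative")
  t <- thresholds()
  idx <- build_index(set, t)
  tx <- set$transcripts
  # extended span per transcript, computed independently of the index
  span_lo <- ifelse(tx$strand == "+", pmax(1, tx$tx_start - t$promoter_window_bp),
                    tx$tx_start)
  span_hi <- ifelse(tx$strand == "+", tx$tx_end, tx$tx_end + t$promoter_window_bp)
  set.seed(1)
  for (pos in sample.int(100000L, 300L)) {
    expected <- tx$transcript_id[span_lo <= pos & pos <= span_hi]
    got_idx <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges("chrS", IRanges::IRanges(pos, pos)), idx$gr))
    expect_setequal(idx$gr$transcript_id[got_idx], expected)
  }
  # exact exon-start coordinate is included
  pos <- set$exons$start[1]
  got <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(
    GenomicRanges::GRanges("chrS", IRanges::IRanges(pos, pos)), idx$gr))
  expect_true(set$exons$transcript_id[1] %in% idx$gr$transcript_id[got])
})

test_that("splice window is an intronic property with the 2 bp default", {
  s <- tiny_set()
  # tplus.1 exon 1 ends at 150: intron offsets 1 and 2 are SPLICE, 3 is not
  expect_identical(classify_variant(v1("a", 151), s)$category, "SPLICE")
  expect_identical(classify_variant(v1("b", 152), s)$category, "SPLICE")
  expect_identical(classify_variant(v1("c", 153), s)$category, "INTRONIC")
  # exonic bases within 2 bp of the boundary stay exonic
  expect_identical(classify_variant(v1("d", 150), s)$category, "CDS")
  # CDS / UTR / ncRNA exon calls
  expect_identical(classify_variant(v1("e", 230), s)$category, "CDS")
  expect_identical(classify_variant(v1("f", 110), s)$category, "UTR5")
  expect_identical(classify_variant(v1("g", 340), s)$category, "UTR3")
  expect_identical(classify_variant(v1("h", 1120), s)$category, "NCRNA_EXONIC")
  expect_identical(classify_variant(v1("i", 5000), s)$category, "INTERGENIC")
})

test_that("promoter windows are strand-aware, exact, and clamped", {
  expect_identical(promoter_interval(5000L, "+", 1000L),
                   data.frame(start = 4000L, end = 4999L))
  expect_identical(promoter_interval(8000L, "-", 1000L),
                   data.frame(start = 8001L, end = 9000L))
  expect_identical(promoter_interval(500L, "+", 1000L),
                   data.frame(start = 1L, end = 499L))
  expect_true(is.na(promoter_interval(1L, "+", 1000L)$start))
  cl <- promoter_interval(9950L, "-", 1000L, contig_length = 10000L)
  expect_identical(cl$end, 10000L)
  # classified promoter hits on both strands of the tiny set
  s <- tiny_set()
  expect_identical(classify_variants(v1("p1", 60), s)$calls$category,
                   "PROMOTER") # tplus TSS = 101, clamped window [1, 100]
  expect_identical(classify_variants(v1("p2", 1250 + 500), s)$calls$category,
                   "PROMOTER")
})

test_that("an intragenic hit in one gene beats a promoter hit in another", {
  s <- annotation_set(
    "two", "alternative",
    transcripts = data.frame(
      transcript_id = c("ta.1", "tb.1"), gene_id = c("ga", "gb"),
      contig = "chrT", strand = "+",
      cds_start = c(NA, NA), cds_end = c(NA, NA)),
    exons = data.frame(
      transcript_id = c("ta.1", "ta.1", "tb.1"),
      start = c(1000L, 3000L, 3500L), end = c(1100L, 3100L, 3600L)))
  # 2500 is intron of ga AND within 1 kb upstream of gb's TSS (3500)
  call <- classify_variant(v1("x", 2500), s)
  expect_identical(call$category, "INTRONIC")
  expect_identical(call$gene_ids, "ga")
})

test_that("classification is invariant to transcript input order", {
  d <- tempfile()
  fx <- generate_fixture(fixture_spec(), d, seed = 32L)
  inp <- load_annotation_dir(d)
  set <- inp$alt_sets[[1]]
  set.seed(9)
  perm <- sample.int(nrow(set$transcripts))
  shuffled <- annotation_set(set$name, set$role,
                             set$transcripts[perm, c("transcript_id", "gene_id",
                                                     "contig", "strand",
                                                     "cds_start", "cds_end")],
                             set$exons)
  a <- classify_variants(inp$variants, set)
  b <- classify_variants(inp$variants, shuffled)
  expect_identical(a$calls, b$calls)
})

test_that("classification matches the per-base brute-force classifier", {
  d <- tempfile()
  generate_fixture(small_fixture_spec(), d, seed = 33L)
  inp <- load_annotation_dir(d)
  L <- 20000L
  allpos <- variant_table(sprintf("p%06d", 1:L), "chrS", 1:L)
  set <- inp$alt_sets[[2]]
  engine <- classify_variants(allpos, set)$calls$category
  brute <- brute_classify_all(set, thresholds(), L)
  expect_identical(engine, brute)
})

test_that("enlarging the promoter window only converts INTERGENIC to PROMOTER", {
  s <- tiny_set()
  pos <- c(seq(1, 2500, by = 7), seq(900, 1400, by = 3))
  v <- variant_table(sprintf("m%04d", seq_along(pos)), "chrT", pos)
  narrow <- classify_variants(v, s, thresholds(promoter_window_bp = 500))$calls
  wide <- classify_variants(v, s, thresholds(promoter_window_bp = 2000))$calls
  changed <- narrow$category != wide$category
  expect_true(all(narrow$category[changed] == "INTERGENIC"))
  expect_true(all(wide$category[changed] == "PROMOTER"))
})

test_that("strand symmetry: mirrored genome and coordinates give identical categories", {
  L <- 5000L
  s <- annotation_set(
    "mir", "baseline",
    transcripts = data.frame(transcript_id = "t1.1", gene_id = "g1",
                             contig = "chrT", strand = "+",
                             cds_start = 1021L, cds_end = 1330L),
    exons = data.frame(transcript_id = c("t1.1", "t1.1", "t1.1"),
                       start = c(1001L, 1201L, 1301L),
                       end = c(1050L, 1260L, 1350L)))
  pos <- seq(1L, L, by = 13L)
  v <- variant_table(sprintf("s%04d", seq_along(pos)), "chrT", pos)
  orig <- classify_variants(v, s)$calls$category
  mv <- v
  mv$position <- mirror_positions(v$position, L)
  mirrored <- classify_variants(mv, mirror_set(s, L))$calls$category
  expect_identical(orig, mirrored)
})

test_that("baseline noncoding filter removes coding-gene exonic and splice hits", {
  s <- tiny_set()
  v <- rbind(v1("in_cds", 230, "A", "G"),     # removed: CDS
             v1("in_utr5", 110),              # removed: UTR5
             v1("in_splice", 152),            # removed: splice window
             v1("deep_intron", 170),          # kept
             v1("nc_exon", 1120),             # kept: ncRNA exonic
             v1("far", 5000))                 # kept: intergenic
  flt <- filter_noncoding(v, s)
  expect_setequal(flt$removed$variant_id, c("in_cds", "in_utr5", "in_splice"))
  expect_identical(nrow(flt$kept) + nrow(flt$removed), nrow(v))
  # splice window of a noncoding gene is NOT removed (the filter targets
  # protein-coding genes)
  v2 <- v1("nc_splice", 1151)
  expect_identical(classify_variant(v2, s)$category, "SPLICE")
  expect_identical(filter_noncoding(v2, s)$kept$variant_id, "nc_splice")
  expect_error(filter_noncoding(v, tiny_set(role = "alternative")), "baseline")
})

test_that("category counts partition the variants for every set", {
  d <- tempfile()
  generate_fixture(fixture_spec(), d, seed = 34L)
  inp <- load_annotation_dir(d)
  calls <- lapply(c(list(inp$baseline), inp$alt_sets),
                  function(s) classify_variants(inp$variants, s))
  cc <- category_counts(calls)
  expect_identical(nrow(cc), 4L)
  for (i in seq_len(nrow(cc)))
    expect_identical(sum(as.integer(cc[i, region_categories()])),
                     nrow(inp$variants))
})

test_that("variants on contigs unknown to the set fall back to INTERGENIC", {
  expect_warning(cl <- classify_variants(v1("x", 10, contig = "chrZ"),
                                         tiny_set()),
                 "absent from set")
  expect_identical(cl$calls$category, "INTERGENIC")
})
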