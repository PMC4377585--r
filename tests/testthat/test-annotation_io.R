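test_that("GTF parsing round-trips the fixture generator's gene structure", {
  d <- tempfile()
  fx <- generate_fixture(fixture_spec(), d, seed = 21L)
  base <- parse_gene_models(file.path(d, "baseline.gtf"), "gtf",
                            "baseline", "baseline")
  tg <- fx$truth$genes
  expect_setequal(unique(base$transcripts$gene_id),
                  tg$gene_id[tg$in_baseline])
  # the baseline view of a missing-exon gene has one exon fewer
  me <- tg$gene_id[tg$mechanism == "missing_exon"][1]
  alt_name <- strsplit(tg$alt_mask[tg$gene_id == me], ",")[[1]][1]
  alt <- parse_gene_models(file.path(d, paste0(alt_name, ".gtf")), "gtf",
                           alt_name, "alternative")
  n_ex <- function(s, g) sum(s$exons$transcript_id %in%
                               s$transcripts$transcript_id[s$transcripts$gene_id == g])
  expect_identical(n_ex(base, me) + 1L, n_ex(alt, me))
  # exons stay genomically ascending on both strands
  for (tid in base$transcripts$transcript_id) {
    e <- base$exons[base$exons$transcript_id == tid, ]
    expect_true(all(diff(e$start) > 0))
  }
})

test_that("empty annotation files yield empty sets", {
  p <- tempfile(fileext = ".gtf")
  writeLines(character(), p)
  s <- parse_gene_models(p, "gtf", "empty", "baseline")
  expect_identical(nrow(s$transcripts), 0L)
  expect_identical(nrow(classify_variants(v1("rs1", 5), s)$calls), 1L)
})

test_that("genePred parsing handles both strands and noncoding transcripts", {
  # tplus.1: 3 exons, CDS 121-330 (0-based starts in genePred)
  p <- tempfile(fileext = ".genepred")
  writeLines(c(
    paste("tplus.1", "chrT", "+", 100, 350, 120, 330, 3,
          "100,200,300,", "150,260,350,", sep = "\t"),
    paste("tminus.1", "chrT", "-", 1100, 1250, 1250, 1250, 2,
          "1100,1200,", "1150,1250,", sep = "\t")), p)
  s <- parse_gene_models(p, "genepred", "gp", "alternative")
  ref <- tiny_set()
  expect_identical(s$transcripts$cds_start[1], ref$transcripts$cds_start[1])
  expect_identical(s$transcripts$cds_end[1], ref$transcripts$cds_end[1])
  expect_false(s$transcripts$is_coding[2])
  expect_identical(s$exons$start, ref$exons$start)
  expect_identical(s$exons$end, ref$exons$end)
})

test_that("VCF variant reading maps fields, drops id-less rows, dedups", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr2\t102957716\trs1420101\tC\tT\t.\t.\t.",
               "chr2\t500\trs9\tA\t.\t.\t.\t.",
               "chr2\t600\t.\tA\tG\t.\t.\t.",
               "chr2\t102957716\trs1420101\tC\tT\t.\t.\t."), p)
  expect_warning(expect_message(v <- read_variants(p, "vcf"), "duplicate"),
                 "without an identifier")
  expect_identical(nrow(v), 2L)
  expect_identical(v$variant_id[1], "rs1420101")
  expect_identical(v$position[1], 102957716L)
  expect_identical(v$ref[1], "C")
  expect_true(is.na(v$alt[v$variant_id == "rs9"]))
})

test_that("TSV variant reading auto-detects catalog-style columns", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\trisk_allele\tdisease_trait",
               "rs10\tchr1\t1234\tA\tasthma",
               "rs11\tchr1\t5678\t\theight"), p)
  v <- read_variants(p, "tsv")
  expect_identical(v$variant_id, c("rs10", "rs11"))
  expect_identical(v$alt, c("A", NA))
  expect_identical(v$trait, c("asthma", "height"))
})

test_that("BED tracks convert half-open coordinates and reject bad rows", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t101", "chr1\t200\t200", "chr1\t10\t20\tx\t3.5"), p)
  expect_warning(tr <- read_tracks(p, "EQTL"), "start >= end")
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$start[1], 100L) # covers 1-based 100-101
  expect_identical(tr$end[1], 101L)
  expect_identical(tr$score[2], 3.5)
  expect_error(read_tracks(p, "NOT_A_CLASS"), "unknown regulatory class")
  empty <- tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_identical(nrow(read_tracks(empty, "MOTIF")), 0L)
})

test_that("expression reading enforces non-negative values and unique keys", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttissue\testimate\tposterior_sd",
               "g1\tliver\t12.3\t0.4",
               "g2\tliver\t-1\t0.4"), p)
  expect_warning(e <- read_expression(p), "rejected")
  expect_identical(nrow(e), 1L)
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttissue\testimate\tposterior_sd",
               "g1\tliver\t12.3\t0.4",
               "g1\tliver\t9\t0.2"), p2)
  expect_error(read_expression(p2), "duplicated")
})

test_that("genome accessor gives uppercased random access with bounds checks", {
  g <- make_test_genome(c(chrT = "acgt"))
  expect_identical(genome_base(g, "chrT", 3), "G")
  expect_identical(genome_slice(g, "chrT", 1, 4), "ACGT")
  expect_error(genome_slice(g, "chrT", 1, 5), "out of range")
  expect_error(genome_base(g, "chrX", 1), "not in genome")
})

test_that("result tables round-trip through TSV and JSON", {
  x <- data.frame(variant_id = c("rs2", "rs1"), set_name = "altA",
                  category = c("CDS", "INTRONIC"),
                  gene_ids = c("g1", "g2"), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_results(x, p, "tsv", params = list(promoter_window_bp = 1000))
  back <- read_results(p, "tsv")
  expect_identical(back$variant_id, c("rs1", "rs2")) # deterministic order
  expect_identical(back$category, c("INTRONIC", "CDS"))
  expect_true(any(grepl("promoter_window_bp", readLines(p))))
  pj <- tempfile(fileext = ".json")
  write_results(x, pj, "json")
  backj <- read_results(pj, "json")
  expect_identical(backj$variant_id, c("rs1", "rs2"))
  # empty results still produce a parseable header-only TSV
  write_results(x[0, ], p, "tsv")
  expect_identical(nrow(read_results(p, "tsv")), 0L)
})

test_that("the VCF reader agrees with VariantAnnotation on fixture VCFs", {
  skip_if_not_installed("VariantAnnotation")
  d <- tempfile()
  generate_fixture(fixture_spec(), d, seed = 51L)
  p <- file.path(d, "variants.vcf")
  mine <- read_variants(p, "vcf")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(p))
  rr <- SummarizedExperiment::rowRanges(vcf)
  m <- match(mine$variant_id, names(rr))
  expect_false(anyNA(m))
  expect_identical(mine$position, GenomicRanges::start(rr)[m])
  expect_identical(mine$ref, as.character(rr$REF)[m])
  alt_ref <- vapply(as.list(rr$ALT)[m], function(a)
    if (length(a)) as.character(a[[1]]) else NA_character_, "")
  expect_identical(is.na(mine$alt), is.na(alt_ref) | !nzchar(alt_ref))
  both <- !is.na(mine$alt)
  expect_identical(mine$alt[both], alt_ref[both])
})
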