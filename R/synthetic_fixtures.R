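# Deterministic synthetic-fixture generator: one random contig, a baseline
# annotation set plus alternative sets that disagree with it by planned
# mechanisms, variants planted with known per-set categories and coding
# consequences, regulatory tracks, and an expression table — all with full
# ground truth, standing in for the study's external downloads.
#
# Discordance mechanisms:
#   shared       — gene identical in every set
#   missing_exon — baseline lacks one internal coding exon the masked
#                  alternative sets include (plants intronic -> CDS deltas)
#   absent       — gene entirely missing from the baseline (plants
#                  intergenic -> CDS/UTR/intronic/ncRNA/promoter deltas)
#   cds_extent   — alternative CDS extends 5' into what the baseline calls
#                  5' UTR
#
# Coding genes are laid out as 3 exons with 30 bp UTR pads and 120 bp
# introns; the CDS is ATG + random non-stop codons + TAA, written into the
# genome strand-aware, so consequence kinds can be forced by stamping chosen
# codons and alt bases from the standard genetic code.

CODING_EXON_LENS <- c(42L, 12L, 42L) # 30 UTR + 12 CDS | 12 CDS | 12 CDS + 30 UTR
INTRON_LEN <- 120L
UTR_PAD <- 30L
NC_EXON_LENS <- c(60L, 60L)

# ref codon / within-codon position / transcript-strand alt base forcing
# each consequence kind under the standard genetic code
.kind_recipes <- list(
  SYNONYMOUS = list(ref = "GCC", within = 3L, alt = "A"),   # GCC->GCA, Ala->Ala
  NONSYNONYMOUS = list(ref = "GCC", within = 1L, alt = "C"),# GCC->CCC, Ala->Pro
  STOPGAIN = list(ref = "TGG", within = 3L, alt = "A"),     # TGG->TGA, Trp->*
  STOPLOSS = list(ref = "TAA", within = 1L, alt = "C"),     # TAA->CAA, *->Gln
  UNKNOWN = list(ref = "GGC", within = 2L, alt = NA_character_))

#' Specification of a synthetic fixture
#'
#' The defaults define the study conditions the test suite runs under:
#' one 100 kb contig, a baseline plus three alternative annotation sets,
#' sixteen tissues, and a planted-variant plan covering every region
#' category, every consequence kind, and every discordance mechanism.
#'
#' @param contig Contig name.
#' @param contig_length Contig length in bp.
#' @param alt_sets Names of the alternative annotation sets.
#' @param n_shared_coding,n_shared_noncoding Genes identical in every set.
#' @param n_missing_exon Coding genes whose middle exon the baseline lacks.
#' @param n_absent_coding,n_absent_noncoding Genes absent from the baseline.
#' @param n_cds_extent Genes whose alternative CDS extends into the
#'   baseline 5' UTR.
#' @param coding_plan Data.frame (kind, host) assigning each planted coding
#'   consequence variant to a host mechanism (`"missing_exon"` or
#'   `"absent"`). STOPLOSS requires an `absent` host (the terminal stop
#'   codon sits in an exon the baseline would otherwise contain); an
#'   infeasible assignment is an error before anything is written.
#' @param n_intergenic Variants planted far from every gene and promoter.
#' @param n_decoys_per_class Regulatory track intervals covering no variant.
#' @param plant_variants When `FALSE`, no variants are planted at all: the
#'   fixture still carries a genome, valid annotation sets, decoy tracks and
#'   an expression table, plus an empty variant file.
#' @param tissues Tissue names for the expression table.
#' @return A `snpreanno_fixture_spec` list.
#' @export
fixture_spec <- function(contig = "chrS", contig_length = 100000L,
                         alt_sets = c("altA", "altB", "altC"),
                         n_shared_coding = 4L, n_shared_noncoding = 2L,
                         n_missing_exon = 3L, n_absent_coding = 3L,
                         n_absent_noncoding = 1L, n_cds_extent = 1L,
                         coding_plan = NULL, n_intergenic = 4L,
                         n_decoys_per_class = 3L, plant_variants = TRUE,
                         tissues = c("adipose", "adrenal", "brain", "breast",
                                     "colon", "heart", "kidney", "liver",
                                     "lung", "lymph_node", "ovary", "prostate",
                                     "skeletal_muscle", "testis", "thyroid",
                                     "white_blood_cells")) {
  if (is.null(coding_plan))
    coding_plan <- data.frame(
      kind = c("SYNONYMOUS", "NONSYNONYMOUS", "STOPGAIN", "UNKNOWN", "UNKNOWN",
               "SYNONYMOUS", "NONSYNONYMOUS", "STOPLOSS"),
      host = c(rep("missing_exon", 5), rep("absent", 3)),
      stringsAsFactors = FALSE)
  stopifnot(all(coding_plan$kind %in% names(.kind_recipes)),
            all(coding_plan$host %in% c("missing_exon", "absent")))
  structure(list(contig = contig, contig_length = as.integer(contig_length),
                 alt_sets = alt_sets,
                 n_shared_coding = n_shared_coding,
                 n_shared_noncoding = n_shared_noncoding,
                 n_missing_exon = n_missing_exon,
                 n_absent_coding = n_absent_coding,
                 n_absent_noncoding = n_absent_noncoding,
                 n_cds_extent = n_cds_extent,
                 coding_plan = coding_plan,
                 n_intergenic = n_intergenic,
                 n_decoys_per_class = n_decoys_per_class,
                 plant_variants = isTRUE(plant_variants),
                 tissues = tissues),
            class = "snpreanno_fixture_spec")
}

# gene blueprint: exon coordinates and (for coding genes) the full-structure
# CDS genomic span; pads are transcript-space, so they flip with strand
make_gene_blueprint <- function(gene_id, mechanism, coding, strand, g0) {
  if (coding) {
    lens <- CODING_EXON_LENS
    starts <- g0 + cumsum(c(0L, lens[-length(lens)] + INTRON_LEN))
    ends <- starts + lens - 1L
    left_pad <- UTR_PAD; right_pad <- UTR_PAD
    cds_start <- starts[1] + left_pad
    cds_end <- ends[3] - right_pad
  } else {
    lens <- NC_EXON_LENS
    starts <- g0 + cumsum(c(0L, lens[-length(lens)] + INTRON_LEN))
    ends <- starts + lens - 1L
    cds_start <- NA_integer_; cds_end <- NA_integer_
  }
  list(gene_id = gene_id, mechanism = mechanism, coding = coding,
       strand = strand, exon_start = starts, exon_end = ends,
       cds_start = cds_start, cds_end = cds_end,
       tx_start = starts[1], tx_end = ends[length(ends)])
}

# genomic positions of the CDS bases in 5'->3' transcript order
cds_positions <- function(bp, cds_start = bp$cds_start, cds_end = bp$cds_end) {
  cs <- pmax(bp$exon_start, cds_start)
  ce <- pmin(bp$exon_end, cds_end)
  keep <- cs <= ce
  pos <- unlist(mapply(seq.int, cs[keep], ce[keep], SIMPLIFY = FALSE))
  if (bp$strand == "-") rev(pos) else pos
}

random_non_stop_codons <- function(n) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- setdiff(codons, "ATG") # avoid internal starts for readability
  sample(codons, n, replace = TRUE)
}

#' Generate a synthetic fixture with ground truth
#'
#' Writes, under `dir`: `genome.fa`, `baseline.gtf`, one `<set>.gtf` per
#' alternative set, `variants.tsv` and `variants.vcf`, one
#' `tracks_<CLASS>.bed` per regulatory class, `expression.tsv`, and
#' `ground_truth.json`. Identical (spec, seed) pairs produce byte-identical
#' files; all randomness flows from `seed`.
#'
#' @param spec A `snpreanno_fixture_spec`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with `truth` (the ground-truth list), `paths`
#'   (named file paths) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir, seed = 42L) {
  stopifnot(inherits(spec, "snpreanno_fixture_spec"))
  bad <- spec$coding_plan$kind == "STOPLOSS" & spec$coding_plan$host == "missing_exon"
  if (any(bad))
    stop("infeasible coding plan: STOPLOSS needs an 'absent' host gene ",
         "(the terminal stop codon lies in an exon the baseline contains)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  genome <- sample(c("A", "C", "G", "T"), spec$contig_length, replace = TRUE)

  ## ---- gene layout ------------------------------------------------------
  plan <- rbind(
    data.frame(mechanism = "shared", coding = TRUE,
               n = spec$n_shared_coding),
    data.frame(mechanism = "shared_nc", coding = FALSE,
               n = spec$n_shared_noncoding),
    data.frame(mechanism = "missing_exon", coding = TRUE,
               n = spec$n_missing_exon),
    data.frame(mechanism = "absent", coding = TRUE,
               n = spec$n_absent_coding),
    data.frame(mechanism = "absent_nc", coding = FALSE,
               n = spec$n_absent_noncoding),
    data.frame(mechanism = "cds_extent", coding = TRUE,
               n = spec$n_cds_extent))
  mech <- rep(plan$mechanism, plan$n)
  coding <- rep(plan$coding, plan$n)
  n_genes <- length(mech)
  slot <- 400L + INTRON_LEN * 2L + max(sum(CODING_EXON_LENS), sum(NC_EXON_LENS)) + 3000L
  if (2000L + n_genes * slot > spec$contig_length)
    stop("infeasible plan: ", n_genes, " genes do not fit on a ",
         spec$contig_length, " bp contig")
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    genes[[i]] <- make_gene_blueprint(
      gene_id = sprintf("g%02d_%s", i, mech[i]),
      mechanism = mech[i], coding = coding[i],
      strand = if (i %% 2L == 0L) "-" else "+",
      g0 = 2000L + (i - 1L) * slot)
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  n_alts <- length(spec$alt_sets)
  alt_mask <- lapply(genes, function(g) {
    if (g$mechanism %in% c("shared", "shared_nc")) spec$alt_sets
    else sort(sample(spec$alt_sets, sample.int(n_alts, 1L)))
  })

  ## ---- write CDS sequences into the genome ------------------------------
  # stamp planted codons first, then lay the whole CDS down strand-aware
  planted_codons <- list() # gene_id -> list(codon_index, recipe, kind)
  host_pool <- list(
    missing_exon = names(genes)[mech == "missing_exon"],
    absent = names(genes)[mech == "absent"])
  slot_cursor <- stats::setNames(rep(0L, n_genes), names(genes))
  host_cursor <- c(missing_exon = 0L, absent = 0L)
  coding_plan <- if (spec$plant_variants) spec$coding_plan else
    spec$coding_plan[0, , drop = FALSE]
  for (r in seq_len(nrow(coding_plan))) {
    kind <- coding_plan$kind[r]
    host <- coding_plan$host[r]
    pool <- host_pool[[host]]
    if (!length(pool))
      stop("infeasible plan: no '", host, "' gene available for a ", kind,
           " variant")
    recipe <- .kind_recipes[[kind]]
    if (kind == "STOPLOSS") {
      gid <- pool[host_cursor[host] %% length(pool) + 1L]
      codon_index <- 12L # the terminal stop codon
    } else {
      # exon-2 codons are indexes 5..8; rotate genes, then slots
      placed <- FALSE
      for (try in seq_along(pool)) {
        gid <- pool[(host_cursor[host] + try - 1L) %% length(pool) + 1L]
        if (slot_cursor[gid] < 4L) { placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible plan: exon-2 codon slots exhausted for host '",
             host, "'")
      codon_index <- 5L + slot_cursor[gid]
      slot_cursor[gid] <- slot_cursor[gid] + 1L
    }
    host_cursor[host] <- host_cursor[host] + 1L
    planted_codons[[gid]] <- c(planted_codons[[gid]],
                               list(list(codon_index = codon_index,
                                         kind = kind, recipe = recipe)))
  }
  cds_info <- list() # gene_id -> list(positions, seq)
  for (g in genes) {
    if (!g$coding) next
    n_codons <- 12L
    codons <- c("ATG", random_non_stop_codons(n_codons - 2L), "TAA")
    for (pl in planted_codons[[g$gene_id]])
      if (pl$kind != "STOPLOSS") codons[pl$codon_index] <- pl$recipe$ref
    cds_seq <- strsplit(paste(codons, collapse = ""), "")[[1]]
    pos <- cds_positions(g)
    stopifnot(length(pos) == length(cds_seq))
    if (g$strand == "+") genome[pos] <- cds_seq
    else genome[pos] <- COMPLEMENT[cds_seq]
    cds_info[[g$gene_id]] <- list(positions = pos, seq = cds_seq)
  }

  ## ---- plant variants ---------------------------------------------------
  vrows <- list()
  add_variant <- function(pos, role, gene = NA_character_, alt = NULL,
                          kind = NA_character_, baseline_cat, alt_cat,
                          unmasked_cat = "INTERGENIC", removed = FALSE,
                          reannotated = FALSE, coding_sets = 0L) {
    ref <- genome[pos]
    if (is.null(alt)) alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    vrows[[length(vrows) + 1L]] <<- list(
      position = as.integer(pos), role = role, gene = gene, ref = ref,
      alt = alt, kind = kind, baseline_cat = baseline_cat, alt_cat = alt_cat,
      unmasked_cat = unmasked_cat, removed = removed,
      reannotated = reannotated, coding_sets = as.integer(coding_sets))
  }
  # transcript-space 5' / 3' ends in genomic coordinates
  five_prime_pad_pos <- function(g, off) # off bases into the 5' UTR pad
    if (g$strand == "+") g$tx_start + off else g$tx_end - off
  three_prime_pad_pos <- function(g, off)
    if (g$strand == "+") g$tx_end - off else g$tx_start + off

  shared_coding <- genes[mech == "shared"]
  shared_nc <- genes[mech == "shared_nc"]
  pick <- function(pool, i) pool[[(i - 1L) %% length(pool) + 1L]]
  if (spec$plant_variants) {
  for (i in seq_len(3L)) { # baseline CDS hits (removed by the filter)
    g <- pick(shared_coding, i)
    add_variant(cds_positions(g)[4L + i], "shared_cds", g$gene_id,
                baseline_cat = "CDS", alt_cat = "CDS", removed = TRUE,
                coding_sets = n_alts)
  }
  for (i in seq_len(2L)) {
    g <- pick(shared_coding, i)
    add_variant(five_prime_pad_pos(g, 10L + i), "shared_utr5", g$gene_id,
                baseline_cat = "UTR5", alt_cat = "UTR5", removed = TRUE)
    g2 <- pick(shared_coding, i + 1L)
    add_variant(three_prime_pad_pos(g2, 10L + i), "shared_utr3", g2$gene_id,
                baseline_cat = "UTR3", alt_cat = "UTR3", removed = TRUE)
    g3 <- pick(shared_coding, i + 2L)
    add_variant(g3$exon_end[i] + 2L, "shared_splice", g3$gene_id,
                baseline_cat = "SPLICE", alt_cat = "SPLICE", removed = TRUE)
    g4 <- pick(shared_coding, i)
    add_variant(if (g4$strand == "+") g4$tx_start - 200L - i else g4$tx_end + 200L + i,
                "shared_promoter", g4$gene_id,
                baseline_cat = "PROMOTER", alt_cat = "PROMOTER")
    g5 <- pick(shared_nc, i)
    add_variant(g5$exon_start[1] + 25L + i, "shared_ncrna", g5$gene_id,
                baseline_cat = "NCRNA_EXONIC", alt_cat = "NCRNA_EXONIC")
  }
  for (i in seq_len(4L)) { # deep-intronic, retained, never re-annotated
    g <- pick(shared_coding, i)
    add_variant(g$exon_end[2] + 60L + i, "shared_intronic", g$gene_id,
                baseline_cat = "INTRONIC", alt_cat = "INTRONIC")
  }
  # planted coding-consequence variants (the re-annotation core)
  for (gid in names(planted_codons)) {
    g <- genes[[gid]]
    ci <- cds_info[[gid]]
    for (pl in planted_codons[[gid]]) {
      off <- (pl$codon_index - 1L) * 3L + pl$recipe$within - 1L
      pos <- ci$positions[off + 1L]
      alt_plus <- if (is.na(pl$recipe$alt)) NA_character_
      else if (g$strand == "-") COMPLEMENT[[pl$recipe$alt]] else pl$recipe$alt
      add_variant(pos, paste0("coding_", tolower(pl$kind)), gid,
                  alt = alt_plus, kind = pl$kind,
                  baseline_cat = if (g$mechanism == "missing_exon") "INTRONIC"
                  else "INTERGENIC",
                  alt_cat = "CDS",
                  unmasked_cat = if (g$mechanism == "missing_exon") "INTRONIC"
                  else "INTERGENIC",
                  reannotated = TRUE, coding_sets = length(alt_mask[[gid]]))
    }
  }
  # other re-annotation patterns on baseline-absent genes
  absent_coding <- genes[mech == "absent"]
  if (length(absent_coding)) {
    g <- pick(absent_coding, 1L)
    add_variant(five_prime_pad_pos(g, 10L), "reannot_utr5", g$gene_id,
                baseline_cat = "INTERGENIC", alt_cat = "UTR5", reannotated = TRUE)
    g <- pick(absent_coding, 2L)
    add_variant(three_prime_pad_pos(g, 10L), "reannot_utr3", g$gene_id,
                baseline_cat = "INTERGENIC", alt_cat = "UTR3", reannotated = TRUE)
    for (i in seq_len(2L)) {
      g <- pick(absent_coding, i)
      add_variant(g$exon_end[2] + 60L + i, "reannot_intronic", g$gene_id,
                  baseline_cat = "INTERGENIC", alt_cat = "INTRONIC",
                  reannotated = TRUE)
      g2 <- pick(absent_coding, i + 1L)
      add_variant(if (g2$strand == "+") g2$tx_start - 150L - i else g2$tx_end + 150L + i,
                  "reannot_promoter", g2$gene_id,
                  baseline_cat = "INTERGENIC", alt_cat = "PROMOTER",
                  reannotated = TRUE)
    }
  }
  if (any(mech == "absent_nc")) {
    g <- genes[[which(mech == "absent_nc")[1]]]
    add_variant(g$exon_start[1] + 30L, "reannot_ncrna", g$gene_id,
                baseline_cat = "INTERGENIC", alt_cat = "NCRNA_EXONIC",
                reannotated = TRUE)
  }
  for (gid in names(genes)[mech == "cds_extent"]) {
    g <- genes[[gid]]
    add_variant(five_prime_pad_pos(g, 20L), "cds_extent", gid,
                baseline_cat = "UTR5", alt_cat = "CDS",
                unmasked_cat = "UTR5", removed = TRUE,
                coding_sets = length(alt_mask[[gid]]))
  }
  for (i in seq_len(spec$n_intergenic)) { # mid-gap positions, far from genes
    pos <- 2000L + i * slot - 1500L
    add_variant(pos, "intergenic", baseline_cat = "INTERGENIC",
                alt_cat = "INTERGENIC")
  }
  } # plant_variants

  ## ---- assemble the variant/truth tables -------------------------------
  n_var <- length(vrows)
  get <- function(f) {
    if (!n_var) return(vector(mode = "character", 0L))
    vapply(vrows, `[[`, vrows[[1]][[f]], f)
  }
  vt <- data.frame(variant_id = sprintf("rs%05d", seq_len(n_var)),
                   contig = rep(spec$contig, n_var),
                   position = if (n_var) get("position") else integer(),
                   ref = as.character(get("ref")),
                   alt = as.character(get("alt")),
                   trait = rep(c("trait_A", "trait_B", NA_character_),
                               length.out = n_var),
                   stringsAsFactors = FALSE)
  # per-set truth categories
  set_cats <- matrix("", n_var, n_alts, dimnames = list(NULL, spec$alt_sets))
  set_gene <- matrix("", n_var, n_alts, dimnames = list(NULL, spec$alt_sets))
  base_gene <- character(n_var)
  for (i in seq_len(n_var)) {
    r <- vrows[[i]]
    for (s in spec$alt_sets) {
      if (is.na(r$gene)) { set_cats[i, s] <- "INTERGENIC"; next }
      masked <- s %in% alt_mask[[r$gene]]
      cat_s <- if (masked) r$alt_cat else {
        gm <- genes[[r$gene]]$mechanism
        if (gm %in% c("absent", "absent_nc")) "INTERGENIC" else r$unmasked_cat
      }
      set_cats[i, s] <- cat_s
      set_gene[i, s] <- if (cat_s == "INTERGENIC") "" else r$gene
    }
    base_gene[i] <- if (is.na(r$gene) || r$baseline_cat == "INTERGENIC") ""
    else r$gene
  }
  coding_support_truth <- rowSums(set_cats == "CDS")
  truth_variants <- data.frame(
    vt,
    role = get("role"),
    anchor_gene = ifelse(is.na(get("gene")), "", get("gene")),
    baseline_category = get("baseline_cat"),
    baseline_gene = base_gene,
    filter_removed = get("removed"),
    is_reannotated = get("reannotated"),
    coding_support = as.integer(coding_support_truth),
    consequence_kind = get("kind"),
    stringsAsFactors = FALSE)
  for (s in spec$alt_sets) {
    truth_variants[[paste0("category_", s)]] <- set_cats[, s]
    truth_variants[[paste0("gene_", s)]] <- set_gene[, s]
  }
  stopifnot(!anyDuplicated(truth_variants$position))

  ## ---- regulatory tracks ------------------------------------------------
  classes <- regulatory_classes()
  k_per_variant <- sample(c(0L, 0L, 1L, 1L, 2L, 3L, 4L), n_var, replace = TRUE)
  planted_classes <- lapply(k_per_variant, function(k)
    if (k == 0L) character() else sort(sample(classes, k)))
  track_rows <- list()
  for (i in seq_len(n_var)) {
    for (cl in planted_classes[[i]]) {
      # single-base intervals: variants can sit 1 bp apart, so wider planted
      # intervals would silently extend a neighbour's class set
      track_rows[[length(track_rows) + 1L]] <- data.frame(
        contig = spec$contig, bed_start = vt$position[i] - 1L,
        bed_end = vt$position[i], feature_class = cl,
        stringsAsFactors = FALSE)
    }
  }
  for (cl in classes) { # decoys covering no variant
    for (j in seq_len(spec$n_decoys_per_class)) {
      p <- sample.int(spec$contig_length - 100L, 1L)
      while (any(abs(p - vt$position) <= 60L))
        p <- (p + 137L) %% (spec$contig_length - 100L) + 1L
      track_rows[[length(track_rows) + 1L]] <- data.frame(
        contig = spec$contig, bed_start = p - 1L, bed_end = p + 9L,
        feature_class = cl, stringsAsFactors = FALSE)
    }
  }
  tracks <- do.call(rbind, track_rows)
  # truth by brute-force containment (guards against any accidental overlap
  # between a variant and another variant's interval or a decoy)
  truth_variants$regulatory_classes <- vapply(seq_len(n_var), function(i) {
    hit <- tracks$bed_start < vt$position[i] & vt$position[i] <= tracks$bed_end
    paste(sort(unique(tracks$feature_class[hit])), collapse = ",")
  }, "")

  ## ---- expression table -------------------------------------------------
  all_gene_ids <- names(genes)
  n_expr_tissues <- rep(c(2L, 0L, 1L, 5L, 3L, 1L, 0L, 4L),
                        length.out = length(all_gene_ids))
  expr_rows <- list()
  truth_genes <- list()
  boundary_done <- FALSE
  for (gi in seq_along(all_gene_ids)) {
    gid <- all_gene_ids[gi]
    expr_tissues <- if (n_expr_tissues[gi] > 0L)
      sort(sample(spec$tissues, n_expr_tissues[gi])) else character()
    for (ti in spec$tissues) {
      expressed <- ti %in% expr_tissues
      sd <- if (expressed) round(stats::runif(1, 0.2, 1.4), 3)
      else if (!boundary_done) { boundary_done <- TRUE; 1.5 }
      else round(stats::runif(1, 1.51, 3.0), 3)
      est <- if (expressed) round(stats::runif(1, 1, 300), 2)
      else round(stats::runif(1, 0, 0.9), 2)
      expr_rows[[length(expr_rows) + 1L]] <- data.frame(
        gene_id = gid, tissue = ti, estimate = est, posterior_sd = sd,
        stringsAsFactors = FALSE)
    }
    truth_genes[[gi]] <- data.frame(
      gene_id = gid, mechanism = genes[[gid]]$mechanism,
      coding = genes[[gid]]$coding, strand = genes[[gid]]$strand,
      in_baseline = !(genes[[gid]]$mechanism %in% c("absent", "absent_nc")),
      alt_mask = paste(alt_mask[[gid]], collapse = ","),
      n_expressed_tissues = length(expr_tissues),
      expressed = length(expr_tissues) >= 1L,
      tissue_specific = length(expr_tissues) == 1L,
      stringsAsFactors = FALSE)
  }
  expression <- do.call(rbind, expr_rows)
  truth_genes <- do.call(rbind, truth_genes)

  ## ---- write files ------------------------------------------------------
  paths <- write_fixture_files(spec, dir, genome, genes, alt_mask, vt,
                               tracks, expression, seed)
  truth <- list(seed = seed, contig = spec$contig,
                contig_length = spec$contig_length,
                alt_sets = spec$alt_sets,
                variants = truth_variants, genes = truth_genes)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  invisible(list(truth = truth, paths = paths, spec = spec))
}

# baseline view of a gene blueprint (or NULL if absent from the baseline)
baseline_view <- function(g) {
  switch(g$mechanism,
    absent = , absent_nc = NULL,
    missing_exon = { # drop the middle exon, keep the CDS span endpoints
      g$exon_start <- g$exon_start[-2]; g$exon_end <- g$exon_end[-2]; g
    },
    cds_extent = g, # pads already 30/30 = the baseline's shorter CDS
    g)
}

# alternative-set view; masked cds_extent genes get a 5'-extended CDS
alt_view <- function(g, set_name, mask) {
  if (!(set_name %in% mask))
    return(baseline_view(g))
  if (g$mechanism == "cds_extent") {
    ext <- 12L
    if (g$strand == "+") g$cds_start <- g$cds_start - ext
    else g$cds_end <- g$cds_end + ext
  }
  g
}

gtf_lines <- function(view_list, contig) {
  out <- character()
  for (g in view_list) {
    if (is.null(g)) next
    tid <- paste0(g$gene_id, ".t1")
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, tid)
    for (k in seq_along(g$exon_start))
      out <- c(out, paste(contig, "snpreanno", "exon", g$exon_start[k],
                          g$exon_end[k], ".", g$strand, ".", attrs, sep = "\t"))
    if (!is.na(g$cds_start)) {
      cs <- pmax(g$exon_start, g$cds_start)
      ce <- pmin(g$exon_end, g$cds_end)
      for (k in which(cs <= ce))
        out <- c(out, paste(contig, "snpreanno", "CDS", cs[k], ce[k], ".",
                            g$strand, ".", attrs, sep = "\t"))
    }
  }
  out
}

write_fixture_files <- function(spec, dir, genome, genes, alt_mask, vt,
                                tracks, expression, seed) {
  paths <- list()
  ## genome
  paths$genome <- file.path(dir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(seqs) <- spec$contig
  Biostrings::writeXStringSet(seqs, paths$genome, width = 80L)
  ## annotation sets
  hdr <- sprintf("## snpreanno fixture seed=%d contig=%s length=%d",
                 seed, spec$contig, spec$contig_length)
  paths$baseline <- file.path(dir, "baseline.gtf")
  writeLines(c(hdr, gtf_lines(lapply(genes, baseline_view), spec$contig)),
             paths$baseline)
  paths$alt <- character()
  for (s in spec$alt_sets) {
    p <- file.path(dir, paste0(s, ".gtf"))
    views <- lapply(names(genes), function(gid)
      alt_view(genes[[gid]], s, alt_mask[[gid]]))
    writeLines(c(hdr, gtf_lines(views, spec$contig)), p)
    paths$alt[s] <- p
  }
  ## variants
  paths$variants_tsv <- file.path(dir, "variants.tsv")
  con <- file(paths$variants_tsv, "w")
  writeLines(sub("^## ", "# ", hdr), con)
  utils::write.table(
    data.frame(variant_id = vt$variant_id, contig = vt$contig,
               position = vt$position,
               ref = ifelse(is.na(vt$ref), "", vt$ref),
               alt = ifelse(is.na(vt$alt), "", vt$alt),
               trait = ifelse(is.na(vt$trait), "", vt$trait)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paths$variants_vcf <- file.path(dir, "variants.vcf")
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", spec$contig, spec$contig_length),
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t")),
           if (nrow(vt)) paste(vt$contig, vt$position, vt$variant_id,
                               ifelse(is.na(vt$ref), ".", vt$ref),
                               ifelse(is.na(vt$alt), ".", vt$alt),
                               ".", ".", ".", sep = "\t"))
  writeLines(vcf, paths$variants_vcf)
  ## tracks
  paths$tracks <- character()
  for (cl in regulatory_classes()) {
    p <- file.path(dir, paste0("tracks_", cl, ".bed"))
    sub <- tracks[tracks$feature_class == cl, , drop = FALSE]
    sub <- sub[order(sub$bed_start), , drop = FALSE]
    writeLines(paste(sub$contig, sub$bed_start, sub$bed_end, sep = "\t"), p)
    paths$tracks[cl] <- p
  }
  ## expression
  paths$expression <- file.path(dir, "expression.tsv")
  con <- file(paths$expression, "w")
  writeLines(sub("^## ", "# ", hdr), con)
  utils::write.table(expression, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paths
}
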