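# End-to-end composition: baseline noncoding filter -> per-set
# classification -> re-annotation deltas -> coding consequences ->
# regulatory profiling -> expression summary.

#' Run the full re-annotation pipeline on in-memory objects
#'
#' @param variants Validated variant data.frame.
#' @param baseline Baseline `snpreanno_set`.
#' @param alt_sets List of alternative `snpreanno_set`s.
#' @param genome A `snpreanno_genome` (needed for coding consequences).
#' @param tracks Track data.frame from [read_tracks()], or NULL to skip
#'   regulatory profiling.
#' @param expression Expression data.frame from [read_expression()], or NULL
#'   to skip the expression summary.
#' @param t Thresholds.
#' @return List: `filter` (kept/removed partition), `baseline_calls`,
#'   `alt_calls`, `deltas`, `consequences`, `breakdown`,
#'   `category_counts`, `reannotation_counts`, `profiles`,
#'   `feature_distribution`, `expression_flags`, `expressed_summary`,
#'   `tissue_specific`.
#' @export
run_pipeline <- function(variants, baseline, alt_sets, genome,
                         tracks = NULL, expression = NULL, t = thresholds()) {
  flt <- filter_noncoding(variants, baseline, t)
  kept <- flt$kept
  alt_calls <- lapply(alt_sets, function(s) classify_variants(kept, s, t))
  deltas <- reannotate(kept, flt$baseline_calls, alt_calls)
  consequences <- call_cds_consequences(kept, alt_sets, alt_calls, genome)
  breakdown <- consequence_breakdown(deltas, consequences)
  profiles <- if (!is.null(tracks)) overlap_features(kept, tracks) else NULL
  expr_flags <- if (!is.null(expression)) flag_expressed(expression, t) else NULL
  list(filter = flt,
       baseline_calls = flt$baseline_calls,
       alt_calls = alt_calls,
       deltas = deltas,
       consequences = consequences,
       breakdown = breakdown,
       category_counts = category_counts(c(list(flt$baseline_calls), alt_calls)),
       reannotation_counts = reannotation_counts(deltas),
       profiles = profiles,
       feature_distribution = if (!is.null(profiles))
         feature_count_distribution(profiles) else NULL,
       expression_flags = expr_flags,
       expressed_summary = if (!is.null(expr_flags))
         expressed_gas_gene_summary(deltas, expr_flags$genes) else NULL,
       tissue_specific = if (!is.null(expression))
         tissue_specific_genes(expression, t) else NULL)
}

# consequence rows for every CDS transcript call of every alternative set
call_cds_consequences <- function(variants, alt_sets, alt_calls, genome) {
  rows <- list()
  set_by_name <- stats::setNames(alt_sets, vapply(alt_sets, `[[`, "", "name"))
  for (cl in alt_calls) {
    tc <- cl$transcript_calls
    tc <- tc[tc$category == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(tc))) {
      v <- variants[variants$variant_id == tc$variant_id[i], , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        call_consequence(v, set_by_name[[tc$set_name[i]]],
                         tc$transcript_id[i], genome)
    }
  }
  if (!length(rows))
    return(data.frame(variant_id = character(), set_name = character(),
                      transcript_id = character(), gene_id = character(),
                      kind = character(), codon_index = integer(),
                      ref_codon = character(), alt_codon = character(),
                      ref_aa = character(), alt_aa = character(),
                      ref_mismatch = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Load fixture-layout inputs from a directory
#'
#' Expects the layout [generate_fixture()] writes: `genome.fa`,
#' `baseline.gtf`, other `*.gtf` as alternative sets, `variants.tsv` (or
#' `variants.vcf`), `tracks_<CLASS>.bed`, `expression.tsv`.
#'
#' @param dir Directory path.
#' @param variant_format `"tsv"` or `"vcf"`.
#' @return List: variants, baseline, alt_sets, genome, tracks, expression.
#' @export
load_annotation_dir <- function(dir, variant_format = c("tsv", "vcf")) {
  variant_format <- match.arg(variant_format)
  gtfs <- list.files(dir, pattern = "\\.gtf$", full.names = TRUE)
  base_path <- file.path(dir, "baseline.gtf")
  if (!file.exists(base_path)) stop("no baseline.gtf in ", dir)
  alt_paths <- sort(setdiff(gtfs, base_path))
  if (!length(alt_paths)) stop("no alternative-set GTFs in ", dir)
  vfile <- file.path(dir, paste0("variants.", variant_format))
  track_paths <- sort(list.files(dir, pattern = "^tracks_.*\\.bed$",
                                 full.names = TRUE))
  track_classes <- sub("^tracks_(.*)\\.bed$", "\\1", basename(track_paths))
  expr_path <- file.path(dir, "expression.tsv")
  list(variants = read_variants(vfile, variant_format),
       baseline = parse_gene_models(base_path, "gtf", "baseline", "baseline"),
       alt_sets = lapply(alt_paths, function(p)
         parse_gene_models(p, "gtf", sub("\\.gtf$", "", basename(p)),
                           "alternative")),
       genome = read_genome(file.path(dir, "genome.fa")),
       tracks = if (length(track_paths)) read_tracks(track_paths, track_classes)
       else NULL,
       expression = if (file.exists(expr_path)) read_expression(expr_path)
       else NULL)
}

#' Run the pipeline on a fixture-layout directory and write result files
#'
#' @param dir Input directory (see [load_annotation_dir()]).
#' @param out_dir Output directory for TSV/JSON results.
#' @param t Thresholds.
#' @param variant_format `"tsv"` or `"vcf"`.
#' @return The [run_pipeline()] result list, invisibly.
#' @export
run_dir_pipeline <- function(dir, out_dir, t = thresholds(),
                             variant_format = c("tsv", "vcf")) {
  inp <- load_annotation_dir(dir, match.arg(variant_format))
  res <- run_pipeline(inp$variants, inp$baseline, inp$alt_sets, inp$genome,
                      inp$tracks, inp$expression, t)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- list(splice_window_bp = t$splice_window_bp,
                 promoter_window_bp = t$promoter_window_bp,
                 expression_sd_max = t$expression_sd_max)
  write_results(res$deltas$deltas, file.path(out_dir, "deltas.tsv"),
                "tsv", params)
  write_results(res$deltas$per_set, file.path(out_dir, "deltas_per_set.tsv"),
                "tsv", params)
  write_results(res$consequences, file.path(out_dir, "consequences.tsv"),
                "tsv", params)
  write_results(res$category_counts, file.path(out_dir, "category_counts.tsv"),
                "tsv", params)
  if (!is.null(res$profiles))
    write_results(res$profiles$pairs, file.path(out_dir, "regulatory_profiles.tsv"),
                  "tsv", params)
  if (!is.null(res$expressed_summary))
    write_results(res$expressed_summary, file.path(out_dir, "expressed_summary.tsv"),
                  "tsv", params)
  summary <- list(
    params = params,
    n_input_variants = nrow(inp$variants),
    n_removed_by_baseline_filter = nrow(res$filter$removed),
    n_noncoding_retained = nrow(res$filter$kept),
    reannotated_union = res$reannotation_counts$union_count,
    reannotated_per_set = as.list(res$reannotation_counts$per_set_count),
    coding_reclassified = sum(res$deltas$deltas$coding_support >= 1L &
                                res$deltas$deltas$is_reannotated),
    consequence_breakdown = as.list(res$breakdown),
    regulatory_coverage = if (!is.null(res$profiles))
      regulatory_coverage(res$profiles) else NULL,
    tissue_specific_genes = length(res$tissue_specific))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}
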