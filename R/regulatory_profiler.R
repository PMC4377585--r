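# Overlap of variant positions with class-labelled regulatory tracks
# (promoter/enhancer states, motifs, DNase footprints, eQTLs, conserved
# elements, TFBS, ChIP-seq protein binding) and the multi-feature coverage
# distribution.

#' Overlap variants with regulatory-feature tracks
#'
#' A variant's profile is the set of distinct feature classes whose
#' intervals contain its position (two tracks of the same class count once).
#'
#' @param variants Validated variant data.frame.
#' @param tracks Track data.frame from [read_tracks()] (1-based inclusive).
#' @return A `snpreanno_profiles` list: `pairs` — long data.frame
#'   (variant_id, feature_class), distinct; `n_classes` — named integer
#'   vector, classes per variant (0 for no overlap); `variant_ids`.
#' @export
overlap_features <- function(variants, tracks) {
  n <- nrow(variants)
  pairs <- data.frame(variant_id = character(), feature_class = character(),
                      stringsAsFactors = FALSE)
  if (n && nrow(tracks)) {
    vgr <- GenomicRanges::GRanges(variants$contig,
                                  IRanges::IRanges(variants$position,
                                                   variants$position))
    tgr <- GenomicRanges::GRanges(tracks$contig,
                                  IRanges::IRanges(tracks$start, tracks$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(vgr, tgr))
    if (length(ov)) {
      pairs <- unique(data.frame(
        variant_id = variants$variant_id[S4Vectors::queryHits(ov)],
        feature_class = tracks$feature_class[S4Vectors::subjectHits(ov)],
        stringsAsFactors = FALSE))
      pairs <- pairs[order(pairs$variant_id, pairs$feature_class), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  n_classes <- stats::setNames(integer(n), variants$variant_id)
  if (nrow(pairs)) {
    tab <- table(pairs$variant_id)
    n_classes[names(tab)] <- as.integer(tab)
  }
  structure(list(pairs = pairs, n_classes = n_classes,
                 variant_ids = variants$variant_id),
            class = "snpreanno_profiles")
}

#' Distribution of regulatory-feature class counts
#'
#' @param profiles A `snpreanno_profiles`.
#' @return Data.frame with columns `k` (0 .. number of feature classes) and
#'   `n_variants`; the counts sum to the number of profiled variants. The
#'   fraction of variants hitting at least one class is
#'   `1 - n_variants[k == 0] / sum(n_variants)`.
#' @export
feature_count_distribution <- function(profiles) {
  stopifnot(inherits(profiles, "snpreanno_profiles"))
  kmax <- length(regulatory_classes())
  counts <- table(factor(profiles$n_classes, levels = 0:kmax))
  data.frame(k = 0:kmax, n_variants = as.integer(counts))
}

#' Per-class variant counts
#'
#' Number of variants overlapping each feature class (a variant can appear
#' under several classes).
#'
#' @param profiles A `snpreanno_profiles`.
#' @return Named integer vector over [regulatory_classes()].
#' @export
per_class_counts <- function(profiles) {
  stopifnot(inherits(profiles, "snpreanno_profiles"))
  counts <- table(factor(profiles$pairs$feature_class,
                         levels = regulatory_classes()))
  stats::setNames(as.integer(counts), regulatory_classes())
}

#' Fraction of variants overlapping at least one regulatory class
#'
#' @param profiles A `snpreanno_profiles`.
#' @return Proportion between 0 and 1 (NaN for zero variants).
#' @export
regulatory_coverage <- function(profiles) {
  stopifnot(inherits(profiles, "snpreanno_profiles"))
  mean(profiles$n_classes >= 1L)
}

#' @export
print.snpreanno_profiles <- function(x, ...) {
  cat(sprintf("<regulatory profiles: %d variants, %.1f%% with >= 1 feature class>\n",
              length(x$n_classes), 100 * mean(x$n_classes >= 1L)))
  invisible(x)
}
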