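---
title: "snpreanno: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snpreanno: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`snpreanno` re-annotates trait-associated SNPs that a baseline
gene-annotation database calls noncoding, using one or more alternative
annotation databases. The pipeline has five stages: (1) a baseline filter
that removes variants in exonic regions or splice windows of baseline
protein-coding genes, defining the noncoding input universe; (2) per-set
region classification of the remaining variants; (3) integration of the
per-set calls into re-annotation deltas; (4) codon-level consequence
calling for variants that an alternative set places in coding sequence;
and (5) regulatory-feature overlap and an expressed-gene summary of the
genes that gain variants. This vignette documents the model, the
parameters, the synthetic study design used by the tests, and the
numerical and design choices that were genuinely open.

## The classification model

Each (variant, annotation set) pair receives exactly one region category.
Per transcript whose footprint (or upstream promoter window) contains the
position, the category is determined by interval logic:

* inside an exon of a coding transcript: `CDS` when within the CDS span,
  otherwise `UTR5`/`UTR3` relative to the CDS on the transcript strand;
* inside an exon of a noncoding transcript: `NCRNA_EXONIC`;
* intronic: `SPLICE` when within `splice_window_bp` of the nearest
  exon/intron boundary, else `INTRONIC`. The splice window is an intronic
  property only — exonic bases within 2 bp of a boundary stay exonic,
  because the baseline filter treats "exonic" and "splice boundary" as
  distinct removal classes;
* upstream: `PROMOTER` when within `promoter_window_bp` of the TSS on the
  transcript strand (plus strand `[TSS - w, TSS - 1]`, minus strand
  `[TSS + 1, TSS + w]`, clamped to the contig).

Per-transcript categories collapse to one top-level category by the
severity order `CDS > SPLICE > UTR5 > UTR3 > NCRNA_EXONIC > INTRONIC >
PROMOTER > INTERGENIC`. The source study does not state its tie-break
between transcripts; we adopt an ANNOVAR-like severity ordering
(consistent with the tool that study used), which also encodes the rule
that an intragenic hit in one gene beats a promoter hit in another. All
genes contributing the winning category are reported, sorted
lexicographically for determinism.

The baseline filter removes variants whose top-level baseline category is
`CDS`, `UTR5` or `UTR3` (necessarily from a protein-coding gene) or
`SPLICE` from a protein-coding gene. Splice windows of purely noncoding
genes are retained: the filter's stated target is protein-coding genes,
and we follow that reading rather than removing all splice hits.

A variant is *re-annotated* when its baseline category is `INTRONIC` or
`INTERGENIC` and at least one alternative set assigns `PROMOTER`, `CDS`,
`UTR5`, `UTR3`, `SPLICE` or `NCRNA_EXONIC` — or `INTRONIC` when the
baseline call was `INTERGENIC`. The asymmetry is deliberate: an intron
over an intron is not a re-annotation, but gaining any gene context over
intergenic space is. The union count uses set semantics: a variant
re-annotated by several sets, or to several categories, counts once.

### Open choice: promoter calls and the baseline

The promoter category participates in re-annotation against alternative
sets but is not a removal class of the baseline filter (a
baseline-promoter variant is retained, and — being neither intronic nor
intergenic at baseline — can never be flagged re-annotated). This mirrors
the asymmetry of the source procedure. Both windows are plain parameters,
so users who want a symmetric treatment can reclassify with their own
thresholds.

## Consequence calling

For a CDS hit, the coding sequence is assembled 5'→3' on the transcript
strand (exonic CDS bases concatenated, reverse-complemented for minus
strand), giving a bijection between CDS genomic positions and 0-based
offsets. The codon index is `offset %/% 3 + 1`; the alternative allele is
complemented for minus-strand transcripts; both codons are translated with
the standard genetic code (translation table 1 — there is no evidence the
domain needs selenocysteine or mitochondrial codes). Kinds: stop-gain
(ref not stop, alt stop), stop-loss (ref stop, alt not), synonymous (equal
amino acids), non-synonymous (different). Numerical edge cases, decided
here and frozen:

* **CDS span includes the stop codon**, so stop-loss at the terminal codon
  is callable as a CDS variant.
* **Stop-preserving substitutions** (e.g. TAA→TGA) are reported as
  `SYNONYMOUS`: the amino-acid outcome is unchanged, matching
  ANNOVAR-style behaviour. The enumeration oracle in the tests states the
  same convention.
* **Missing alternative allele** or a variant in the **trailing partial
  codon** of a CDS whose length is not a multiple of 3 yields `UNKNOWN`;
  frame information (codon index, reference codon) is still reported when
  known.
* **Reference mismatches**: when the stated ref allele disagrees with the
  genome base, the genome base defines the reference codon and the result
  carries `ref_mismatch = TRUE`. This keeps consequences well-defined on
  discordant inputs — many catalog risk alleles equal the reference, and
  allele orientation in catalogs is not guaranteed. We record alleles as
  given and never strand-flip them.
* **Start-codon disruptions** are reported as `NONSYNONYMOUS`; the
  category system has exactly five kinds.
* Severity for per-gene summaries: `STOPGAIN = STOPLOSS > NONSYNONYMOUS >
  SYNONYMOUS > UNKNOWN`, ties broken by transcript id.

## Expression and regulatory stages

A gene is expressed in a tissue when the posterior standard deviation of
its expression estimate is **strictly below** `expression_sd_max`
(default 1.5); the boundary value 1.5 is therefore *not expressed*. The
threshold is applied to the `posterior_sd` column as provided — whether
the upstream estimator worked on a log scale is the caller's concern, not
this package's. Estimates are consumed, never computed: read alignment
and posterior inference are explicitly upstream. "Tissue-specific" is
operationalized as expressed in exactly one tissue; the source's claim is
qualitative (a clustering heatmap), so we chose the simplest auditable
definition and exposed it as an overridable function.

Regulatory evidence arrives as class-labelled BED tracks (seven classes:
promoter/enhancer states, motifs, DNase footprints, eQTLs, conserved
elements, conserved TFBS, ChIP-seq protein binding). Web-server queries
are deliberately replaced by file-based overlap so the computation is
reproducible offline. The per-variant profile is the set of *distinct*
classes containing the position (two tracks of one class count once);
both the per-class counts and the k-classes-per-variant distribution are
emitted because figure-style bar counts can be read either way.

## Parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `splice_window_bp` | bp | 2 | intronic positions within this distance of an exon boundary are `SPLICE` |
| `promoter_window_bp` | bp | 1000 | upstream extent of the promoter window, on the transcript strand |
| `expression_sd_max` | SD units of the expression estimate | 1.5 | strict upper bound for "expressed" |

Coordinates are 1-based inclusive everywhere in memory; BED's 0-based
half-open intervals are converted on input (`start + 1`, `end`), VCF and
GTF positions are taken as-is. Variants are single-nucleotide only; indels
are rejected with a clear error.

## The synthetic study design

`generate_fixture()` emulates the structure of the study's inputs with
full ground truth: one 100 kb contig, a baseline plus three alternative
annotation sets, 37 planted variants and 14 genes across both strands,
and 16 tissues. Discordance between sets is modelled by the three
mechanisms visible in the study's worked examples: a coding exon missing
from the baseline (creating intronic→CDS deltas), a gene entirely absent
from the baseline (intergenic→CDS/UTR/promoter/ncRNA/intronic deltas),
and a CDS extending further 5' in the alternative set. Coding genes are
laid out as three exons with 30 bp UTR pads and 120 bp introns; the CDS
is `ATG` + random non-stop codons + `TAA`, written into the genome
strand-aware, so each consequence kind can be forced by stamping a chosen
codon and alternative base (e.g. GCC→GCA for synonymous, TGG→TGA for
stop-gain, terminal TAA→CAA for stop-loss). Gene slots are spaced so that
no promoter window or planted intergenic position can interact with a
neighbouring gene, which is what makes the per-set truth derivable from
the plan rather than from the classifier. Infeasible plans (a stop-loss
hosted on a missing-exon gene, whose terminal exon the baseline contains)
error before anything is written. All randomness flows from one seed and
regeneration is byte-identical.

What the fixture does *not* emulate: realistic human gene density or
length distributions, overlapping genes, multi-transcript genes,
multi-allelic sites, LD structure, and population allele frequencies.
Passing tests therefore demonstrate correctness of the interval logic,
strand handling, codon arithmetic and set algebra — not calibration
against real annotation databases, whose version-dependent content is
exactly why the study's absolute counts are not reproducible at desk
scale.

## Problem sizes and verification strategy

The test suite verifies the classifier against a brute-force per-base
oracle (independent interval arithmetic, no index) at every position of
20 kb fixtures across multiple seeds and all four annotation sets; the
consequence caller against an exhaustive enumeration of all 576
single-base codon substitutions checked with an independent genetic-code
table (`seqinr` in the unit tests, an inline table in the acceptance
script); the integrator against direct set algebra on randomized planted
memberships; and the full pipeline against the generator's ground truth
(100% planted-label recovery over five seeds). These sizes keep the whole
suite in the low minutes on one CPU while covering every category,
mechanism and strand combination.

## Known limitations

* One transcript per gene in the fixture generator (the engine itself
  handles arbitrarily many transcripts per gene, including overlapping
  genes).
* No downstream (3'-of-gene) category and no nearest-gene assignment for
  intergenic variants — intergenic means intergenic.
* GFF3, bgzip/tabix and remote database fetching are out of scope; the
  genePred reader covers the 10- and 15-column dialects only.
* Consequence calling covers SNVs only: no indels, frameshifts,
  splice-disruption scores or protein-impact prediction.
* The per-variant trait label is carried through but not analysed; trait
  enrichment across deltas is out of scope.
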