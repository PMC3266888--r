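# Genome-wide classification of weighted hits.
#
# Every hit is assigned to exactly one of five exhaustive categories, in
# precedence order: exons/splice junctions, introns, regions flanking
# annotated loci (within a fixed distance of a locus border), transposable
# elements outside loci, and the remaining intergenic space. Category totals
# accumulate hit weights, so the per-category totals are fractional. A
# replicate-concordance summary reports, per category, the share of hit
# weight falling into regions sequenced in both replicates.

REGION_CATEGORIES <- c("exon_or_junction", "intron", "flanking",
                       "te_outside_loci", "intergenic")

#' Classify hits into genomic categories
#'
#' Assigns each hit its most "genic" explanation, with precedence
#' exon/junction > intron > flanking > TE outside loci > intergenic:
#' a gapped (spliced) hit or one overlapping an annotated exon is
#' `exon_or_junction`; a hit overlapping a locus but no exon is `intron`;
#' a hit closer than `flank` bases to a locus border is `flanking`; a hit
#' overlapping a standalone transposable element is `te_outside_loci`;
#' everything else is `intergenic`. Overlap means at least one shared base,
#' evaluated on the hit's aligned (non-gap) blocks.
#'
#' @param hits hit table (alignments with weights).
#' @param ann a `GenomeAnnotation`.
#' @param flank distance in bases below which a hit counts as flanking a
#'   locus (default 200; the border distance must be strictly below this).
#' @return Character vector of categories, one per hit.
#' @export
classify_hits <- function(hits, ann, flank = 200L) {
  n <- nrow(hits)
  out <- rep("intergenic", n)
  if (n == 0L) return(out)
  blocks <- hit_blocks_granges(hits)

  hit_overlaps <- function(target_gr) {
    if (length(target_gr) == 0L) return(logical(n))
    ov <- GenomicRanges::findOverlaps(blocks, target_gr)
    res <- logical(n)
    res[unique(blocks$hit[S4Vectors::queryHits(ov)])] <- TRUE
    res
  }

  exon_gr <- df_granges(ann$exons)
  locus_gr <- df_granges(ann$loci)
  te_gr <- df_granges(ann$te_features)
  # A border distance strictly below `flank` corresponds, in half-open
  # coordinates, to overlap with the locus extended by `flank` on each side.
  flank_df <- ann$loci
  flank_df$start <- pmax(0L, flank_df$start - as.integer(flank))
  flank_df$end <- flank_df$end + as.integer(flank)
  flank_gr <- df_granges(flank_df)

  gapped <- nzchar(hits$gaps)
  in_exon <- hit_overlaps(exon_gr)
  in_locus <- hit_overlaps(locus_gr)
  in_flank <- hit_overlaps(flank_gr)
  in_te <- hit_overlaps(te_gr)

  out[in_te] <- "te_outside_loci"
  out[in_flank] <- "flanking"
  out[in_locus] <- "intron"
  out[gapped | in_exon] <- "exon_or_junction"
  out
}

#' Summarise hit weight per genomic category
#'
#' Accumulates hit weights (not integer counts) in each category of
#' [classify_hits()]. The totals partition the input: they sum to the total
#' hit weight.
#'
#' @inheritParams classify_hits
#' @return data.frame with columns `category` and `weighted_hits`, one row
#'   per category in precedence order.
#' @export
summarize_by_category <- function(hits, ann, flank = 200L) {
  cats <- classify_hits(hits, ann, flank)
  totals <- vapply(REGION_CATEGORIES, function(cl)
    sum(hits$weight[cats == cl]), numeric(1L))
  data.frame(category = REGION_CATEGORIES, weighted_hits = unname(totals))
}

#' Regions sequenced in both replicates
#'
#' A base belongs to the reproducibly sequenced set when it is covered by at
#' least one hit (any positive weight) in each of the two replicates, over
#' the hits' aligned (non-gap) blocks. Returned as merged, sorted, disjoint
#' intervals.
#'
#' @param hitsA,hitsB hit tables of the two replicates.
#' @return data.frame of class `ReproducibleRegionSet` with columns `chrom`,
#'   `start`, `end` (0-based half-open), sorted by (chrom, start).
#' @export
reproducibly_sequenced_regions <- function(hitsA, hitsB) {
  covered <- function(hits) {
    hits <- hits[hits$weight > 0, , drop = FALSE]
    GenomicRanges::reduce(hit_blocks_granges(hits))
  }
  both <- GenomicRanges::intersect(covered(hitsA), covered(hitsB))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(both)),
                   start = GenomicRanges::start(both) - 1L,
                   end = GenomicRanges::end(both))
  df <- order_intervals(df)
  rownames(df) <- NULL
  class(df) <- c("ReproducibleRegionSet", "data.frame")
  df
}

#' Weighted fraction of hits overlapping a region set
#'
#' A hit overlaps the set when at least one of its aligned bases lies in a
#' region; the numerator sums weights of overlapping hits and the
#' denominator all hit weight. Reported overall and per genomic category.
#'
#' @param hits hit table.
#' @param regions `ReproducibleRegionSet` (or any chrom/start/end
#'   data.frame).
#' @param ann a `GenomeAnnotation` (for the per-category split).
#' @param flank flanking distance passed to [classify_hits()].
#' @return data.frame with columns `category` (the five categories plus
#'   `"overall"`), `weighted_hits`, and `fraction_reproducible` (`NaN` where
#'   a category holds no weight).
#' @export
fraction_hits_reproducible <- function(hits, regions, ann, flank = 200L) {
  cats <- classify_hits(hits, ann, flank)
  region_gr <- df_granges(regions)
  blocks <- hit_blocks_granges(hits)
  inset <- logical(nrow(hits))
  if (length(region_gr) && length(blocks)) {
    ov <- GenomicRanges::findOverlaps(blocks, region_gr)
    inset[unique(blocks$hit[S4Vectors::queryHits(ov)])] <- TRUE
  }
  one <- function(sel) {
    tot <- sum(hits$weight[sel])
    c(tot, sum(hits$weight[sel & inset]) / tot)
  }
  rows <- lapply(REGION_CATEGORIES, function(cl) one(cats == cl))
  overall <- one(rep(TRUE, nrow(hits)))
  data.frame(
    category = c(REGION_CATEGORIES, "overall"),
    weighted_hits = vapply(c(rows, list(overall)), `[`, numeric(1L), 1L),
    fraction_reproducible = vapply(c(rows, list(overall)), `[`,
                                   numeric(1L), 2L)
  )
}
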