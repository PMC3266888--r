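# Multi-mapped read weighting by local unique coverage.
#
# Aligners are allowed to report several alignments per read (up to 10 here)
# so that reads from duplicated gene families are not silently lost; counting
# each alignment once would then overestimate expression. Each alignment of a
# multi-mapped read is instead given a score from evidence contributed by
# uniquely aligned reads -- summed unique-read depth in a window around the
# alignment (the "allocation distance") for ungapped alignments, the number
# of unique reads spanning the same splice gap for gapped ones -- and a
# weight w = s / sum(s) over the read's alignments. A weighted alignment is
# called a "hit"; hit counts are therefore fractional. If all scores of a
# read are zero the read is discarded.

#' Weighting configuration
#'
#' @param allocation_distance window, in bases, of unique-read coverage summed
#'   on each side of an ungapped alignment when scoring it (default 100).
#' @param max_alignments maximum alignments per read (default 10).
#' @return A list of class `WeightingConfig`.
#' @export
weighting_config <- function(allocation_distance = 100L, max_alignments = 10L) {
  stopifnot(allocation_distance >= 0L, max_alignments >= 1L)
  structure(list(allocation_distance = as.integer(allocation_distance),
                 max_alignments = as.integer(max_alignments)),
            class = "WeightingConfig")
}

#' Per-base coverage from uniquely aligned reads
#'
#' Builds one depth vector per chromosome counting, at every base, the
#' uniquely aligned reads covering it. Only alignments with
#' `is_unique = TRUE` contribute, and only over their aligned (non-gap)
#' blocks; bases under a splice gap are not covered.
#'
#' @param alignments alignment table from [read_alignments()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return Object of class `CoverageTrack`: a list of integer depth vectors,
#'   one per chromosome.
#' @export
build_unique_coverage <- function(alignments, chrom_lengths) {
  u <- alignments[alignments$is_unique, , drop = FALSE]
  if (nrow(u) && (any(!u$chrom %in% names(chrom_lengths)) ||
                  any(u$end > chrom_lengths[u$chrom]) || any(u$start < 0L)))
    stop("alignment outside chromosome bounds")
  if (nrow(u)) {
    gr <- hit_blocks_granges(u)
    chr <- as.character(GenomicRanges::seqnames(gr))
    track <- lapply(names(chrom_lengths), function(ch) {
      ir <- IRanges::ranges(gr[chr == ch])
      as.integer(IRanges::coverage(ir, width = chrom_lengths[[ch]]))
    })
  } else {
    track <- lapply(chrom_lengths, integer)
  }
  names(track) <- names(chrom_lengths)
  structure(track, class = "CoverageTrack")
}

#' Splice-junction support from uniquely aligned reads
#'
#' Counts, for every gap (intron) observed in the alignments, how many
#' uniquely aligned reads span that exact gap. A unique read with several
#' gaps increments each of them once.
#'
#' @param alignments alignment table from [read_alignments()].
#' @return Named integer vector (class `JunctionIndex`); names are
#'   `"chrom:start-end"` junction keys in 0-based half-open coordinates.
#' @export
build_junction_index <- function(alignments) {
  u <- alignments[alignments$is_unique & nzchar(alignments$gaps), ,
                  drop = FALSE]
  keys <- character(0)
  if (nrow(u)) {
    per <- lapply(seq_len(nrow(u)), function(i) {
      g <- string_to_gaps(u$gaps[i])
      junction_key(u$chrom[i], g[, 1L], g[, 2L])
    })
    keys <- unlist(per)
  }
  tab <- table(keys)
  idx <- as.integer(tab)
  names(idx) <- names(tab)
  structure(idx, class = "JunctionIndex")
}

# Cumulative-sum representation of a coverage track for O(1) window sums.
coverage_cumsum <- function(cov) {
  lapply(unclass(cov), function(v) c(0, cumsum(as.numeric(v))))
}

#' Score one alignment against unique coverage and junction support
#'
#' Ungapped alignments score the summed unique-read depth over the alignment
#' extended by the allocation distance on both sides (clipped at chromosome
#' ends). Gapped alignments score the number of unique reads spanning the
#' same gap; alignments with several gaps take the minimum support over
#' their gaps, and an unobserved gap scores 0.
#'
#' @param alignment single-row alignment data.frame (or list) with `chrom`,
#'   `start`, `end`, `gaps`.
#' @param cov `CoverageTrack` from [build_unique_coverage()].
#' @param jx `JunctionIndex` from [build_junction_index()].
#' @param cfg [weighting_config()].
#' @return Non-negative numeric score.
#' @export
score_alignment <- function(alignment, cov, jx, cfg = weighting_config()) {
  g <- string_to_gaps(alignment$gaps)
  if (nrow(g)) {
    keys <- junction_key(alignment$chrom, g[, 1L], g[, 2L])
    support <- unclass(jx)[keys]
    support[is.na(support)] <- 0L
    return(min(support))
  }
  v <- unclass(cov)[[alignment$chrom]]
  if (is.null(v)) stop("unknown chromosome: ", alignment$chrom)
  lo <- max(0L, alignment$start - cfg$allocation_distance)
  hi <- min(length(v), alignment$end + cfg$allocation_distance)
  if (alignment$start < 0L || alignment$end > length(v))
    stop("alignment outside chromosome bounds")
  sum(v[(lo + 1L):hi])
}

#' Weight the alignments of one read
#'
#' Converts the alignment group of a single read into weighted hits. A
#' uniquely aligned read always yields one hit with weight 1 (its score is
#' never consulted: weighting exists only to apportion multi-mappers). For a
#' multi-mapped read every alignment is scored and weighted
#' `w_i = s_i / sum(s)`; when all scores are zero the whole group is
#' discarded and an empty table returned.
#'
#' @param group alignment rows sharing one `read_id`.
#' @inheritParams score_alignment
#' @return The group with `score` and `weight` columns appended (zero rows if
#'   discarded).
#' @export
weight_read_group <- function(group, cov, jx, cfg = weighting_config()) {
  if (length(unique(group$read_id)) > 1L)
    stop("weight_read_group() called with mixed read ids")
  if (nrow(group) > cfg$max_alignments)
    stop("alignment group larger than max_alignments")
  if (nrow(group) == 1L) {
    # Sole candidate placement: weight 1 whether the read is flagged unique
    # or its other alignments were filtered upstream.
    group$score <- NA_real_
    group$weight <- 1
    return(group)
  }
  s <- vapply(seq_len(nrow(group)), function(i)
    score_alignment(group[i, ], cov, jx, cfg), numeric(1L))
  if (sum(s) == 0) return(group[0L, c(names(group)), drop = FALSE])
  group$score <- s
  group$weight <- s / sum(s)
  group
}

#' Weight all alignments of a sample
#'
#' Vectorised application of the unique-coverage weighting to a whole
#' alignment table: builds window sums from the coverage track, scores every
#' alignment, normalises weights within each read and drops zero-total
#' multi-mapped reads. Unique reads pass through with weight 1.
#'
#' @param alignments alignment table from [read_alignments()].
#' @param cov `CoverageTrack`; built from `alignments` when `NULL`.
#' @param jx `JunctionIndex`; built from `alignments` when `NULL`.
#' @param cfg [weighting_config()].
#' @param chrom_lengths needed only when `cov` is `NULL`.
#' @return Hit table: the retained alignments with `score` and `weight`
#'   columns. Weights of each retained read sum to 1.
#' @export
weight_alignments <- function(alignments, cov = NULL, jx = NULL,
                              cfg = weighting_config(),
                              chrom_lengths = NULL) {
  if (is.null(cov)) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths required when no coverage track is supplied")
    cov <- build_unique_coverage(alignments, chrom_lengths)
  }
  if (is.null(jx)) jx <- build_junction_index(alignments)
  a <- alignments
  if (nrow(a) == 0L) {
    a$score <- numeric(0); a$weight <- numeric(0)
    return(a)
  }
  cum <- coverage_cumsum(cov)
  lens <- vapply(unclass(cov), length, integer(1L))
  d <- cfg$allocation_distance

  gapped <- nzchar(a$gaps)
  s <- numeric(nrow(a))
  if (any(!gapped)) {
    i <- which(!gapped)
    lo <- pmax(0L, a$start[i] - d)
    hi <- pmin(lens[a$chrom[i]], a$end[i] + d)
    s[i] <- vapply(seq_along(i), function(k) {
      cm <- cum[[a$chrom[i[k]]]]
      cm[hi[k] + 1L] - cm[lo[k] + 1L]
    }, numeric(1L))
  }
  if (any(gapped)) {
    i <- which(gapped)
    s[i] <- vapply(i, function(k) {
      g <- string_to_gaps(a$gaps[k])
      support <- unclass(jx)[junction_key(a$chrom[k], g[, 1L], g[, 2L])]
      support[is.na(support)] <- 0L
      min(support)
    }, numeric(1L))
  }

  dt <- data.table::data.table(read_id = a$read_id, s = s)
  tot <- dt[, list(total = sum(s), size = .N), by = "read_id"]
  m <- match(a$read_id, tot$read_id)
  totals <- tot$total[m]
  sizes <- tot$size[m]

  sole <- a$is_unique | sizes == 1L
  keep <- sole | totals > 0
  w <- ifelse(sole, 1, ifelse(totals > 0, s / totals, 0))
  out <- a[keep, , drop = FALSE]
  out$score <- ifelse(sole[keep], NA_real_, s[keep])
  out$weight <- w[keep]
  rownames(out) <- NULL
  out
}
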