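# Concordance of assembled locus sets and expression vectors between
# biological replicates.
#
# Loci assembled de novo from intergenic reads ("splice-loci" when their
# transcript model is supported by at least one splice junction) are
# compared between replicates by an asymmetric overlap fraction: shared
# bases divided by the length of the query locus, against the union of all
# overlapping target loci. Expression vectors are compared by correlation
# of log2(x + 1) values over the union of expressed loci.

#' Overlap fraction of a query locus with a target locus set
#'
#' Number of query bases covered by the union of the target intervals,
#' divided by the query length. The measure is asymmetric: a short query
#' inside a long target scores 1, the reverse does not.
#'
#' @param query single-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param targets data.frame of target intervals.
#' @return Fraction in `[0, 1]`.
#' @export
locus_overlap <- function(query, targets) {
  targets <- targets[targets$chrom == query$chrom, , drop = FALSE]
  if (nrow(targets) == 0L) return(0)
  q <- IRanges::IRanges(start = query$start + 1L, end = query$end)
  t <- IRanges::reduce(IRanges::IRanges(start = targets$start + 1L,
                                        end = targets$end))
  shared <- sum(IRanges::width(IRanges::intersect(q, t)))
  shared / (query$end - query$start)
}

#' Count query loci exceeding overlap thresholds
#'
#' For each query locus the overlap fraction against the target set is
#' computed with [locus_overlap()]; the result reports, for every threshold,
#' how many query loci reach it. When `include_unspliced` is `FALSE` the
#' target set is restricted to junction-supported loci, mirroring the
#' stricter comparison in which only splice-loci count as confirmation.
#'
#' @param queries data.frame of query loci (`chrom`, `start`, `end`).
#' @param targets data.frame of target loci with a logical
#'   `junction_supported` column.
#' @param thresholds numeric vector of overlap thresholds in `[0, 1]`.
#' @param include_unspliced also accept targets without junction support.
#' @param strict require overlap strictly greater than the threshold
#'   (default `FALSE`: at least the threshold).
#' @return List with `fractions` (per-query best overlap fraction) and
#'   `counts` (data.frame `threshold`, `count`).
#' @export
count_above_thresholds <- function(queries, targets, thresholds,
                                   include_unspliced = FALSE,
                                   strict = FALSE) {
  if (!include_unspliced) {
    if (is.null(targets$junction_supported))
      stop("targets lack a junction_supported column")
    targets <- targets[targets$junction_supported, , drop = FALSE]
  }
  fractions <- vapply(seq_len(nrow(queries)), function(i)
    locus_overlap(queries[i, ], targets), numeric(1L))
  counts <- vapply(thresholds, function(th)
    if (strict) sum(fractions > th) else sum(fractions >= th), numeric(1L))
  list(fractions = fractions,
       counts = data.frame(threshold = thresholds, count = as.integer(counts)))
}

#' Correlation of expression between two replicates
#'
#' Computed on `log2(x + 1)` expression over the loci expressed in at least
#' one of the two replicates (the union expressed set).
#'
#' @param matrix an `ExpressionMatrix` from [build_matrix()] with at least
#'   two replicates.
#' @param method `"pearson"` or `"spearman"`.
#' @param reps indices (or names) of the two replicates to compare.
#' @return Correlation coefficient.
#' @export
expression_correlation <- function(matrix, method = c("pearson", "spearman"),
                                   reps = c(1L, 2L)) {
  method <- match.arg(method)
  sel <- matrix$expressed[, reps[1L]] | matrix$expressed[, reps[2L]]
  x <- log_transform(matrix$expression[sel, reps[1L]])
  y <- log_transform(matrix$expression[sel, reps[2L]])
  stats::cor(x, y, method = method)
}

#' Stratify assembled loci by expression level
#'
#' Splits an assembled-locus table into low- and high-expression strata at a
#' hit-count boundary; loci whose total hit weight is strictly below the
#' boundary form the low stratum. Low-expression splice-loci reproduce
#' poorly between replicates, so concordance is usually reported per
#' stratum.
#'
#' @param loci data.frame with a `hit_total` column.
#' @param min_hits_stratum boundary (default 25).
#' @return List with `low` and `high` data.frames.
#' @export
stratify_by_expression <- function(loci, min_hits_stratum = 25) {
  low <- loci$hit_total < min_hits_stratum
  list(low = loci[low, , drop = FALSE], high = loci[!low, , drop = FALSE])
}
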