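# SOLiD colorspace read prefiltering and double encoding.
#
# Reads destined for de novo assembly are filtered before error-prone
# colorspace data reaches the assembler: low total quality, ambiguous color
# calls ('.'), repetitive color sequence (one adjacent color pair dominating
# the read, typical of amplification artefacts) and exact duplicates are
# removed, in that order. Base-space assemblers consume colorspace reads
# after "double encoding": the bijective remapping 0->A, 1->C, 2->G, 3->T.

#' Read-filter configuration
#'
#' @param min_total_quality minimal summed per-color quality (default 200).
#' @param max_repetitive_fraction maximal tolerated fraction of the sequence
#'   taken by one repeated adjacent color pair (default 0.30, strict).
#' @param rep_mode how the repetitive fraction is measured: `"pairs"`
#'   (occurrences of the most frequent pair over the number of adjacent
#'   positions) or `"covered"` (color positions covered by occurrences of
#'   that pair over the read length).
#' @return A list of class `FilterConfig`.
#' @export
filter_config <- function(min_total_quality = 200,
                          max_repetitive_fraction = 0.30,
                          rep_mode = c("pairs", "covered")) {
  stopifnot(min_total_quality >= 0, max_repetitive_fraction >= 0)
  structure(list(min_total_quality = min_total_quality,
                 max_repetitive_fraction = max_repetitive_fraction,
                 rep_mode = match.arg(rep_mode)),
            class = "FilterConfig")
}

#' Total quality of a colorspace read
#'
#' @param qualities integer vector of per-color qualities.
#' @return Their sum (0 for an empty read).
#' @export
total_quality <- function(qualities) sum(as.integer(qualities))

#' Does a read contain an ambiguous color call?
#'
#' @param colors color string over `0123.`.
#' @return `TRUE` iff the string contains `'.'`.
#' @export
is_ambiguous <- function(colors) grepl(".", colors, fixed = TRUE)

#' Is a read repetitive?
#'
#' Scans all overlapping adjacent color pairs of the read; the read is
#' repetitive when the most frequent pair accounts for more than
#' `max_fraction` of the sequence. In `"pairs"` mode the fraction is the
#' pair's occurrence count over the `length - 1` adjacent positions; in
#' `"covered"` mode it is the number of color positions covered by
#' occurrences of the pair over the read length. Reads shorter than two
#' colors have no pairs and are never repetitive.
#'
#' @param colors color string.
#' @param max_fraction strict threshold (default 0.30).
#' @param mode `"pairs"` or `"covered"`.
#' @return Logical.
#' @export
is_repetitive <- function(colors, max_fraction = 0.30,
                          mode = c("pairs", "covered")) {
  mode <- match.arg(mode)
  n <- nchar(colors)
  if (n < 2L) return(FALSE)
  pairs <- substring(colors, 1:(n - 1L), 2:n)
  if (mode == "pairs") {
    return(max(table(pairs)) / (n - 1L) > max_fraction)
  }
  best <- names(which.max(table(pairs)))
  pos <- which(pairs == best)
  covered <- length(unique(c(pos, pos + 1L)))
  covered / n > max_fraction
}

#' Remove duplicated reads
#'
#' Keeps the first occurrence of each exact color string (qualities are
#' ignored: assembly only cares about sequence), preserving input order.
#'
#' @param reads colorspace read table (as from [read_colorspace()]).
#' @return The deduplicated table.
#' @export
deduplicate <- function(reads) {
  reads[!duplicated(reads$colors), , drop = FALSE]
}

#' Filter colorspace reads for de novo assembly
#'
#' Applies the four removal rules in order -- low total quality, ambiguous
#' color, repetitive sequence, exact duplicate -- and returns the surviving
#' reads together with a per-reason ledger. The ledger balances:
#' `n_in = n_out + sum(removed)`. Order affects the per-reason counts only,
#' not the surviving set.
#'
#' @param reads colorspace read table.
#' @param cfg a [filter_config()].
#' @return List with `reads` (survivors) and `report` (class
#'   `FilterReport`): `n_in`, `n_out` and per-reason counts `low_quality`,
#'   `ambiguous`, `repetitive`, `duplicate`.
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  n_in <- nrow(reads)
  tq <- vapply(reads$qualities, total_quality, numeric(1L))
  low <- tq < cfg$min_total_quality
  r <- reads[!low, , drop = FALSE]

  amb <- is_ambiguous(r$colors)
  r2 <- r[!amb, , drop = FALSE]

  rep_flag <- vapply(r2$colors, is_repetitive, logical(1L),
                     max_fraction = cfg$max_repetitive_fraction,
                     mode = cfg$rep_mode, USE.NAMES = FALSE)
  r3 <- r2[!rep_flag, , drop = FALSE]

  r4 <- deduplicate(r3)

  report <- structure(list(
    n_in = n_in, n_out = nrow(r4),
    low_quality = sum(low), ambiguous = sum(amb),
    repetitive = sum(rep_flag), duplicate = nrow(r3) - nrow(r4)),
    class = "FilterReport")
  list(reads = r4, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", x$n_in, "in,", x$n_out, "out",
      sprintf("(low_quality %d, ambiguous %d, repetitive %d, duplicate %d)\n",
              x$low_quality, x$ambiguous, x$repetitive, x$duplicate))
  invisible(x)
}

#' Double-encode a color string into base space
#'
#' The bijection 0<->A, 1<->C, 2<->G, 3<->T applied per color; the primer
#' base (not part of the color string) is dropped on encoding. Only defined
#' for '.'-free strings.
#'
#' @param colors color string over `0123`.
#' @return Base-space string over `ACGT`.
#' @export
double_encode <- function(colors) {
  if (is_ambiguous(colors))
    stop("cannot double-encode a read with ambiguous colors")
  chartr("0123", "ACGT", colors)
}

#' Decode a double-encoded string back to colors
#'
#' Inverse of [double_encode()].
#'
#' @param encoded base-space string over `ACGT`.
#' @return Color string over `0123`.
#' @export
double_decode <- function(encoded) chartr("ACGT", "0123", encoded)
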