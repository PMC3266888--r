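# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based,
# half-open [start, end). Conversion to/from 1-based closed coordinates
# happens only at format boundaries (GFF3, SAM).

# Encode a 2-column gap matrix as "s-e;s-e" (empty string for no gaps).
gaps_to_string <- function(gaps) {
  if (is.null(gaps) || nrow(gaps) == 0L) return("")
  paste(paste0(gaps[, 1L], "-", gaps[, 2L]), collapse = ";")
}

# Inverse of gaps_to_string(); returns an integer matrix with columns start,end.
string_to_gaps <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Aligned (non-gap) blocks of an alignment spanning [start, end) with the
# given gaps. Returns an integer matrix with columns start,end.
alignment_blocks <- function(start, end, gaps) {
  if (is.null(gaps) || nrow(gaps) == 0L) {
    return(matrix(c(start, end), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- c(start, gaps[, 2L])
  ends <- c(gaps[, 1L], end)
  m <- cbind(start = starts, end = ends)
  m[m[, 1L] < m[, 2L], , drop = FALSE]
}

# All aligned blocks of a hit table as a GRanges (one range per block, with
# a `hit` column pointing back at the originating row). Used wherever
# "overlap" is defined on the non-gap aligned blocks of a hit.
hit_blocks_granges <- function(hits) {
  gl <- lapply(hits$gaps, string_to_gaps)
  nb <- vapply(gl, nrow, integer(1L)) + 1L
  idx <- rep.int(seq_len(nrow(hits)), nb)
  starts <- integer(0); ends <- integer(0)
  blocks <- mapply(function(s, e, g) alignment_blocks(s, e, g),
                   hits$start, hits$end, gl, SIMPLIFY = FALSE)
  bm <- do.call(rbind, blocks)
  if (is.null(bm)) bm <- matrix(integer(0), ncol = 2L)
  GenomicRanges::GRanges(
    seqnames = hits$chrom[idx],
    ranges = IRanges::IRanges(start = bm[, 1L] + 1L, end = bm[, 2L]),
    hit = idx
  )
}

# GRanges from a 0-based half-open data.frame with chrom/start/end columns.
df_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Stable key for a junction (gap) used by the junction index.
junction_key <- function(chrom, gap_start, gap_end) {
  paste0(chrom, ":", gap_start, "-", gap_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic ordering of an interval data.frame by (chrom, start, end).
order_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
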