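# Fixture builders shared across the test files. Everything is constructed
# in code; coordinates are 0-based half-open as everywhere in the package.

# A hand-laid-out annotation on one 10 kb chromosome:
#   GA:  + strand, 2 exons (1000,1200) and (1400,1700), intron (1200,1400)
#   GB:  - strand, 1 exon  (3000,3600)
#   INNER/OUTER: nested pair; INNER (+) 1 exon (5200,5600), OUTER (+) 1 exon
#        (5000,6100) fully containing INNER, 3' end 500 bases past INNER
#   TE feature (8000,8400); everything else intergenic.
toy_annotation <- function() {
  loci <- data.frame(
    locus_id = c("GA", "GB", "INNER", "OUTER"),
    chrom = "Chr1",
    start = c(1000L, 3000L, 5200L, 5000L),
    end = c(1700L, 3600L, 5600L, 6100L),
    strand = c("+", "-", "+", "+"),
    biotype = "gene")
  transcripts <- data.frame(
    transcript_id = c("GA.1", "GB.1", "INNER.1", "OUTER.1"),
    locus_id = c("GA", "GB", "INNER", "OUTER"),
    chrom = "Chr1",
    start = c(1000L, 3000L, 5200L, 5000L),
    end = c(1700L, 3600L, 5600L, 6100L),
    strand = c("+", "-", "+", "+"))
  exons <- data.frame(
    transcript_id = c("GA.1", "GA.1", "GB.1", "INNER.1", "OUTER.1"),
    chrom = "Chr1",
    start = c(1000L, 1400L, 3000L, 5200L, 5000L),
    end = c(1200L, 1700L, 3600L, 5600L, 6100L))
  te <- data.frame(chrom = "Chr1", start = 8000L, end = 8400L, strand = "+")
  genome_annotation(loci, transcripts, exons, te,
                    chrom_lengths = c(Chr1 = 10000L))
}

# Quick hit-table constructor; weight defaults to 1, no gaps.
make_hits <- function(start, end, chrom = "Chr1", gaps = "", weight = 1,
                      read_id = NULL, n_alignments = 1L) {
  n <- length(start)
  data.frame(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end), gaps = rep_len(gaps, n),
    n_alignments = rep_len(as.integer(n_alignments), n),
    is_unique = rep_len(as.integer(n_alignments), n) == 1L,
    score = NA_real_, weight = rep_len(weight, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random alignment table over a 1 kb single-chromosome toy genome: a mix of
# unique ungapped, unique gapped and multi-mapped reads with up to
# `max_group` alignments. Used by the weighting-oracle comparisons.
random_alignment_set <- function(seed, n_reads = 20L, max_group = 4L,
                                 genome_length = 1000L) {
  set.seed(seed)
  rows <- list()
  gap_pool <- cbind(start = c(300L, 500L), end = c(400L, 620L))
  for (i in seq_len(n_reads)) {
    k <- sample(seq_len(max_group), 1L, prob = c(0.6, rep(0.4 / (max_group - 1),
                                                          max_group - 1L)))
    for (j in seq_len(k)) {
      gapped <- stats::runif(1) < 0.3
      if (gapped) {
        g <- gap_pool[sample(nrow(gap_pool), 1L), , drop = FALSE]
        s <- g[1L, 1L] - sample(10:40, 1L)
        e <- g[1L, 2L] + sample(10:40, 1L)
        gaps <- paste0(g[1L, 1L], "-", g[1L, 2L])
      } else {
        s <- sample.int(genome_length - 60L, 1L) - 1L
        e <- s + 50L
        gaps <- ""
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("s%d_r%02d", seed, i), chrom = "chrT",
        start = as.integer(s), end = as.integer(e), gaps = gaps,
        n_alignments = k, is_unique = k == 1L)
    }
  }
  do.call(rbind, rows)
}

# Small simulated fixture reused by several files (kept small for speed).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 42L, n_reads = 2000L,
                               chrom_length = 50000L, n_loci = 12L)
      sim <- simulate_annotation(cfg)
      r1 <- simulate_reads(sim$annotation, sim$truth, cfg, replicate = 1L)
      r2 <- simulate_reads(sim$annotation, sim$truth, cfg, replicate = 2L)
      h1 <- weight_alignments(r1$alignments,
                              chrom_lengths = sim$annotation$chrom_lengths)
      h2 <- weight_alignments(r2$alignments,
                              chrom_lengths = sim$annotation$chrom_lengths)
      cache <<- list(cfg = cfg, sim = sim, r1 = r1, r2 = r2,
                     h1 = h1, h2 = h2)
    }
    cache
  }
})
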