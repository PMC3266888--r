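# Independent per-base reference implementation.
#
# Deliberately naive re-implementation of the weighting, classification,
# quantification and overlap computations using explicit per-base loops and
# no interval machinery. It exists to compute expected outputs for fixtures
# and regression tests; the optimised implementations in the other files
# must agree with it. Nothing here shares code with the fast path beyond
# the gap-string helpers.

# Per-base unique coverage as plain logical bookkeeping: one integer vector
# per chromosome, incremented base by base.
bf_unique_coverage <- function(alignments, chrom_lengths) {
  cov <- lapply(chrom_lengths, function(L) integer(L))
  u <- alignments[alignments$is_unique, , drop = FALSE]
  for (i in seq_len(nrow(u))) {
    b <- alignment_blocks(u$start[i], u$end[i], string_to_gaps(u$gaps[i]))
    for (k in seq_len(nrow(b))) {
      for (pos in seq.int(b[k, 1L], b[k, 2L] - 1L)) {
        cov[[u$chrom[i]]][pos + 1L] <- cov[[u$chrom[i]]][pos + 1L] + 1L
      }
    }
  }
  cov
}

# Score of one alignment: windowed per-base sum for ungapped, minimum exact
# gap support for gapped, both recomputed by direct looping over the
# alignment table.
bf_score <- function(i, alignments, cov, allocation_distance = 100L) {
  a <- alignments[i, ]
  g <- string_to_gaps(a$gaps)
  if (nrow(g) > 0L) {
    support <- integer(nrow(g))
    for (k in seq_len(nrow(g))) {
      n <- 0L
      for (j in seq_len(nrow(alignments))) {
        if (!alignments$is_unique[j] || alignments$chrom[j] != a$chrom) next
        gj <- string_to_gaps(alignments$gaps[j])
        for (kk in seq_len(nrow(gj))) {
          if (gj[kk, 1L] == g[k, 1L] && gj[kk, 2L] == g[k, 2L]) n <- n + 1L
        }
      }
      support[k] <- n
    }
    return(min(support))
  }
  v <- cov[[a$chrom]]
  lo <- max(0L, a$start - allocation_distance)
  hi <- min(length(v), a$end + allocation_distance)
  s <- 0L
  for (pos in seq.int(lo, hi - 1L)) s <- s + v[pos + 1L]
  s
}

# Weights for every read by direct grouping; returns the hit table.
bf_weight_alignments <- function(alignments, chrom_lengths,
                                 allocation_distance = 100L) {
  cov <- bf_unique_coverage(alignments, chrom_lengths)
  out <- list()
  for (rid in unique(alignments$read_id)) {
    idx <- which(alignments$read_id == rid)
    grp <- alignments[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      grp$score <- NA_real_; grp$weight <- 1
      out[[length(out) + 1L]] <- grp
      next
    }
    s <- vapply(idx, bf_score, numeric(1L), alignments = alignments,
                cov = cov, allocation_distance = allocation_distance)
    if (sum(s) == 0) next
    grp$score <- s; grp$weight <- s / sum(s)
    out[[length(out) + 1L]] <- grp
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- alignments[0L, ]; res$score <- numeric(0); res$weight <- numeric(0)
  }
  rownames(res) <- NULL
  res
}

# Does interval [s1,e1) share at least one base with [s2,e2)?
bf_overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# Category of a single hit by direct enumeration over the annotation.
bf_classify_hit <- function(hit, ann, flank = 200L) {
  blocks <- alignment_blocks(hit$start, hit$end, string_to_gaps(hit$gaps))
  touches <- function(df) {
    for (k in seq_len(nrow(blocks))) {
      for (j in seq_len(nrow(df))) {
        if (df$chrom[j] == hit$chrom &&
            bf_overlaps(blocks[k, 1L], blocks[k, 2L],
                        df$start[j], df$end[j])) return(TRUE)
      }
    }
    FALSE
  }
  if (nzchar(hit$gaps) || touches(ann$exons)) return("exon_or_junction")
  if (touches(ann$loci)) return("intron")
  fl <- ann$loci
  fl$start <- pmax(0L, fl$start - as.integer(flank)); fl$end <- fl$end + as.integer(flank)
  if (touches(fl)) return("flanking")
  if (touches(ann$te_features)) return("te_outside_loci")
  "intergenic"
}

# Union-of-targets overlap fraction of a query interval by per-base marking.
bf_overlap_fraction <- function(query, targets) {
  len <- query$end - query$start
  covered <- logical(len)
  for (j in seq_len(nrow(targets))) {
    if (targets$chrom[j] != query$chrom) next
    lo <- max(query$start, targets$start[j])
    hi <- min(query$end, targets$end[j])
    if (lo < hi) covered[(lo - query$start + 1L):(hi - query$start)] <- TRUE
  }
  sum(covered) / len
}

# Spliced 3'-window pieces of one transcript, by an explicit exon walk.
bf_three_prime_pieces <- function(ex, strand, window) {
  ex <- ex[order(ex$start), , drop = FALSE]
  pieces <- list(); remaining <- window
  ord <- if (strand == "+") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  for (j in ord) {
    take <- min(ex$end[j] - ex$start[j], remaining)
    pieces[[length(pieces) + 1L]] <- if (strand == "+")
      c(ex$end[j] - take, ex$end[j]) else c(ex$start[j], ex$start[j] + take)
    remaining <- remaining - take
    if (remaining <= 0L) break
  }
  do.call(rbind, pieces)
}

# Full two-step quantification by direct loops: hit/transcript
# compatibility tested block against exon (and gap against intron), the
# same filter criteria, proportional distribution, and the re-filter.
bf_quantify <- function(hits, ann, min_hits = 5, three_prime_window = 250L,
                        apply_filters = TRUE) {
  n <- nrow(hits)
  tx_ids <- ann$transcripts$transcript_id
  compat <- vector("list", n); in3p <- vector("list", n)
  for (i in seq_len(n)) {
    g <- string_to_gaps(hits$gaps[i])
    blocks <- alignment_blocks(hits$start[i], hits$end[i], g)
    ok <- character(0); ok3 <- character(0)
    for (t in seq_along(tx_ids)) {
      tid <- tx_ids[t]
      if (ann$transcripts$chrom[t] != hits$chrom[i]) next
      ex <- ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      hit_tx <- FALSE
      for (k in seq_len(nrow(blocks))) {
        for (j in seq_len(nrow(ex))) {
          if (bf_overlaps(blocks[k, 1L], blocks[k, 2L],
                          ex$start[j], ex$end[j])) hit_tx <- TRUE
        }
      }
      if (!hit_tx && nrow(g) && nrow(ex) > 1L) {
        for (k in seq_len(nrow(g))) {
          for (j in seq_len(nrow(ex) - 1L)) {
            if (g[k, 1L] == ex$end[j] && g[k, 2L] == ex$start[j + 1L])
              hit_tx <- TRUE
          }
        }
      }
      if (!hit_tx) next
      ok <- c(ok, tid)
      w3 <- bf_three_prime_pieces(ex, ann$transcripts$strand[t],
                                  three_prime_window)
      for (k in seq_len(nrow(blocks))) {
        for (j in seq_len(nrow(w3))) {
          if (bf_overlaps(blocks[k, 1L], blocks[k, 2L],
                          w3[j, 1L], w3[j, 2L])) ok3 <- c(ok3, tid)
        }
      }
    }
    compat[[i]] <- ok; in3p[[i]] <- unique(ok3)
  }

  locus_of <- stats::setNames(ann$transcripts$locus_id, tx_ids)
  run_filter <- function(contrib_of_hit_locus, allowed_tx) {
    # Tally per transcript using each hit's contribution to its locus.
    tot <- stats::setNames(numeric(length(tx_ids)), tx_ids)
    t3 <- stats::setNames(numeric(length(tx_ids)), tx_ids)
    for (i in seq_len(n)) {
      for (tid in intersect(compat[[i]], allowed_tx)) {
        cval <- contrib_of_hit_locus(i, locus_of[[tid]])
        tot[tid] <- tot[tid] + cval
        if (tid %in% in3p[[i]]) t3[tid] <- t3[tid] + cval
      }
    }
    if (!apply_filters) return(allowed_tx)
    names(tot)[tot >= min_hits & t3 > 0 & names(tot) %in% allowed_tx]
  }

  full_w <- function(i, locus) hits$weight[i]
  s1 <- run_filter(full_w, tx_ids)

  cand <- lapply(seq_len(n), function(i)
    unique(unname(locus_of[intersect(compat[[i]], s1)])))
  u <- stats::setNames(numeric(nrow(ann$loci)), ann$loci$locus_id)
  for (i in seq_len(n)) {
    if (length(cand[[i]]) == 1L)
      u[cand[[i]]] <- u[cand[[i]]] + hits$weight[i]
  }
  share <- function(i, locus) {
    cs <- cand[[i]]
    if (!(locus %in% cs)) return(0)
    if (length(cs) == 1L) return(hits$weight[i])
    su <- sum(u[cs])
    if (su > 0) hits$weight[i] * u[[locus]] / su
    else hits$weight[i] / length(cs)
  }
  s2 <- run_filter(share, s1)

  expr <- stats::setNames(numeric(nrow(ann$loci)), ann$loci$locus_id)
  for (i in seq_len(n)) {
    for (locus in unique(unname(locus_of[intersect(compat[[i]], s2)]))) {
      expr[locus] <- expr[locus] + share(i, locus)
    }
  }
  surviving <- table(unname(locus_of[s2]))
  out <- data.frame(locus_id = sort(ann$loci$locus_id))
  out$expression <- unname(expr[out$locus_id])
  out$n_transcripts_surviving <- as.integer(surviving[out$locus_id])
  out$n_transcripts_surviving[is.na(out$n_transcripts_surviving)] <- 0L
  out$expressed <- if (apply_filters) out$n_transcripts_surviving > 0L
                   else out$expression > 0
  out[, c("locus_id", "expression", "expressed", "n_transcripts_surviving")]
}

# One-sided upper-tail Fisher p by explicit binomial-coefficient summation.
bf_fisher_tail <- function(a, b, n_test, n_ref) {
  m <- a + b
  hi <- min(n_test, m)
  num <- 0
  for (k in a:hi) {
    if (m - k > n_ref) next
    num <- num + choose(n_test, k) * choose(n_ref, m - k)
  }
  num / choose(n_test + n_ref, m)
}
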