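# Seeded synthetic fixtures: toy genomes, annotations, 3'-biased spliced
# alignments and colorspace reads with full ground truth.
#
# The generator emulates the salient features of amplified, oligo-dT-primed
# low-input RNA-seq: strong 3' bias (fragment 3' ends drawn from a
# truncated exponential anchored at the transcript 3' terminus), duplicated
# gene families producing multi-mapped reads, a "truly" expressed locus
# nested inside a silent one (the failure mode the two-step quantification
# exists to avoid), transposable elements and transcribed-but-unannotated
# intervals outside loci, and a low uniform background of spurious
# alignments. All randomness flows from the single seed in the
# configuration: the same seed reproduces the fixture byte for byte.

#' Simulation configuration
#'
#' Defaults define the package's standard study conditions: a 2 x 100 kb
#' genome carrying 30 loci (one nested silent locus, one two-member paralog
#' family), log-normal true expression, exponential 3' bias with mean
#' fragment-end offset 50 bases, 50-base reads, and mild log-normal
#' between-replicate noise.
#'
#' @param seed integer seed driving all randomness.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_loci number of annotated loci (including the nested pair and
#'   paralog family members).
#' @param paralog_family_count,paralog_family_size duplicated gene families
#'   with byte-identical exonic sequence; their reads are emitted as
#'   multi-mapped alignments.
#' @param paralog_unique_fraction fraction of paralog reads covering a
#'   (hypothetical) divergent position and therefore aligned uniquely;
#'   these anchor the proportional allocation of the rest.
#' @param fraction_te standalone transposable-element features, as a
#'   fraction of `n_loci`.
#' @param n_novel transcribed but unannotated intergenic intervals.
#' @param expr_meanlog,expr_sdlog log-normal law of true locus expression.
#' @param three_prime_decay rate (1/bases) of the exponential law placing
#'   fragment 3' ends upstream of the transcript 3' terminus; 0 gives
#'   uniform coverage.
#' @param read_length read length in bases.
#' @param n_reads reads per replicate.
#' @param background_fraction fraction of reads placed uniformly at random
#'   on the genome (spurious alignments feeding the intron/flanking/
#'   intergenic categories). Off by default: on a toy-sized genome even a
#'   small read fraction yields an unrealistically dense per-base noise
#'   level, which can anchor the 3' window of the planted silent locus.
#' @param replicate_noise sdlog of the per-locus multiplicative log-normal
#'   factor applied between replicates.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 100000L,
                              n_loci = 30L,
                              paralog_family_count = 1L,
                              paralog_family_size = 2L,
                              paralog_unique_fraction = 0.2,
                              fraction_te = 0.1,
                              n_novel = 2L,
                              expr_meanlog = log(100),
                              expr_sdlog = 1,
                              three_prime_decay = 0.02,
                              read_length = 50L,
                              n_reads = 10000L,
                              background_fraction = 0,
                              replicate_noise = 0.2) {
  stopifnot(seed == as.integer(seed), n_chromosomes >= 1L,
            chrom_length >= 5000L, n_loci >= 0L,
            paralog_family_count >= 0L, paralog_family_size >= 2L,
            fraction_te >= 0, n_novel >= 0L, three_prime_decay >= 0,
            read_length >= 20L, n_reads >= 0L,
            background_fraction >= 0, background_fraction <= 1,
            replicate_noise >= 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a toy genome annotation
#'
#' Lays out `n_loci` loci over the genome with generous intergenic space:
#' each locus has one transcript of 1-3 exons on a random strand. The
#' construction plants (i) one locus nested entirely inside a silent
#' enclosing locus whose 3' end extends well past the inner locus, so the
#' inner locus' hits can never anchor the outer transcript's 3' window;
#' (ii) `paralog_family_count` families of loci with identical exon layout
#' and (in the emitted FASTA) identical sequence; (iii) standalone
#' transposable elements and unannotated "novel" transcribed intervals in
#' the intergenic space. Chromosome sequences are uniform random DNA with
#' the paralog regions copied verbatim.
#'
#' @param cfg a [simulation_config()].
#' @return List with `annotation` (a `GenomeAnnotation`), `sequences` (a
#'   `Biostrings::DNAStringSet`) and `truth` (ground-truth list: per-locus
#'   `true_expression`, `nested_pair`, `paralog_families`,
#'   `novel_intervals`, `te_intervals`).
#' @export
simulate_annotation <- function(cfg = simulation_config()) {
  if (cfg$n_loci == 0L) stop("cannot simulate an annotation with 0 loci")
  set.seed(cfg$seed)
  n_paralog <- cfg$paralog_family_count * cfg$paralog_family_size
  n_regular <- cfg$n_loci - 1L - n_paralog   # one slot for the nested outer
  if (n_regular < 1L)
    stop("n_loci too small for the requested paralog families")
  n_te <- as.integer(round(cfg$fraction_te * cfg$n_loci))

  # Sequential layout with >= 1 kb intergenic gaps; each slot holds one
  # locus (plus room for the enclosing nested locus around the first one).
  loci <- list(); transcripts <- list(); exons <- list()
  slot_chrom <- character(0); slot_range <- list()
  chroms <- paste0("Chr", seq_len(cfg$n_chromosomes))
  cursor <- stats::setNames(rep(1500L, cfg$n_chromosomes), chroms)
  chrom_lengths <- stats::setNames(rep(as.integer(cfg$chrom_length),
                                       cfg$n_chromosomes), chroms)

  make_layout <- function() {
    n_ex <- sample(1:3, 1L)
    widths <- sample(200:600, n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample(60:200, n_ex - 1L, replace = TRUE)
               else integer(0)
    starts <- cumsum(c(0L, widths[-n_ex] + introns))
    cbind(start = starts, end = starts + widths)
  }
  place <- function(layout) {
    span <- max(layout[, "end"])
    ok <- chroms[cursor + span + 1200L < chrom_lengths]
    if (!length(ok)) stop("chromosomes too short for the requested loci")
    ch <- if (length(ok) == 1L) ok else sample(ok, 1L)
    at <- cursor[[ch]]
    cursor[[ch]] <<- at + span + as.integer(sample(1000:2000, 1L))
    list(chrom = ch, at = at)
  }
  add_locus <- function(id, layout, strand, biotype = "gene",
                        chrom = NULL, at = NULL) {
    if (is.null(chrom)) {
      p <- place(layout); chrom <- p$chrom; at <- p$at
    }
    ex <- layout
    ex[, ] <- ex + at
    loci[[length(loci) + 1L]] <<- data.frame(
      locus_id = id, chrom = chrom, start = min(ex[, "start"]),
      end = max(ex[, "end"]), strand = strand, biotype = biotype)
    tid <- paste0(id, ".1")
    transcripts[[length(transcripts) + 1L]] <<- data.frame(
      transcript_id = tid, locus_id = id, chrom = chrom,
      start = min(ex[, "start"]), end = max(ex[, "end"]), strand = strand)
    exons[[length(exons) + 1L]] <<- data.frame(
      transcript_id = tid, chrom = chrom, start = ex[, "start"],
      end = ex[, "end"])
    invisible(list(chrom = chrom, start = min(ex[, "start"]),
                   end = max(ex[, "end"])))
  }

  # Regular loci (the first becomes the inner locus of the nested pair).
  ids <- sprintf("LOC%03d", seq_len(n_regular))
  inner_pos <- NULL
  inner_strand <- sample(c("+", "-"), 1L)
  for (i in seq_len(n_regular)) {
    strand <- if (i == 1L) inner_strand else sample(c("+", "-"), 1L)
    pos <- add_locus(ids[i], make_layout(), strand)
    if (i == 1L) inner_pos <- pos
  }

  # Enclosing silent locus around the inner one: single exon spanning the
  # inner locus, 3' end 400 bases past the inner locus' 3' side.
  outer_id <- "LOCOUTER"
  if (inner_strand == "+") {
    o_start <- inner_pos$start - 300L; o_end <- inner_pos$end + 400L
  } else {
    o_start <- inner_pos$start - 400L; o_end <- inner_pos$end + 300L
  }
  add_locus(outer_id,
            cbind(start = 0L, end = o_end - o_start),
            inner_strand, chrom = inner_pos$chrom, at = o_start)

  # Paralog families: one layout per family, members are shifted copies.
  paralog_families <- list()
  for (f in seq_len(cfg$paralog_family_count)) {
    layout <- make_layout()
    members <- sprintf("PAR%d_%d", f, seq_len(cfg$paralog_family_size))
    for (m in members) add_locus(m, layout, "+")
    paralog_families[[f]] <- members
  }

  # Standalone TEs and unannotated novel intervals in remaining space.
  te_intervals <- data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), strand = character(0))
  for (i in seq_len(n_te)) {
    w <- sample(300:800, 1L)
    p <- place(cbind(start = 0L, end = w))
    te_intervals <- rbind(te_intervals, data.frame(
      chrom = p$chrom, start = p$at, end = p$at + w,
      strand = sample(c("+", "-"), 1L)))
  }
  novel_intervals <- data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), strand = character(0))
  for (i in seq_len(cfg$n_novel)) {
    w <- sample(400:900, 1L)
    p <- place(cbind(start = 0L, end = w))
    novel_intervals <- rbind(novel_intervals, data.frame(
      chrom = p$chrom, start = p$at, end = p$at + w, strand = "+"))
  }

  ann <- genome_annotation(do.call(rbind, loci), do.call(rbind, transcripts),
                           do.call(rbind, exons), te_intervals,
                           chrom_lengths)

  # True expression: log-normal per locus; the outer nested locus is silent.
  expr <- stats::rlnorm(nrow(ann$loci), cfg$expr_meanlog, cfg$expr_sdlog)
  names(expr) <- ann$loci$locus_id
  expr[outer_id] <- 0

  # Random genome with paralog regions copied verbatim.
  sequences <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_lengths[[ch]],
                 replace = TRUE), collapse = ""), character(1L)))
  names(sequences) <- chroms
  for (fam in paralog_families) {
    l <- ann$loci[match(fam, ann$loci$locus_id), ]
    tmpl <- Biostrings::subseq(sequences[[l$chrom[1L]]],
                               l$start[1L] + 1L, l$end[1L])
    for (m in seq_along(fam)[-1L]) {
      Biostrings::subseq(sequences[[l$chrom[m]]],
                         l$start[m] + 1L, l$end[m]) <- tmpl
    }
  }

  truth <- list(true_expression = expr,
                nested_pair = c(inner = ids[1L], outer = outer_id),
                paralog_families = paralog_families,
                novel_intervals = novel_intervals,
                te_intervals = te_intervals)
  list(annotation = ann, sequences = sequences, truth = truth)
}

# Map a spliced interval [start_s, end_s) (0-based, 5'->3') of a transcript
# to genomic blocks, given its exons sorted by genomic start and its strand.
spliced_to_genomic <- function(exons, strand, start_s, end_s) {
  w <- exons$end - exons$start
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  w_t <- w[ord]
  cum0 <- cumsum(c(0L, w_t))[seq_along(w_t)]
  pieces <- list()
  for (k in seq_along(ord)) {
    lo <- max(start_s, cum0[k]); hi <- min(end_s, cum0[k] + w_t[k])
    if (lo >= hi) next
    i <- ord[k]
    if (strand == "+") {
      gs <- exons$start[i] + (lo - cum0[k]); ge <- exons$start[i] + (hi - cum0[k])
    } else {
      ge <- exons$end[i] - (lo - cum0[k]); gs <- exons$end[i] - (hi - cum0[k])
    }
    pieces[[length(pieces) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, pieces)
  m[order(m[, 1L]), , drop = FALSE]
}

# Draw fragment 3'-end offsets (bases upstream of the transcript 3'
# terminus) from an exponential truncated at the spliced length; decay 0
# gives the uniform law.
draw_three_prime_offsets <- function(n, spliced_length, decay) {
  if (decay <= 0) return(sample.int(spliced_length, n, replace = TRUE) - 1L)
  u <- stats::runif(n)
  x <- -log(1 - u * (1 - exp(-decay * spliced_length))) / decay
  pmin(as.integer(floor(x)), spliced_length - 1L)
}

#' Simulate one replicate of 3'-biased reads
#'
#' Read counts per source (transcripts, novel intervals, TE intervals) are
#' multinomial on the true expression (novel/TE sources at a reduced rate),
#' fragment 3' ends follow the truncated-exponential bias model, and reads
#' spanning introns are emitted as gapped alignments. Reads from paralog
#' family members carry one alignment per member (multi-mapped) except for
#' the `paralog_unique_fraction` that aligns uniquely. A
#' `background_fraction` of reads is scattered uniformly over the genome.
#' No aligner is involved: alignments are emitted directly.
#'
#' @param ann a `GenomeAnnotation` from [simulate_annotation()].
#' @param truth its ground-truth list.
#' @param cfg the [simulation_config()].
#' @param replicate replicate number (drives the seed offset and the
#'   per-locus log-normal replicate noise).
#' @return List with `alignments` (internal alignment table, ready for
#'   [write_sam()] or [weight_alignments()]), `read_origin` (data.frame
#'   `read_id`, `source_id`, `locus_id`) and `counts` (reads drawn per
#'   locus).
#' @export
simulate_reads <- function(ann, truth, cfg = simulation_config(),
                           replicate = 1L) {
  set.seed(cfg$seed + 7919L * as.integer(replicate))
  prefix <- sprintf("r%d", replicate)

  # Source pool: one entry per transcript, novel interval and TE interval.
  tx <- ann$transcripts
  tx_expr <- truth$true_expression[tx$locus_id]
  noise <- stats::rlnorm(nrow(ann$loci), 0, cfg$replicate_noise)
  names(noise) <- ann$loci$locus_id
  tx_expr <- tx_expr * noise[tx$locus_id]

  aux <- rbind(
    if (nrow(truth$novel_intervals))
      cbind(truth$novel_intervals,
            source_id = sprintf("NOV%d", seq_len(nrow(truth$novel_intervals)))),
    if (nrow(truth$te_intervals))
      cbind(truth$te_intervals,
            source_id = sprintf("TEI%d", seq_len(nrow(truth$te_intervals)))))
  aux_expr <- if (!is.null(aux) && nrow(aux))
    stats::rlnorm(nrow(aux), cfg$expr_meanlog, cfg$expr_sdlog) * 0.2
  else numeric(0)

  probs <- c(tx_expr, aux_expr)
  n_bg <- stats::rbinom(1L, cfg$n_reads, cfg$background_fraction)
  n_src <- cfg$n_reads - n_bg
  counts <- if (sum(probs) > 0 && n_src > 0)
    as.integer(stats::rmultinom(1L, n_src, probs)) else rep(0L, length(probs))

  fam_of <- stats::setNames(rep(NA_integer_, nrow(tx)), tx$transcript_id)
  for (f in seq_along(truth$paralog_families))
    fam_of[paste0(truth$paralog_families[[f]], ".1")] <- f

  # Preallocated accumulators (one slot per emitted alignment).
  max_fam <- max(c(1L, cfg$paralog_family_size))
  cap <- cfg$n_reads * max_fam + 16L
  A <- list(read_id = character(cap), chrom = character(cap),
            start = integer(cap), end = integer(cap),
            gaps = character(cap), n_alignments = integer(cap))
  O <- list(read_id = character(cfg$n_reads + 16L),
            source_id = character(cfg$n_reads + 16L),
            locus_id = character(cfg$n_reads + 16L))
  na <- 0L; no <- 0L; read_no <- 0L
  emit <- function(read_id, chrom, blocks, n_aln) {
    na <<- na + 1L
    g <- if (nrow(blocks) > 1L)
      cbind(blocks[-nrow(blocks), 2L], blocks[-1L, 1L])
    else matrix(integer(0), ncol = 2L)
    A$read_id[na] <<- read_id; A$chrom[na] <<- chrom
    A$start[na] <<- blocks[1L, 1L]; A$end[na] <<- blocks[nrow(blocks), 2L]
    A$gaps[na] <<- gaps_to_string(g); A$n_alignments[na] <<- n_aln
  }
  note_origin <- function(read_id, source_id, locus_id) {
    no <<- no + 1L
    O$read_id[no] <<- read_id; O$source_id[no] <<- source_id
    O$locus_id[no] <<- locus_id
  }

  for (si in seq_along(counts)) {
    n <- counts[si]
    if (n == 0L) next
    if (si <= nrow(tx)) {
      t <- tx[si, ]
      ex <- ann$exons[ann$exons$transcript_id == t$transcript_id, ,
                      drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      L <- sum(ex$end - ex$start)
      offs <- draw_three_prime_offsets(n, L, cfg$three_prime_decay)
      fam <- fam_of[[t$transcript_id]]
      uniq <- if (!is.na(fam)) stats::runif(n) < cfg$paralog_unique_fraction
              else rep(TRUE, n)
      members <- if (!is.na(fam)) paste0(truth$paralog_families[[fam]], ".1")
      shifts <- if (!is.na(fam))
        tx$start[match(members, tx$transcript_id)] - t$start
      member_chroms <- if (!is.na(fam))
        tx$chrom[match(members, tx$transcript_id)]
      for (j in seq_len(n)) {
        read_no <- read_no + 1L
        rid <- sprintf("%s_%06d", prefix, read_no)
        end_s <- L - offs[j]; start_s <- max(0L, end_s - cfg$read_length)
        blocks <- spliced_to_genomic(ex, t$strand, start_s, end_s)
        if (is.na(fam) || uniq[j]) {
          emit(rid, t$chrom, blocks, 1L)
        } else {
          for (m in seq_along(members))
            emit(rid, member_chroms[m], blocks + shifts[m], length(members))
        }
        note_origin(rid, t$transcript_id, t$locus_id)
      }
    } else {
      iv <- aux[si - nrow(tx), ]
      L <- iv$end - iv$start
      offs <- draw_three_prime_offsets(n, L, cfg$three_prime_decay)
      for (j in seq_len(n)) {
        read_no <- read_no + 1L
        rid <- sprintf("%s_%06d", prefix, read_no)
        end_s <- L - offs[j]; start_s <- max(0L, end_s - cfg$read_length)
        emit(rid, iv$chrom,
             cbind(iv$start + start_s, iv$start + end_s), 1L)
        note_origin(rid, iv$source_id, NA_character_)
      }
    }
  }

  # Uniform background.
  for (j in seq_len(n_bg)) {
    read_no <- read_no + 1L
    rid <- sprintf("%s_%06d", prefix, read_no)
    ch <- sample(names(ann$chrom_lengths), 1L)
    st <- sample.int(ann$chrom_lengths[[ch]] - cfg$read_length, 1L) - 1L
    emit(rid, ch, cbind(st, st + cfg$read_length), 1L)
    note_origin(rid, "background", NA_character_)
  }

  alignments <- data.frame(
    read_id = A$read_id[seq_len(na)], chrom = A$chrom[seq_len(na)],
    start = A$start[seq_len(na)], end = A$end[seq_len(na)],
    gaps = A$gaps[seq_len(na)], n_alignments = A$n_alignments[seq_len(na)],
    stringsAsFactors = FALSE)
  alignments$is_unique <- alignments$n_alignments == 1L
  origin <- data.frame(read_id = O$read_id[seq_len(no)],
                       source_id = O$source_id[seq_len(no)],
                       locus_id = O$locus_id[seq_len(no)],
                       stringsAsFactors = FALSE)
  per_locus <- table(origin$locus_id[!is.na(origin$locus_id)])
  counts_per_locus <- stats::setNames(rep(0L, nrow(ann$loci)),
                                      ann$loci$locus_id)
  counts_per_locus[names(per_locus)] <- as.integer(per_locus)
  list(alignments = alignments, read_origin = origin,
       counts = counts_per_locus)
}

#' Render simulated reads in SOLiD colorspace
#'
#' Extracts each alignment's base sequence from the simulated genome
#' (reverse-complemented for minus-strand sources is unnecessary for the
#' filter fixtures, so reads are rendered in genome orientation), encodes
#' it in colorspace behind a `T` primer base using the standard dibase code
#' (color = XOR of the 2-bit base encodings), and attaches per-color
#' qualities drawn uniformly from `qual_range`. Multi-mapped reads are
#' rendered once from their first alignment.
#'
#' @param alignments alignment table from [simulate_reads()].
#' @param sequences `DNAStringSet` of chromosome sequences.
#' @param cfg the [simulation_config()] (seed and replicate offset drive the
#'   qualities).
#' @param qual_range integer range of per-color qualities.
#' @return Colorspace read table as from [read_colorspace()].
#' @export
render_colorspace <- function(alignments, sequences,
                              cfg = simulation_config(),
                              qual_range = c(15L, 35L)) {
  set.seed(cfg$seed + 104729L)
  a <- alignments[!duplicated(alignments$read_id), , drop = FALSE]
  colors <- character(nrow(a)); quals <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    g <- string_to_gaps(a$gaps[i])
    b <- alignment_blocks(a$start[i], a$end[i], g)
    seq <- paste(vapply(seq_len(nrow(b)), function(k)
      as.character(Biostrings::subseq(sequences[[a$chrom[i]]],
                                      b[k, 1L] + 1L, b[k, 2L])),
      character(1L)), collapse = "")
    colors[i] <- encode_colors(paste0("T", seq))
    quals[[i]] <- sample(seq(qual_range[1L], qual_range[2L]),
                         nchar(colors[i]), replace = TRUE)
  }
  data.frame(read_id = a$read_id, primer_base = "T", colors = colors,
             qualities = I(quals), stringsAsFactors = FALSE)
}

# SOLiD dibase encoding: color of a base pair is the XOR of the 2-bit codes
# A=0, C=1, G=2, T=3. Input includes the primer base; output has one color
# per adjacent pair.
encode_colors <- function(bases) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- code[strsplit(bases, "")[[1L]]]
  paste(bitwXor(v[-length(v)], v[-1L]), collapse = "")
}

#' Colorspace fixture with planted filter violators
#'
#' Generates `n` clean reads guaranteed to pass every filter rule (distinct
#' non-repetitive color strings, qualities comfortably above the quality
#' threshold, no ambiguous call) and optionally appends exactly one
#' violator per rule: a low-quality read, a read with an ambiguous color, a
#' repetitive read, and an exact duplicate of a clean read.
#'
#' @param n number of clean reads.
#' @param seed seed.
#' @param read_length colors per read.
#' @param plant_violators append the four violators.
#' @return Colorspace read table.
#' @export
simulate_colorspace_fixture <- function(n = 20L, seed = 1L,
                                        read_length = 30L,
                                        plant_violators = TRUE) {
  set.seed(seed)
  mk_clean <- function() {
    repeat {
      cs <- paste(sample(0:3, read_length, replace = TRUE), collapse = "")
      if (!is_repetitive(cs)) return(cs)
    }
  }
  colors <- character(0)
  while (length(colors) < n) {
    cs <- mk_clean()
    if (!cs %in% colors) colors <- c(colors, cs)
  }
  quals <- replicate(n, sample(15:35, read_length, replace = TRUE),
                     simplify = FALSE)
  ids <- sprintf("clean_%03d", seq_len(n))
  if (plant_violators) {
    colors <- c(colors, mk_clean(), sub("0|1|2|3", ".", mk_clean()),
                paste(rep("01", read_length %/% 2L), collapse = ""),
                colors[1L])
    quals <- c(quals, list(rep(1L, read_length)),
               replicate(3L, sample(15:35, read_length, replace = TRUE),
                         simplify = FALSE))
    quals <- mapply(function(q, cs) rep_len(q, nchar(cs)),
                    quals, colors, SIMPLIFY = FALSE)
    ids <- c(ids, "viol_lowqual", "viol_ambiguous", "viol_repetitive",
             "viol_duplicate")
  }
  data.frame(read_id = ids, primer_base = "T", colors = colors,
             qualities = I(unname(quals)), stringsAsFactors = FALSE)
}

#' Generate a complete end-to-end fixture directory
#'
#' Writes every input the pipeline consumes -- GFF3 annotation, genome
#' FASTA, two replicate SAM files, csfasta/qual colorspace reads -- plus
#' ground truth (true expression, per-read origin) and expected outputs
#' computed with the independent per-base brute-force reference
#' implementation (weights, category totals, per-locus expression), for use
#' in regression tests.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`annotation`,
#'   `truth`, `alignments` per replicate, `expected` brute-force results)
#'   and the file paths written.
#' @export
end_to_end_fixture <- function(cfg = simulation_config(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_annotation(cfg)
  repA <- simulate_reads(sim$annotation, sim$truth, cfg, replicate = 1L)
  repB <- simulate_reads(sim$annotation, sim$truth, cfg, replicate = 2L)

  paths <- list(
    gff = file.path(dir, "annotation.gff3"),
    fasta = file.path(dir, "genome.fa"),
    samA = file.path(dir, "repA.sam"),
    samB = file.path(dir, "repB.sam"),
    csfasta = file.path(dir, "repA.csfasta"),
    qual = file.path(dir, "repA.qual"),
    truth = file.path(dir, "true_expression.tsv"),
    expected = file.path(dir, "expected_expression.tsv"))

  write_annotation(sim$annotation, paths$gff)
  Biostrings::writeXStringSet(sim$sequences, paths$fasta)
  write_sam(repA$alignments, sim$annotation$chrom_lengths, paths$samA)
  write_sam(repB$alignments, sim$annotation$chrom_lengths, paths$samB)
  cs <- render_colorspace(repA$alignments, sim$sequences, cfg)
  write_colorspace(cs, paths$csfasta, paths$qual)
  write_table(data.frame(locus_id = names(sim$truth$true_expression),
                         true_expression = sim$truth$true_expression,
                         reads_repA = repA$counts,
                         reads_repB = repB$counts),
              paths$truth)

  hitsA <- bf_weight_alignments(repA$alignments,
                                sim$annotation$chrom_lengths)
  expected <- bf_quantify(hitsA, sim$annotation)
  write_table(expected, paths$expected)

  invisible(list(annotation = sim$annotation, sequences = sim$sequences,
                 truth = sim$truth, repA = repA, repB = repB,
                 colorspace = cs, expected = expected, paths = paths))
}
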