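# Reading and writing of the standard formats the toolkit touches: GFF3
# annotations, SAM alignments, SOLiD csfasta/qual colorspace reads, BED and
# TSV tables. All coordinates are normalised to 0-based half-open on the way
# in and converted back at the boundary on the way out.

#' Construct a genome annotation object
#'
#' Bundles loci, transcripts, exons, standalone transposable-element features
#' and chromosome lengths into the container used by all downstream modules.
#' Usually produced by [read_annotation()] or [simulate_annotation()]; exposed
#' so toy annotations can be built programmatically.
#'
#' All coordinates are 0-based half-open. Invariants enforced: every
#' transcript lies within its locus, every exon within its transcript, exons
#' of a transcript are non-overlapping, and every locus has at least one
#' transcript.
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (one of `"gene"`, `"pseudogene"`, `"te_gene"`).
#' @param transcripts data.frame with columns `transcript_id`, `locus_id`,
#'   `chrom`, `start`, `end`, `strand` (`"+"` or `"-"`).
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`, `end`.
#' @param te_features data.frame with columns `chrom`, `start`, `end`,
#'   `strand`; transposable elements outside annotated loci.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(loci, transcripts, exons,
                              te_features = NULL, chrom_lengths = NULL) {
  te_features <- te_features %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  loci <- as.data.frame(loci); transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons); te_features <- as.data.frame(te_features)

  if (nrow(loci) && anyDuplicated(loci$locus_id))
    stop("duplicated locus ids")
  if (nrow(transcripts) && anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript ids")
  bad <- setdiff(transcripts$locus_id, loci$locus_id)
  if (length(bad)) stop("transcript parent locus not found: ", bad[1L])
  bad <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(bad)) stop("exon parent transcript not found: ", bad[1L])
  orphan <- setdiff(loci$locus_id, transcripts$locus_id)
  if (length(orphan)) stop("locus without transcript: ", orphan[1L])
  noexon <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(noexon)) stop("transcript without exons: ", noexon[1L])
  if (any(loci$start >= loci$end) || any(exons$start >= exons$end))
    stop("empty or inverted interval in annotation")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'")

  li <- match(transcripts$locus_id, loci$locus_id)
  if (any(transcripts$start < loci$start[li] | transcripts$end > loci$end[li] |
          transcripts$chrom != loci$chrom[li])) {
    off <- which(transcripts$start < loci$start[li] |
                 transcripts$end > loci$end[li] |
                 transcripts$chrom != loci$chrom[li])[1L]
    stop("transcript outside its locus: ", transcripts$transcript_id[off])
  }
  ti <- match(exons$transcript_id, transcripts$transcript_id)
  if (any(exons$start < transcripts$start[ti] | exons$end > transcripts$end[ti] |
          exons$chrom != transcripts$chrom[ti])) {
    off <- which(exons$start < transcripts$start[ti] |
                 exons$end > transcripts$end[ti])[1L]
    stop("exon outside its transcript: ", exons$transcript_id[off])
  }

  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (ids in by_tx) {
    if (length(ids) > 1L) {
      s <- exons$start[ids]; e <- exons$end[ids]
      if (any(s[-1L] < e[-length(e)]))
        stop("overlapping exons in transcript: ", exons$transcript_id[ids[1L]])
    }
  }

  if (is.null(chrom_lengths)) {
    ends <- c(loci$end, te_features$end)
    chroms <- c(loci$chrom, te_features$chrom)
    chrom_lengths <- vapply(split(ends, chroms), max, numeric(1L))
    chrom_lengths <- as.integer(chrom_lengths)
    names(chrom_lengths) <- names(split(ends, chroms))
  }
  rownames(loci) <- rownames(transcripts) <- rownames(exons) <- NULL
  rownames(te_features) <- NULL
  structure(list(loci = loci, transcripts = transcripts, exons = exons,
                 te_features = te_features,
                 chrom_lengths = chrom_lengths),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$loci), "loci,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons,", nrow(x$te_features),
      "TE features,", length(x$chrom_lengths), "chromosomes\n")
  invisible(x)
}

#' Read a genome annotation from GFF3
#'
#' Parses a GFF3 file in the TAIR dialect (locus features with mRNA and exon
#' children, plus standalone transposable elements) into a
#' [genome_annotation()] object. 1-based closed GFF coordinates are converted
#' to the internal 0-based half-open convention. Locus features of biotype
#' `transposable_element_gene` become loci; standalone features of the
#' `te_types` (by default `transposable_element`) that are not children of a
#' locus populate the separate TE track used for intergenic classification.
#'
#' Transcripts without exon children receive a single full-length pseudo-exon,
#' so annotations that omit exon rows for pseudogenes or TE genes are accepted.
#'
#' @param path GFF3 file.
#' @param locus_types GFF3 feature types treated as loci.
#' @param te_types feature types treated as standalone transposable elements.
#' @param chrom_lengths optional named integer vector; inferred from feature
#'   extents when absent.
#' @return A `GenomeAnnotation`.
#' @export
read_annotation <- function(path,
                            locus_types = c("gene", "pseudogene",
                                            "transposable_element_gene"),
                            te_types = "transposable_element",
                            chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    # Honour ##sequence-region directives when the file carries them.
    hdr <- grep("^##sequence-region", readLines(path, n = 200L),
                value = TRUE)
    if (length(hdr)) {
      parts <- strsplit(trimws(hdr), "\\s+")
      chrom_lengths <- vapply(parts, function(p) as.integer(p[[4L]]),
                              integer(1L))
      names(chrom_lengths) <- vapply(parts, `[[`, character(1L), 2L)
    }
  }
  g <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(g)
  df$Parent <- vapply(as.list(g$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  df$ID <- as.character(df$ID)

  is_locus <- df$type %in% locus_types
  loci <- data.frame(
    locus_id = df$ID[is_locus],
    chrom = as.character(df$seqnames[is_locus]),
    start = df$start[is_locus] - 1L,
    end = df$end[is_locus],
    strand = as.character(df$strand[is_locus]),
    biotype = ifelse(df$type[is_locus] == "pseudogene", "pseudogene",
                     ifelse(df$type[is_locus] == "transposable_element_gene",
                            "te_gene", "gene"))
  )
  if (anyNA(loci$locus_id)) stop("locus feature without an ID attribute")

  is_tx <- !is.na(df$Parent) & df$Parent %in% loci$locus_id & !is_locus
  transcripts <- data.frame(
    transcript_id = df$ID[is_tx],
    locus_id = df$Parent[is_tx],
    chrom = as.character(df$seqnames[is_tx]),
    start = df$start[is_tx] - 1L,
    end = df$end[is_tx],
    strand = as.character(df$strand[is_tx])
  )
  if (anyNA(transcripts$transcript_id))
    stop("transcript feature without an ID attribute under locus ",
         transcripts$locus_id[which(is.na(transcripts$transcript_id))[1L]])

  is_exon <- df$type == "exon" & !is.na(df$Parent) &
    df$Parent %in% transcripts$transcript_id
  exons <- data.frame(
    transcript_id = df$Parent[is_exon],
    chrom = as.character(df$seqnames[is_exon]),
    start = df$start[is_exon] - 1L,
    end = df$end[is_exon]
  )

  # Pseudogene/TE-gene transcripts may lack exon rows: give them one
  # full-length pseudo-exon.
  noexon <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(noexon)) {
    i <- match(noexon, transcripts$transcript_id)
    exons <- rbind(exons, data.frame(
      transcript_id = noexon, chrom = transcripts$chrom[i],
      start = transcripts$start[i], end = transcripts$end[i]))
  }

  is_te <- df$type %in% te_types &
    (is.na(df$Parent) | !(df$Parent %in% loci$locus_id))
  te_features <- data.frame(
    chrom = as.character(df$seqnames[is_te]),
    start = df$start[is_te] - 1L,
    end = df$end[is_te],
    strand = as.character(df$strand[is_te])
  )

  genome_annotation(loci, transcripts, exons, te_features, chrom_lengths)
}

#' Read read alignments from a SAM file
#'
#' Loads a SAM file (converted to BAM in a temporary directory) and returns
#' one row per alignment with all alignments of a read grouped together.
#' Gapped alignments (CIGAR `N` operations) carry their skipped intervals in
#' the `gaps` column, encoded `"start-end;start-end"` in 0-based half-open
#' genome coordinates. The per-read alignment count is taken from the `NH`
#' tag when present, otherwise from the group size after grouping by read
#' name; reads with more alignments than `max_alignments` are dropped with a
#' warning.
#'
#' @param path SAM (or BAM) file.
#' @param max_alignments maximum alignments per read to retain (default 10).
#' @return data.frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `gaps`, `n_alignments`, `is_unique`, ordered by read id then position.
#' @export
read_alignments <- function(path, max_alignments = 10L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(tag = "NH"))
  if (length(ga) == 0L) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      gaps = character(0), n_alignments = integer(0),
                      is_unique = logical(0)))
  }
  gapr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), ops = "N",
    pos = GenomicRanges::start(ga))
  gaps <- vapply(seq_along(ga), function(i) {
    r <- gapr[[i]]
    if (length(r) == 0L) return("")
    gaps_to_string(cbind(IRanges::start(r) - 1L, IRanges::end(r)))
  }, character(1L))

  df <- data.frame(
    read_id = names(ga),
    chrom = as.character(GenomicRanges::seqnames(ga)),
    start = GenomicRanges::start(ga) - 1L,
    end = GenomicRanges::end(ga),
    gaps = gaps,
    stringsAsFactors = FALSE
  )
  nh <- S4Vectors::mcols(ga)$NH
  grp <- as.integer(table(df$read_id)[df$read_id])
  df$n_alignments <- if (!is.null(nh) && !anyNA(nh)) as.integer(nh) else grp
  # An NH tag smaller than the observed group is inconsistent; trust the group.
  df$n_alignments <- pmax(df$n_alignments, grp)
  too_many <- df$n_alignments > max_alignments
  if (any(too_many)) {
    warning(sum(too_many), " alignment(s) from ",
            length(unique(df$read_id[too_many])),
            " read(s) exceed max_alignments = ", max_alignments,
            " and were skipped")
    df <- df[!too_many, , drop = FALSE]
  }
  df$is_unique <- df$n_alignments == 1L
  df <- df[order(df$read_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read SOLiD colorspace reads from csfasta + qual files
#'
#' Each csfasta record is a primer base followed by a color string over
#' `0123.`; the paired qual file carries one integer quality per color.
#' Record ids must match pairwise between the two files and quality vectors
#' must match the color-string lengths.
#'
#' @param csfasta_path,qual_path paths to the paired files.
#' @return data.frame with columns `read_id`, `primer_base`, `colors` and a
#'   list column `qualities`.
#' @export
read_colorspace <- function(csfasta_path, qual_path) {
  parse_records <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    hdr <- startsWith(lines, ">")
    if (length(lines) && !hdr[1L]) stop("malformed csfasta/qual: ", path)
    ids <- sub("^>", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    vals <- split(lines[!hdr], cumsum(hdr)[!hdr])
    vals <- vapply(vals, paste, character(1L), collapse = " ")
    if (length(vals) != length(ids)) stop("record without sequence in ", path)
    list(ids = ids, vals = unname(vals))
  }
  cs <- parse_records(csfasta_path)
  qu <- parse_records(qual_path)
  if (length(cs$ids) != length(qu$ids))
    stop("csfasta and qual have different record counts")
  mism <- which(cs$ids != qu$ids)
  if (length(mism))
    stop("csfasta/qual id mismatch at read ", cs$ids[mism[1L]])
  if (length(cs$ids) == 0L) {
    return(data.frame(read_id = character(0), primer_base = character(0),
                      colors = character(0),
                      qualities = I(list())))
  }
  seqs <- gsub(" ", "", cs$vals)
  primer <- substr(seqs, 1L, 1L)
  if (!all(primer %in% c("A", "C", "G", "T")))
    stop("invalid primer base at read ",
         cs$ids[which(!primer %in% c("A", "C", "G", "T"))[1L]])
  colors <- substr(seqs, 2L, nchar(seqs))
  quals <- lapply(strsplit(trimws(qu$vals), "\\s+"), as.integer)
  bad <- which(nchar(colors) != lengths(quals))
  if (length(bad))
    stop("quality length mismatch at read ", cs$ids[bad[1L]])
  data.frame(read_id = cs$ids, primer_base = primer, colors = colors,
             qualities = I(quals), stringsAsFactors = FALSE)
}

#' Write colorspace reads to csfasta + qual files
#'
#' Inverse of [read_colorspace()].
#'
#' @param reads data.frame as returned by [read_colorspace()].
#' @param csfasta_path,qual_path output paths; the qual file is omitted when
#'   `qual_path` is `NULL`.
#' @export
write_colorspace <- function(reads, csfasta_path, qual_path = NULL) {
  writeLines(paste0(">", reads$read_id, "\n", reads$primer_base, reads$colors),
             csfasta_path)
  if (!is.null(qual_path)) {
    quals <- vapply(reads$qualities, paste, character(1L), collapse = " ")
    writeLines(paste0(">", reads$read_id, "\n", quals), qual_path)
  }
  invisible(csfasta_path)
}

#' Write a table as TSV
#'
#' Tab-separated with header, no quoting, deterministic row order (rows are
#' sorted by the first column, then the second when present, unless
#' `sort = FALSE`).
#'
#' @param rows data.frame.
#' @param path output path.
#' @param sort sort rows for determinism (default `TRUE`).
#' @export
write_table <- function(rows, path, sort = TRUE) {
  rows <- as.data.frame(rows)
  if (sort && nrow(rows) > 1L) {
    keys <- rows[, seq_len(min(2L, ncol(rows))), drop = FALSE]
    rows <- rows[do.call(order, unname(keys)), , drop = FALSE]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

#' Write intervals as BED
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates are written unchanged. Rows are sorted by (chrom, start, end).
#' Optional `name`/`score`/`strand` columns are emitted when present.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_regions <- function(intervals, path) {
  df <- order_intervals(as.data.frame(intervals))
  cols <- list(df$chrom, df$start, df$end)
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(df)) cols <- c(cols, list(df[[extra]]))
    else if (any(c("name", "score", "strand") %in% names(df)[-(1:3)])) break
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` plus `name`, `score`,
#'   `strand` when present in the file.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write alignments as SAM
#'
#' Emits a minimal SAM file (header with `@SQ` lines, `NH` alignment-count
#' tags, `*` sequence) from an alignment table in internal coordinates.
#' CIGAR strings are reconstructed from the aligned blocks and gaps
#' (`M`/`N` operations). Rows are sorted by read id then position so output
#' is deterministic.
#'
#' @param alignments data.frame as returned by [read_alignments()].
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @param path output path.
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  a <- alignments[order(alignments$read_id, alignments$chrom,
                        alignments$start), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chrom_lengths),
                  "\tLN:", as.integer(chrom_lengths)))
  cigars <- vapply(seq_len(nrow(a)), function(i) {
    g <- string_to_gaps(a$gaps[i])
    b <- alignment_blocks(a$start[i], a$end[i], g)
    ops <- paste0(b[, 2L] - b[, 1L], "M")
    if (nrow(g)) {
      ns <- paste0(g[, 2L] - g[, 1L], "N")
      paste0(paste0(ops[-length(ops)], ns, collapse = ""), ops[length(ops)])
    } else ops
  }, character(1L))
  body <- paste(a$read_id, 0L, a$chrom, a$start + 1L, 255L, cigars,
                "*", 0L, 0L, "*", "*",
                paste0("NH:i:", a$n_alignments), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a genome annotation as GFF3 (TAIR dialect)
#'
#' Inverse of [read_annotation()]: loci become `gene`/`pseudogene`/
#' `transposable_element_gene` rows with `mRNA` and `exon` children, TE
#' features become standalone `transposable_element` rows, and chromosome
#' lengths are recorded as `##sequence-region` directives. Internal 0-based
#' half-open coordinates are converted back to 1-based closed.
#'
#' @param ann a `GenomeAnnotation`.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  type_of <- c(gene = "gene", pseudogene = "pseudogene",
               te_gene = "transposable_element_gene")
  l <- order_intervals(ann$loci)
  rows <- character(0)
  for (i in seq_len(nrow(l))) {
    rows <- c(rows, paste(l$chrom[i], "lamquant", type_of[[l$biotype[i]]],
                          l$start[i] + 1L, l$end[i], ".", l$strand[i], ".",
                          paste0("ID=", l$locus_id[i]), sep = "\t"))
    txs <- ann$transcripts[ann$transcripts$locus_id == l$locus_id[i], ,
                           drop = FALSE]
    txs <- txs[order(txs$start, txs$transcript_id), , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      rows <- c(rows, paste(txs$chrom[j], "lamquant", "mRNA",
                            txs$start[j] + 1L, txs$end[j], ".", txs$strand[j],
                            ".", paste0("ID=", txs$transcript_id[j],
                                        ";Parent=", l$locus_id[i]),
                            sep = "\t"))
      ex <- ann$exons[ann$exons$transcript_id == txs$transcript_id[j], ,
                      drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      rows <- c(rows, paste(ex$chrom, "lamquant", "exon", ex$start + 1L,
                            ex$end, ".", txs$strand[j], ".",
                            paste0("Parent=", txs$transcript_id[j]),
                            sep = "\t"))
    }
  }
  te <- order_intervals(ann$te_features)
  if (nrow(te)) {
    rows <- c(rows, paste(te$chrom, "lamquant", "transposable_element",
                          te$start + 1L, te$end, ".", te$strand, ".",
                          paste0("ID=TE", seq_len(nrow(te))), sep = "\t"))
  }
  writeLines(c("##gff-version 3",
               paste("##sequence-region", names(ann$chrom_lengths), 1L,
                     as.integer(ann$chrom_lengths)),
               rows), path)
  invisible(path)
}

#' Write and read hit tables
#'
#' Hits (weighted alignments) are exchanged as TSV with columns `read_id`,
#' `chrom`, `start`, `end`, `gaps`, `n_alignments`, `is_unique`, `score`,
#' `weight`; rows sorted by read id then position. [read_hits()] restores
#' the empty-string encoding of "no gaps".
#'
#' @param hits hit table from [weight_alignments()].
#' @param path TSV path.
#' @export
write_hits <- function(hits, path) {
  h <- hits[order(hits$read_id, hits$chrom, hits$start), , drop = FALSE]
  write_table(h, path, sort = FALSE)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "",
                         colClasses = c(gaps = "character"))
  h$gaps[is.na(h$gaps)] <- ""
  h
}
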