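write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("GFF3 coordinates convert to 0-based half-open with length preserved", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "Chr1\t.\tgene\t101\t200\t.\t+\t.\tID=L1",
    "Chr1\t.\tmRNA\t101\t200\t.\t+\t.\tID=T1;Parent=L1",
    "Chr1\t.\texon\t101\t140\t.\t+\t.\tParent=T1",
    "Chr1\t.\texon\t161\t200\t.\t+\t.\tParent=T1"), ".gff3")
  ann <- read_annotation(gff)
  expect_equal(ann$loci$start, 100L)
  expect_equal(ann$loci$end, 200L)
  # Internal length equals GFF end - start + 1 for every feature.
  expect_equal(ann$loci$end - ann$loci$start, 200L - 101L + 1L)
  expect_equal(ann$exons$end - ann$exons$start, c(40L, 40L))
  expect_equal(nrow(ann$loci), 1L)
  expect_equal(nrow(ann$transcripts), 1L)
  expect_equal(nrow(ann$exons), 2L)
})

test_that("annotation hierarchy violations are rejected by feature id", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "Chr1\t.\tgene\t101\t200\t.\t+\t.\tID=L1",
    "Chr1\t.\tmRNA\t101\t200\t.\t+\t.\tID=T1;Parent=L1",
    "Chr1\t.\texon\t101\t240\t.\t+\t.\tParent=T1"), ".gff3")
  expect_error(read_annotation(gff), "T1")

  # A pseudogene transcript without exon children gets a full-length
  # pseudo-exon instead of an error.
  gff2 <- write_lines_tmp(c(
    "##gff-version 3",
    "Chr1\t.\tpseudogene\t501\t900\t.\t-\t.\tID=P1",
    "Chr1\t.\tmRNA\t501\t900\t.\t-\t.\tID=P1.1;Parent=P1"), ".gff3")
  ann <- read_annotation(gff2)
  expect_equal(ann$exons$start, 500L)
  expect_equal(ann$exons$end, 900L)
  expect_equal(ann$loci$biotype, "pseudogene")
})

test_that("te_gene features become loci while standalone TEs stay separate", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "Chr1\t.\ttransposable_element_gene\t1001\t1500\t.\t+\t.\tID=TG1",
    "Chr1\t.\tmRNA\t1001\t1500\t.\t+\t.\tID=TG1.1;Parent=TG1",
    "Chr1\t.\texon\t1001\t1500\t.\t+\t.\tParent=TG1.1",
    "Chr1\t.\ttransposable_element\t3001\t3400\t.\t-\t.\tID=TE1"), ".gff3")
  ann <- read_annotation(gff)
  expect_equal(ann$loci$biotype, "te_gene")
  expect_equal(nrow(ann$te_features), 1L)
  expect_equal(ann$te_features$start, 3000L)
})

test_that("SAM reading performs CIGAR arithmetic and groups multireads", {
  sam <- write_lines_tmp(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:Chr1\tLN:1000",
    "r1\t0\tChr1\t11\t255\t50M\t*\t0\t0\t*\t*\tNH:i:1",
    "r2\t0\tChr1\t1\t255\t20M100N30M\t*\t0\t0\t*\t*\tNH:i:1",
    "r3\t0\tChr1\t101\t255\t50M\t*\t0\t0\t*\t*\tNH:i:2",
    "r3\t0\tChr1\t501\t255\t50M\t*\t0\t0\t*\t*\tNH:i:2"), ".sam")
  a <- read_alignments(sam)
  r1 <- a[a$read_id == "r1", ]
  expect_equal(c(r1$start, r1$end), c(10L, 60L))
  expect_equal(r1$gaps, "")
  r2 <- a[a$read_id == "r2", ]
  expect_equal(c(r2$start, r2$end), c(0L, 150L))
  expect_equal(r2$gaps, "20-120")
  r3 <- a[a$read_id == "r3", ]
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$n_alignments, c(2L, 2L))
  expect_false(any(r3$is_unique))
})

test_that("reads exceeding max_alignments are skipped with a warning", {
  sam <- write_lines_tmp(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:Chr1\tLN:1000",
    "r1\t0\tChr1\t1\t255\t10M\t*\t0\t0\t*\t*\tNH:i:3",
    "r1\t0\tChr1\t101\t255\t10M\t*\t0\t0\t*\t*\tNH:i:3",
    "r1\t0\tChr1\t201\t255\t10M\t*\t0\t0\t*\t*\tNH:i:3",
    "r2\t0\tChr1\t301\t255\t10M\t*\t0\t0\t*\t*\tNH:i:1"), ".sam")
  expect_warning(a <- read_alignments(sam, max_alignments = 2L),
                 "max_alignments")
  expect_equal(a$read_id, "r2")
})

test_that("csfasta/qual parse, validate ids and lengths, and round-trip", {
  cs <- write_lines_tmp(c("# comment", ">r1", "T0123.", ">r2", "G001"),
                        ".csfasta")
  qu <- write_lines_tmp(c(">r1", "20 20 20 20 20", ">r2", "9 8 7"), ".qual")
  reads <- read_colorspace(cs, qu)
  expect_equal(reads$primer_base, c("T", "G"))
  expect_equal(reads$colors, c("0123.", "001"))
  expect_equal(reads$qualities[[1L]], rep(20L, 5L))

  qu_bad <- write_lines_tmp(c(">r1", "20 20 20 20 20", ">rX", "9 8 7"),
                            ".qual")
  expect_error(read_colorspace(cs, qu_bad), "r2|rX")
  qu_short <- write_lines_tmp(c(">r1", "20 20", ">r2", "9 8 7"), ".qual")
  expect_error(read_colorspace(cs, qu_short), "r1")

  out_cs <- tempfile(); out_qu <- tempfile()
  write_colorspace(reads, out_cs, out_qu)
  back <- read_colorspace(out_cs, out_qu)
  expect_equal(back, reads)

  empty <- read_colorspace(write_lines_tmp(character(0), ".csfasta"),
                           write_lines_tmp(character(0), ".qual"))
  expect_equal(nrow(empty), 0L)
})

test_that("TSV and BED writers round-trip with deterministic order", {
  df <- data.frame(chrom = c("Chr2", "Chr1", "Chr1"),
                   start = c(5L, 100L, 7L), end = c(50L, 200L, 30L))
  p <- tempfile()
  write_table(df, p)
  back <- read_table(p)
  expect_equal(back, df[order(df$chrom, df$start), ], ignore_attr = TRUE)

  b <- tempfile()
  write_regions(df, b)
  bed <- read_regions(b)
  expect_equal(bed, order_df <- df[order(df$chrom, df$start, df$end), ],
               ignore_attr = TRUE)
  # Byte-determinism of the writers.
  p2 <- tempfile(); write_table(df, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("generated annotations and alignments survive write/read cycles", {
  fx <- small_sim()
  ann <- fx$sim$annotation
  gff <- tempfile(fileext = ".gff3")
  write_annotation(ann, gff)
  ann2 <- read_annotation(gff, chrom_lengths = ann$chrom_lengths)
  for (slot in c("loci", "transcripts", "exons")) {
    a <- ann[[slot]][do.call(order, unname(ann[[slot]])), ]
    b <- ann2[[slot]][do.call(order, unname(ann2[[slot]])), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b[, names(a)])
  }

  sam <- tempfile(fileext = ".sam")
  write_sam(fx$r1$alignments, ann$chrom_lengths, sam)
  back <- read_alignments(sam)
  orig <- fx$r1$alignments[order(fx$r1$alignments$read_id,
                                 fx$r1$alignments$chrom,
                                 fx$r1$alignments$start), ]
  rownames(orig) <- NULL
  expect_equal(back, orig[, names(back)])

  hp <- tempfile(fileext = ".tsv")
  write_hits(fx$h1, hp)
  h <- read_hits(hp)
  ho <- fx$h1[order(fx$h1$read_id, fx$h1$chrom, fx$h1$start), ]
  rownames(ho) <- NULL
  expect_equal(h, ho[, names(h)])
})
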