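test_that("hit assignment separates unambiguous, ambiguous and unassigned", {
  ann <- toy_annotation()
  hits <- make_hits(
    start = c(5300L, 5800L, 1250L, 1100L),
    end   = c(5350L, 5850L, 1300L, 1150L))
  # 1: INNER exon (also inside OUTER exon) -> ambiguous {INNER, OUTER}
  # 2: OUTER exon only -> unambiguous OUTER
  # 3: GA intron, no exon overlap -> unassigned
  # 4: GA exon -> unambiguous GA
  a <- assign_hits(hits, ann)
  expect_setequal(a$ambiguous$locus_id[a$ambiguous$hit == 1L],
                  c("INNER", "OUTER"))
  expect_equal(a$unambiguous$locus_id[a$unambiguous$hit == 2L], "OUTER")
  expect_true(3L %in% a$unassigned)
  expect_equal(a$unambiguous$locus_id[a$unambiguous$hit == 4L], "GA")

  # A gapped hit spanning GA's intron matches GA via the gap.
  spliced <- make_hits(1150L, 1450L, gaps = "1200-1400")
  asp <- assign_hits(spliced, ann)
  expect_equal(asp$unambiguous$locus_id, "GA")

  # A hit shared by two isoforms of one locus stays unambiguous and counts
  # once toward the locus.
  iso_ann <- genome_annotation(
    loci = data.frame(locus_id = "L", chrom = "Chr1", start = 0L,
                      end = 1000L, strand = "+", biotype = "gene"),
    transcripts = data.frame(transcript_id = c("L.1", "L.2"), locus_id = "L",
                             chrom = "Chr1", start = 0L, end = 1000L,
                             strand = "+"),
    exons = data.frame(transcript_id = c("L.1", "L.2"), chrom = "Chr1",
                       start = 0L, end = 1000L),
    chrom_lengths = c(Chr1 = 2000L))
  ai <- assign_hits(make_hits(100L, 150L, weight = 0.8), iso_ann)
  expect_equal(nrow(ai$unambiguous), 1L)
  expect_equal(ai$unambiguous$weight, 0.8)
  expect_equal(ai$transcript_table$total_weight, c(0.8, 0.8))
})

test_that("transcript filter enforces min hits and a 3'-window anchor", {
  cfg <- quant_config(min_hits = 5, three_prime_window = 250L)
  tab <- data.frame(
    transcript_id = c("t_ok", "t_no3p", "t_low"),
    locus_id = c("A", "B", "C"),
    total_weight = c(6, 6, 4),
    three_prime_weight = c(1, 0, 1))
  expect_equal(filter_transcripts(tab, cfg), "t_ok")
  expect_setequal(filter_transcripts(tab, quant_config(apply_filters = FALSE)),
                  tab$transcript_id)
})

test_that("the 3' window follows transcript orientation through introns", {
  ann <- toy_annotation()
  w3 <- lamquant:::transcript_three_prime_windows(ann, 250L)
  # GA (+, exons (1000,1200) and (1400,1700)): last 250 spliced bases all in
  # the second exon.
  ga <- w3[w3$transcript_id == "GA.1", ]
  expect_equal(c(ga$start, ga$end), c(1450L, 1700L))
  # GB (-): 3' end is at the genomic start.
  gb <- w3[w3$transcript_id == "GB.1", ]
  expect_equal(c(gb$start, gb$end), c(3000L, 3250L))
  # A short window spanning the intron splits in two.
  w3b <- lamquant:::transcript_three_prime_windows(ann, 350L)
  gab <- w3b[w3b$transcript_id == "GA.1", ]
  expect_equal(sum(gab$end - gab$start), 350L)
  expect_equal(nrow(gab), 2L)
})

test_that("ambiguous weight is split by unambiguous totals or equally", {
  amb <- data.frame(hit = c(1L, 1L), locus_id = c("A", "B"),
                    weight = c(1, 1))
  d <- distribute_ambiguous(amb, c(A = 9, B = 1))
  expect_equal(d$share, c(0.9, 0.1))
  d0 <- distribute_ambiguous(amb, c(A = 0, B = 0))
  expect_equal(d0$share, c(0.5, 0.5))
  d1 <- distribute_ambiguous(amb[0L, ], c(A = 1))
  expect_equal(nrow(d1), 0L)
})

test_that("a nested silent locus never steals the inner locus' expression", {
  ann <- toy_annotation()
  # 10 hits on INNER (one at its 3' terminus), none unambiguous: every hit
  # also lies inside OUTER's single exon.
  hits <- make_hits(seq(5200L, 5560L, by = 40L), seq(5240L, 5600L, by = 40L))
  q <- quantify(hits, ann)
  expect_equal(q$expression[q$locus_id == "INNER"], 10)
  expect_false(q$expressed[q$locus_id == "OUTER"])
  expect_equal(q$expression[q$locus_id == "OUTER"], 0)
  expect_true(q$expressed[q$locus_id == "INNER"])
  # Brute-force agreement on the same fixture.
  bf <- lamquant:::bf_quantify(hits, ann)
  expect_equal(q$expression, bf$expression, tolerance = 1e-9)
  expect_equal(q$expressed, bf$expressed)

  # Single-step behaviour for contrast: without the filters OUTER receives
  # half of every hit (no unambiguous anchors anywhere).
  q1 <- quantify(hits, ann, quant_config(apply_filters = FALSE))
  expect_equal(q1$expression[q1$locus_id == "OUTER"], 5)
  expect_equal(q1$expression[q1$locus_id == "INNER"], 5)
})

test_that("paralog ambiguity follows unambiguous anchor mass", {
  ann <- genome_annotation(
    loci = data.frame(locus_id = c("P1", "P2"), chrom = "Chr1",
                      start = c(0L, 5000L), end = c(1000L, 6000L),
                      strand = "+", biotype = "gene"),
    transcripts = data.frame(transcript_id = c("P1.1", "P2.1"),
                             locus_id = c("P1", "P2"), chrom = "Chr1",
                             start = c(0L, 5000L), end = c(1000L, 6000L),
                             strand = "+"),
    exons = data.frame(transcript_id = c("P1.1", "P2.1"), chrom = "Chr1",
                       start = c(0L, 5000L), end = c(1000L, 6000L)),
    chrom_lengths = c(Chr1 = 10000L))
  # 3 unique anchors on P1 (one at the 3' end), none on P2; 6 multireads
  # hitting both paralogs with weight split 0.5/0.5 upstream.
  anchors <- make_hits(c(100L, 400L, 900L), c(150L, 450L, 950L),
                       read_id = paste0("u", 1:3))
  multis <- rbind(
    make_hits(rep(c(200L, 300L, 500L), each = 1L),
              rep(c(250L, 350L, 550L), each = 1L),
              read_id = paste0("m", 1:3), n_alignments = 2L, weight = 0.5),
    make_hits(c(5200L, 5300L, 5500L), c(5250L, 5350L, 5550L),
              read_id = paste0("m", 1:3), n_alignments = 2L, weight = 0.5))
  q <- quantify(rbind(anchors, multis), ann, quant_config(min_hits = 3))
  # P2 has no 3'-window hit: filtered in step 1, so each multiread's P1
  # alignment (weight 0.5) lands on P1 and its P2 alignment is dropped.
  expect_equal(q$expression[q$locus_id == "P1"], 3 + 3 * 0.5)
  expect_false(q$expressed[q$locus_id == "P2"])
  # Hand-enumerated check via the brute-force path.
  bf <- lamquant:::bf_quantify(rbind(anchors, multis), ann, min_hits = 3)
  expect_equal(q$expression, bf$expression, tolerance = 1e-9)
})

test_that("quantify conserves hit mass and matches brute force on fixtures", {
  fx <- small_sim()
  q <- quantify(fx$h1, fx$sim$annotation)
  m <- attr(q, "mass")
  expect_equal(m$total,
               m$unassigned + m$step1_filtered + m$refilter_dropped +
                 m$assigned,
               tolerance = 1e-6 * max(1, m$total))
  bf <- lamquant:::bf_quantify(fx$h1, fx$sim$annotation)
  expect_equal(q$expression, bf$expression, tolerance = 1e-9)
  expect_equal(q$expressed, bf$expressed)
  expect_equal(q$n_transcripts_surviving, bf$n_transcripts_surviving)

  # Expressed loci always reach the min-hits bar.
  expect_true(all(q$expression[q$expressed] >= 5))
  expect_error(quantify(fx$h1, genome_annotation(
    fx$sim$annotation$loci[0L, ], fx$sim$annotation$transcripts[0L, ],
    fx$sim$annotation$exons[0L, ],
    chrom_lengths = fx$sim$annotation$chrom_lengths)), "locus|empty")
})

test_that("raising min_hits never increases the expressed count", {
  fx <- small_sim()
  prev <- Inf
  for (mh in c(1, 5, 10, 25, 50)) {
    q <- quantify(fx$h1, fx$sim$annotation, quant_config(min_hits = mh))
    n <- sum(q$expressed)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("log transform and expression matrices behave as documented", {
  expect_equal(log_transform(c(0, 1, 7)), c(0, 1, 3))
  r1 <- data.frame(locus_id = c("A", "B"), expression = c(10, 0),
                   expressed = c(TRUE, FALSE), n_transcripts_surviving = c(1L, 0L))
  r2 <- data.frame(locus_id = c("A", "B"), expression = c(0, 8),
                   expressed = c(FALSE, TRUE), n_transcripts_surviving = c(0L, 1L))
  m <- build_matrix(list(cc1 = r1, cc2 = r2))
  expect_equal(dim(m$expression), c(2L, 2L))
  expect_equal(unname(m$expressed_any), c(TRUE, TRUE))
  both <- build_matrix(list(a = r1, b = r1))
  expect_equal(unname(both$expressed["A", ]), c(TRUE, TRUE))
  empty <- build_matrix(list())
  expect_equal(nrow(empty$expression), 0L)
  expect_error(build_matrix(list(r1, r2[1L, ])), "different")
})
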