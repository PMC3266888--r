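test_that("unique coverage counts only unique reads over non-gap bases", {
  cl <- c(Chr1 = 1000L)
  aln <- make_hits(c(100L, 105L, 300L), c(150L, 155L, 400L),
                   read_id = c("u1", "u2", "m1"),
                   n_alignments = c(1L, 1L, 2L))[, 1:7]
  cov <- build_unique_coverage(aln, cl)
  v <- unclass(cov)$Chr1
  expect_equal(sum(v), 50L + 50L)
  expect_equal(unique(v[106:150]), 2L)          # overlap depth 2
  expect_equal(sum(v[300:401]), 0L)             # multi-mapped contributes 0

  gapped <- make_hits(500L, 700L, gaps = "550-650", read_id = "ug")[, 1:7]
  covg <- build_unique_coverage(gapped, cl)
  expect_equal(sum(unclass(covg)$Chr1[551:650]), 0L)  # gap bases excluded
  expect_equal(sum(unclass(covg)$Chr1), 100L)

  expect_error(build_unique_coverage(make_hits(900L, 1100L)[, 1:7], cl),
               "bounds")
})

test_that("junction index counts unique spanning reads per gap", {
  aln <- rbind(
    make_hits(100L, 400L, gaps = "150-250;300-350", read_id = "u1")[, 1:7],
    make_hits(120L, 270L, gaps = "150-250", read_id = "u2")[, 1:7],
    make_hits(120L, 270L, gaps = "150-250", read_id = "m1",
              n_alignments = 2L)[, 1:7])
  jx <- build_junction_index(aln)
  expect_equal(unname(unclass(jx)["Chr1:150-250"]), 2L)
  expect_equal(unname(unclass(jx)["Chr1:300-350"]), 1L)
  expect_false("Chr1:999-1000" %in% names(unclass(jx)))
})

test_that("alignment scores follow the windowed-coverage / gap-support rules", {
  cl <- c(Chr1 = 1000L)
  # Unique depth 1 across (200,250), zero elsewhere.
  base <- make_hits(200L, 250L, read_id = "u1")[, 1:7]
  cov <- build_unique_coverage(base, cl)
  jx <- build_junction_index(base)
  cfg <- weighting_config(allocation_distance = 100L)

  a <- list(chrom = "Chr1", start = 200L, end = 250L, gaps = "")
  expect_equal(score_alignment(a, cov, jx, cfg), 50)

  # Toy track with depth 2 at positions 90..99 and alignment (100,150):
  # the d=100 window is [0, 250) and the brute-force per-base sum is 20.
  toy <- make_hits(c(90L, 90L), c(100L, 100L), read_id = c("a", "b"))[, 1:7]
  cov2 <- build_unique_coverage(toy, cl)
  a2 <- list(chrom = "Chr1", start = 100L, end = 150L, gaps = "")
  bf <- lamquant:::bf_score(3L, rbind(toy, data.frame(
    read_id = "q", chrom = "Chr1", start = 100L, end = 150L, gaps = "",
    n_alignments = 2L, is_unique = FALSE)),
    lamquant:::bf_unique_coverage(toy, cl), 100L)
  expect_equal(bf, 20L)
  expect_equal(score_alignment(a2, cov2, jx, cfg), 20)

  # Gapped alignments score junction support; unmatched gaps score 0;
  # multi-gap alignments take the minimum.
  jr <- rbind(make_hits(100L, 300L, gaps = "150-250",
                        read_id = paste0("j", 1:7))[, 1:7])
  jx2 <- build_junction_index(jr)
  g1 <- list(chrom = "Chr1", start = 120L, end = 280L, gaps = "150-250")
  expect_equal(score_alignment(g1, cov, jx2, cfg), 7)
  g2 <- list(chrom = "Chr1", start = 120L, end = 280L, gaps = "151-250")
  expect_equal(score_alignment(g2, cov, jx2, cfg), 0)
  g3 <- list(chrom = "Chr1", start = 100L, end = 500L,
             gaps = "150-250;400-450")
  expect_equal(score_alignment(g3, cov, jx2, cfg), 0)
})

test_that("read groups weight by score share and drop zero-total groups", {
  cl <- c(Chr1 = 2000L)
  # Unique coverage: 30 bases of depth 1 under candidate 1, 10 under
  # candidate 2 (d = 0 isolates the alignment span).
  support <- rbind(
    make_hits(100L, 130L, read_id = "u1")[, 1:7],
    make_hits(500L, 510L, read_id = "u2")[, 1:7])
  cov <- build_unique_coverage(support, cl)
  jx <- build_junction_index(support)
  cfg <- weighting_config(allocation_distance = 0L)

  grp <- make_hits(c(100L, 500L), c(130L, 510L),
                   read_id = "m", n_alignments = 2L)
  w <- weight_read_group(grp[, 1:7], cov, jx, cfg)
  expect_equal(w$score, c(30, 10))
  expect_equal(w$weight, c(0.75, 0.25))

  # All scores zero: the whole group is discarded.
  far <- make_hits(c(1500L, 1700L), c(1550L, 1750L),
                   read_id = "z", n_alignments = 2L)
  expect_equal(nrow(weight_read_group(far[, 1:7], cov, jx, cfg)), 0L)

  # Ungapped (score > 0) + gapped (unsupported): weights 1 and 0.
  mix <- rbind(
    make_hits(100L, 130L, read_id = "x", n_alignments = 2L),
    make_hits(900L, 1100L, gaps = "950-1050", read_id = "x",
              n_alignments = 2L))
  wm <- weight_read_group(mix[, 1:7], cov, jx, cfg)
  expect_equal(wm$weight, c(1, 0))

  # A unique read yields weight 1 even with zero coverage anywhere near it.
  solo <- make_hits(1800L, 1850L, read_id = "s")
  ws <- weight_read_group(solo[, 1:7], cov, jx, cfg)
  expect_equal(ws$weight, 1)

  expect_error(weight_read_group(rbind(solo, make_hits(1L, 5L,
    read_id = "other"))[, 1:7], cov, jx, cfg), "mixed")
})

test_that("weights conserve read mass and match the per-base oracle", {
  for (seed in 1:12) {
    aln <- random_alignment_set(seed)
    cl <- c(chrT = 1000L)
    fast <- weight_alignments(aln, chrom_lengths = cl)
    bf <- lamquant:::bf_weight_alignments(aln, cl)
    ford <- fast[order(fast$read_id, fast$start, fast$gaps), ]
    bord <- bf[order(bf$read_id, bf$start, bf$gaps), ]
    rownames(ford) <- rownames(bord) <- NULL
    expect_identical(ford$weight, bord$weight)
    # Conservation: weights of every retained read sum to 1.
    per_read <- tapply(fast$weight, fast$read_id, sum)
    expect_true(all(abs(per_read - 1) < 1e-9))
  }
})

test_that("added unique coverage under an alignment never lowers its weight", {
  cl <- c(Chr1 = 2000L)
  cfg <- weighting_config(allocation_distance = 50L)
  grp <- make_hits(c(100L, 800L), c(150L, 850L), read_id = "m",
                   n_alignments = 2L)[, 1:7]
  support <- make_hits(c(100L, 800L), c(150L, 850L),
                       read_id = c("u1", "u2"))[, 1:7]
  prev <- -Inf
  for (extra in 0:4) {
    boost <- if (extra > 0)
      make_hits(rep(100L, extra), rep(150L, extra),
                read_id = paste0("b", seq_len(extra)))[, 1:7]
    aln <- rbind(support, boost, grp)
    w <- weight_alignments(aln, chrom_lengths = cl, cfg = cfg)
    w1 <- w$weight[w$read_id == "m" & w$start == 100L]
    expect_gte(w1, prev)
    prev <- w1
  }
  expect_gt(prev, 0.5)
})

test_that("fractional hit totals are preserved, never rounded per read", {
  fx <- small_sim()
  tot <- sum(fx$h1$weight)
  expect_equal(tot, length(unique(fx$h1$read_id)))
  expect_true(any(fx$h1$weight %% 1 != 0))
})
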