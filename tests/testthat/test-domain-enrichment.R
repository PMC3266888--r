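chain_h <- function() domain_hierarchy(
  data.frame(parent = c("a", "b"), child = c("b", "c")))

test_that("lowest-term reduction removes ancestors and is idempotent", {
  h <- chain_h()
  expect_equal(reduce_to_lowest_terms(c("a", "b"), h), "b")
  expect_equal(reduce_to_lowest_terms(c("t1", "t2"), h), c("t1", "t2"))
  expect_equal(reduce_to_lowest_terms(c("a", "b", "c"), h), "c")
  once <- reduce_to_lowest_terms(c("a", "c", "x"), h)
  expect_equal(reduce_to_lowest_terms(once, h), once)
  expect_error(domain_hierarchy(data.frame(parent = c("a", "b"),
                                           child = c("b", "a"))), "cycle")
})

test_that("gene combinations are canonical sets with unknown fallback", {
  h <- chain_h()
  ann <- data.frame(gene = c("g1", "g1", "g2", "g3", "g3"),
                    term = c("a", "c", "b", "t2", "t1"))
  combos <- domain_combinations(c("g1", "g2", "g3", "g4"), ann, h)
  expect_equal(unname(combos["g1"]), "c")
  expect_equal(unname(combos["g2"]), "b")
  expect_equal(unname(combos["g3"]), "t1|t2")  # order-insensitive
  expect_equal(unname(combos["g4"]), "unknown")
})

test_that("one-sided Fisher p equals the hypergeometric tail", {
  # 5-of-5 vs 0-of-5: single most extreme table.
  expect_equal(fisher_one_sided(5, 0, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(lamquant:::bf_fisher_tail(5, 0, 5, 5), 1 / 252,
               tolerance = 1e-15)
  # a = 0 is the weakest possible evidence.
  expect_equal(fisher_one_sided(0, 3, 10, 10), 1.0)
  # Equal proportions on a small table are far from significant.
  expect_gte(fisher_one_sided(2, 2, 4, 4), 0.5)

  # Exhaustive agreement with the binomial-coefficient oracle on a grid of
  # smaller tables (the full <= 40 sweep runs in the acceptance suite).
  for (n_test in c(3L, 5L, 8L)) {
    for (n_ref in c(4L, 7L)) {
      for (a in 0:n_test) {
        for (b in 0:n_ref) {
          expect_equal(fisher_one_sided(a, b, n_test, n_ref),
                       lamquant:::bf_fisher_tail(a, b, n_test, n_ref),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("p is monotone non-increasing in a at fixed margins", {
  for (m in c(4L, 9L)) {
    p <- vapply(0:m, function(a) fisher_one_sided(a, m - a, 12L, 15L),
                numeric(1L))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("enrichment testing flags over-represented combinations", {
  h <- domain_hierarchy(data.frame(parent = character(0),
                                   child = character(0)))
  # 10/100 test genes vs 1/1000 reference genes carry domain X.
  test_genes <- sprintf("t%03d", 1:100)
  ref_genes <- sprintf("r%04d", 1:1000)
  ann <- data.frame(
    gene = c(test_genes[1:10], ref_genes[1]),
    term = "X")
  res <- test_enrichment(test_genes, ref_genes, ann, h)
  x <- res[res$combination == "X", ]
  expect_true(x$significant)
  expect_equal(x$p, fisher_one_sided(10, 1, 100, 1000))
  expect_equal(x$enrichment, (10 / 100) / (1 / 1000))

  # Zero reference occurrences: enrichment value is the occurrence count.
  ann2 <- data.frame(gene = test_genes[1:12], term = "Y")
  res2 <- test_enrichment(test_genes, ref_genes, ann2, h)
  y <- res2[res2$combination == "Y", ]
  expect_true(y$b_zero)
  expect_equal(y$enrichment, 12)

  # Identical composition: nothing significant.
  ann3 <- data.frame(gene = c(test_genes[1:10], ref_genes[1:100]),
                     term = "Z")
  res3 <- test_enrichment(test_genes, ref_genes, ann3, h)
  expect_false(any(res3$significant))

  expect_error(test_enrichment(c("g1", "g2"), c("g2", "g3"),
                               ann, h), "disjoint")
})

test_that("BH mode is at least as stringent as raw p thresholds", {
  h <- domain_hierarchy(data.frame(parent = character(0),
                                   child = character(0)))
  set.seed(3)
  test_genes <- sprintf("t%03d", 1:60)
  ref_genes <- sprintf("r%03d", 1:200)
  ann <- data.frame(
    gene = c(test_genes, ref_genes),
    term = sample(LETTERS[1:8], 260L, replace = TRUE))
  raw <- test_enrichment(test_genes, ref_genes, ann, h)
  bh <- test_enrichment(test_genes, ref_genes, ann, h, bh = TRUE)
  expect_true(all(bh$p_adj >= bh$p - 1e-12))
  expect_lte(sum(bh$significant), sum(raw$significant))
})

test_that("universe variants implement the probed/all-genes set algebra", {
  rnaseq <- c("g1", "g2", "g3", "g4", "g5")
  array <- c("g3", "g4", "g6")
  probed <- c("g1", "g3", "g4", "g6", "g7")
  v <- universe_variants(rnaseq, array, probed)
  expect_setequal(v$all_genes$test, c("g1", "g2", "g5"))
  expect_setequal(v$all_genes$ref, array)
  expect_setequal(v$probed_only$test, "g1")
  expect_setequal(v$probed_only$ref, c("g3", "g4", "g6"))
  expect_length(intersect(v$probed_only$test, v$probed_only$ref), 0L)

  v_empty <- universe_variants(rnaseq, array, character(0))
  expect_length(v_empty$probed_only$test, 0L)
  v_all <- universe_variants(rnaseq, array, union(rnaseq, array))
  expect_setequal(v_all$probed_only$test, v_all$all_genes$test)
  expect_setequal(v_all$probed_only$ref, v_all$all_genes$ref)
})

test_that("annotation and hierarchy TSV readers accept optional headers", {
  p1 <- tempfile(); writeLines(c("gene\tterm", "g1\tA", "g2\tB"), p1)
  a <- read_domain_annotation(p1)
  expect_equal(a$gene, c("g1", "g2"))
  p2 <- tempfile(); writeLines(c("A\tB", "B\tC"), p2)
  h <- read_hierarchy(p2)
  expect_equal(reduce_to_lowest_terms(c("A", "C"), h), "C")
})
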