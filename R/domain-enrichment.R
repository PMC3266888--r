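# Enrichment of protein-domain (InterPro) combinations between gene sets.
#
# InterPro terms are hierarchically linked: a gene annotated with a term is
# implicitly annotated with all its ancestors, which would dilute
# statistical power if every level were tested. Genes are therefore
# characterised by their lowest (most specific) terms only, and the exact
# set of lowest terms of a gene -- its domain combination -- is the unit of
# testing. Genes without annotation carry the reserved combination
# "unknown". Each combination occurring in the test set is tested for
# over-representation against a disjoint reference set with a one-sided
# Fisher exact test; by default no multiple-testing correction is applied
# (redundancy in the InterPro annotation makes correction overly
# stringent), with Benjamini-Hochberg available as the high-stringency
# variant.

#' Build a domain hierarchy from parent/child edges
#'
#' @param edges data.frame with columns `parent`, `child` (term ids); must
#'   be acyclic.
#' @return Object of class `DomainHierarchy` wrapping the directed graph.
#' @export
domain_hierarchy <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("parent", "child")], directed = TRUE)
    if (!igraph::is_dag(g)) stop("domain hierarchy contains a cycle")
  }
  structure(list(graph = g), class = "DomainHierarchy")
}

#' Read a parent/child term hierarchy from TSV
#'
#' Two-column tab-separated file (`parent`, `child`), with or without a
#' header line.
#'
#' @param path TSV file.
#' @return A `DomainHierarchy`.
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("parent", "child"))
  if (nrow(df) && identical(tolower(df[1L, 1L]), "parent"))
    df <- df[-1L, , drop = FALSE]
  domain_hierarchy(df)
}

#' Read a gene-to-term annotation table from TSV
#'
#' Two-column tab-separated file (`gene`, `term`), one row per gene/term
#' pair, with or without a header line.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene`, `term`.
#' @export
read_domain_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("gene", "term"))
  if (nrow(df) && identical(tolower(df[1L, 1L]), "gene"))
    df <- df[-1L, , drop = FALSE]
  df
}

#' Reduce a term set to its lowest terms
#'
#' Removes every term that is a (transitive) ancestor of another member of
#' the set, leaving only the most specific characterisation. Idempotent.
#'
#' @param terms character vector of term ids.
#' @param h a [domain_hierarchy()].
#' @return Character vector of the remaining terms, sorted.
#' @export
reduce_to_lowest_terms <- function(terms, h) {
  terms <- unique(terms)
  known <- terms[terms %in% igraph::V(h$graph)$name]
  if (length(known) > 1L) {
    drop <- vapply(known, function(t) {
      desc <- names(igraph::subcomponent(h$graph, t, mode = "out"))
      any(setdiff(desc, t) %in% known)
    }, logical(1L))
    terms <- setdiff(terms, known[drop])
  }
  sort(terms)
}

#' Domain combination of each gene
#'
#' The combination of a gene is the canonical (sorted, duplicate-free) set
#' of its lowest terms, encoded as a single `|`-separated string; genes
#' without any annotated term receive the reserved combination `"unknown"`.
#'
#' @param genes character vector of gene ids.
#' @param annotation gene/term table as from [read_domain_annotation()].
#' @param h a [domain_hierarchy()].
#' @return Named character vector: combination per gene.
#' @export
domain_combinations <- function(genes, annotation, h) {
  ann <- annotation[annotation$gene %in% genes, , drop = FALSE]
  by_gene <- split(ann$term, ann$gene)
  combos <- vapply(by_gene, function(t)
    paste(reduce_to_lowest_terms(t, h), collapse = "|"), character(1L))
  out <- stats::setNames(rep("unknown", length(genes)), genes)
  out[names(combos)] <- combos
  out
}

#' One-sided Fisher exact test for over-representation
#'
#' For a combination occurring `a` times among `n_test` test genes and `b`
#' times among `n_ref` reference genes, computes the upper hypergeometric
#' tail `P(X >= a)` for the 2x2 table `[[a, n_test - a], [b, n_ref - b]]` --
#' the one-sided Fisher exact p-value for over-representation in the test
#' set.
#'
#' @param a,b occurrence counts in the test and reference set.
#' @param n_test,n_ref set sizes.
#' @return p-value in `(0, 1]`.
#' @export
fisher_one_sided <- function(a, b, n_test, n_ref) {
  stopifnot(a >= 0, b >= 0, a <= n_test, b <= n_ref)
  stats::phyper(a - 1, a + b, n_test + n_ref - a - b, n_test,
                lower.tail = FALSE)
}

#' Test enrichment of domain combinations between two gene sets
#'
#' Every distinct combination occurring in the test set is tested with
#' [fisher_one_sided()] against the (disjoint) reference set. The
#' enrichment ratio is `(a / n_test) / (b / n_ref)`; when the combination
#' does not occur in the reference set (`b = 0`, infinite ratio) the
#' reported enrichment value is the occurrence count `a` itself. By default
#' combinations with `p < alpha` are flagged significant without
#' multiple-testing correction; `bh = TRUE` switches to the high-stringency
#' variant flagging Benjamini-Hochberg FDR `< alpha`.
#'
#' @param test_genes,ref_genes disjoint character vectors of gene ids.
#' @param annotation gene/term table.
#' @param h a [domain_hierarchy()].
#' @param alpha significance cutoff (default 0.05).
#' @param bh apply Benjamini-Hochberg correction before thresholding.
#' @return data.frame sorted by p-value: `combination`, `a`, `b`, `n_test`,
#'   `n_ref`, `p` (and `p_adj` when `bh`), `enrichment`, `b_zero`,
#'   `significant`.
#' @export
test_enrichment <- function(test_genes, ref_genes, annotation, h,
                            alpha = 0.05, bh = FALSE) {
  if (length(intersect(test_genes, ref_genes)))
    stop("test and reference gene sets must be disjoint")
  test_combo <- domain_combinations(unique(test_genes), annotation, h)
  ref_combo <- domain_combinations(unique(ref_genes), annotation, h)
  n_test <- length(test_combo); n_ref <- length(ref_combo)
  combos <- sort(unique(test_combo))
  a <- vapply(combos, function(cb) sum(test_combo == cb), numeric(1L))
  b <- vapply(combos, function(cb) sum(ref_combo == cb), numeric(1L))
  p <- mapply(fisher_one_sided, a, b,
              MoreArgs = list(n_test = n_test, n_ref = n_ref))
  b_zero <- b == 0
  enrichment <- ifelse(b_zero, a, (a / n_test) / (b / n_ref))
  out <- data.frame(combination = combos, a = as.integer(a),
                    b = as.integer(b), n_test = n_test, n_ref = n_ref,
                    p = p, enrichment = enrichment, b_zero = b_zero)
  if (bh) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out <- out[order(out$p, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test/reference pairs separating sensitivity from genome coverage
#'
#' Detecting more genes by sequencing than by microarray mixes two effects:
#' higher sensitivity on the genes the array can see, and coverage of genes
#' with no probeset at all. Two test/reference pairs separate them. Variant
#' `probed_only` restricts both sets to genes with an array probeset
#' (sensitivity effect); variant `all_genes` uses all genes (adds the
#' coverage effect). In both, the test set holds the sequencing-specific
#' genes (expressed in RNA-seq but not on the array) and the reference set
#' the array-expressed genes, so the pair is disjoint as required by
#' [test_enrichment()].
#'
#' @param expressed_rnaseq,expressed_array character vectors of expressed
#'   gene ids in the two platforms.
#' @param probed_genes genes with a probeset on the array.
#' @return List of two lists (`probed_only`, `all_genes`), each with `test`
#'   and `ref` gene vectors.
#' @export
universe_variants <- function(expressed_rnaseq, expressed_array,
                              probed_genes) {
  test_all <- setdiff(expressed_rnaseq, expressed_array)
  list(
    probed_only = list(test = intersect(test_all, probed_genes),
                       ref = intersect(expressed_array, probed_genes)),
    all_genes = list(test = test_all, ref = expressed_array)
  )
}
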