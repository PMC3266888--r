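---
title: "Quantifying 3'-biased low-input RNA-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3'-biased low-input RNA-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamquant)
```

## The data this package is built for

Transcriptome profiling of rare cell types — for instance single cell types
laser-microdissected out of fixed plant tissue — starts from well under a
nanogram of total RNA. Getting from there to a sequencing library requires
oligo-dT–primed cDNA synthesis and heavy linear amplification, and the
resulting short-read data differ from bulk RNA-seq in three ways that break
standard quantification assumptions:

* **3' bias.** Because cDNA synthesis is primed at the poly(A) tail and
  fragments are short, coverage piles up near transcript 3' ends instead of
  being uniform along the transcript. Length-normalised measures (RPKM-style)
  systematically underestimate long transcripts; counting hits per locus does
  not.
* **Multi-mapped reads.** Allowing up to ten alignments per read keeps reads
  from duplicated gene families in play, but a read counted once per
  alignment overestimates expression.
* **Overlapping annotation.** Hits falling where loci overlap cannot be
  attributed by position alone; with biased coverage, a naive assignment
  invents expression for silent enclosing loci.

`lamquant` implements a quantification and QC pipeline designed around these
three properties, plus the surrounding machinery: genomic classification of
hits, replicate-concordance metrics, protein-domain enrichment between gene
sets, SOLiD colorspace read prefiltering for de novo assembly, and a seeded
synthetic-data generator that reproduces all the constructions above with
known ground truth.

## Multi-read weighting

Let a read have $k$ alignments $a_1 \dots a_k$. Each alignment receives a
score $s_i$ from evidence contributed by *uniquely* aligned reads only:

* ungapped alignment: $s_i$ is the summed per-base depth of unique-read
  coverage over the alignment extended by the **allocation distance** $d$
  (default 100 bases) on both sides, clipped at chromosome ends;
* gapped (spliced) alignment: $s_i$ is the number of unique reads spanning
  exactly the same gap. An alignment with several gaps takes the minimum
  support over its gaps — the conservative extension of "the same gap" — and
  an unobserved gap scores 0.

The weight is $w_i = s_i / \sum_j s_j$; the weighted alignment is called a
**hit**, so hit counts are fractional and are never rounded per read. If
$\sum_j s_j = 0$ the read is discarded: there is no evidence to place it.
Two boundary rules matter: a uniquely aligned read always yields one hit
with $w = 1$ (its score is never consulted — weighting exists only to
apportion multi-mappers), and a read whose group contains a single candidate
alignment keeps $w = 1$ even at zero score. Scoring is unstranded: the data
are single-end and unstranded, so coverage and junction support aggregate
over both strands.

The windowed-sum reading of "the alignment and its surroundings" includes
the alignment's own span; the window is an interval of length
$\mathrm{len} + 2d$ clipped to the chromosome. Scores are integers, so the
optimised cumulative-sum implementation and the per-base loop oracle agree
exactly, division included.

## Genomic classification

Each hit is assigned to exactly one of five exhaustive categories with its
full weight, in precedence order:

1. `exon_or_junction` — the hit overlaps an annotated exon by at least one
   base (evaluated on its aligned, non-gap blocks), or is spliced;
2. `intron` — overlaps a locus but no exon;
3. `flanking` — lies strictly within 200 bases (configurable) of a locus
   border;
4. `te_outside_loci` — overlaps a standalone transposable element;
5. `intergenic` — isolated from every known feature.

The precedence order is a design choice: a hit gets its most "genic"
explanation, which makes the intergenic category mean *isolated from any
known genomic feature*. Splitting a boundary-spanning hit's weight across
categories would be an alternative; we assign whole hits because the
category totals then partition the hit mass exactly (the partition law is
asserted to 1e-6 relative in the tests).

**Reproducibly sequenced regions** are the bases covered by at least one hit
(any positive weight, no depth minimum) in each of two replicates, over the
hits' aligned blocks; gap bases under splices do not count as sequenced.
Concordance is then reported as the weighted fraction of hits touching those
regions, overall and per category.

## Two-step 3'-anchored quantification

A hit is *compatible* with a transcript when it overlaps one of its exons by
at least one base or one of its gaps exactly matches one of its introns;
purely intronic hits count toward no transcript (the classification table
reports them separately). A hit compatible with transcripts of exactly one
locus is **unambiguous**, otherwise **ambiguous**. Ambiguous hits of weight
$w$ with candidate loci $L_j$ carrying unambiguous totals $u_j$ contribute
$w \cdot u_j / \sum u$ to each candidate, or $w / |\{L_j\}|$ when
$\sum u = 0$. "Number of unambiguous hits" means summed weights throughout,
consistent with fractional hits.

A single assignment pass fails when an expressed locus A lies entirely
inside a silent locus B: all of A's hits look ambiguous, and B either
siphons half of them (no unambiguous hits anywhere) or — if B picked up a
couple of stray unambiguous hits — all of them. The two-step procedure
exploits the library chemistry instead. Because cDNA synthesis is
poly(A)-primed, a truly expressed transcript must have at least one hit in
the last 250 spliced bases of its 3' end (**3' window**; the whole
transcript when shorter), and at least `min_hits = 5` total hit weight to
clear sequencing noise:

* **Step 1** assigns every hit to every compatible transcript (full weight
  in the tallies) and discards transcripts failing either criterion.
* **Step 2** repeats the assignment against the survivors, assigns
  unambiguous hits first, distributes ambiguous hits proportionally, then
  re-filters with the same criteria.

A locus is **expressed** when at least one of its transcripts survives both
passes, and its expression value is the summed contribution of the
*distinct* hits assigned to any surviving transcript (the distinct-hit union
prevents double counting across isoforms). Ambiguous hits whose every
candidate was filtered in step 1 are dropped rather than re-routed — the
minimal-assumption reading — and all dropped mass is tracked, so total
weight = assigned + unassigned + filtered mass to 1e-6 relative.

One detail is left open by the verbal description: which tallies the second
filter pass uses. We tally each transcript with each hit's *step-2
contribution to that transcript's locus* (full weight for unambiguous hits,
the proportional share for ambiguous ones); step 1 deliberately uses full
weights because no distribution exists yet. Whether the 5-hit criterion
counts weighted or integer hits is also unstated in verbal form; we use
weighted totals, which is the only choice consistent with fractional hit
accounting.

For external datasets quantified without thresholds, `quant_config(apply_filters
= FALSE)` turns both criteria off; `expressed` then just means positive
assigned weight.

Expression vectors are compared between replicates on the
$\log_2(x + 1)$ scale over the union of expressed loci, with Pearson or
Spearman correlation.

## Assembled-locus overlap

Loci assembled de novo from intergenic reads are compared between
replicates by an **asymmetric** overlap fraction: bases of the query locus
covered by the union of overlapping target loci, divided by the query
length. Union coverage (not best-single-target) is used because a
fragmented assembly legitimately covers one query locus with several target
loci. Counts of query loci reaching a threshold grid are reported, with
junction-supported targets only or all targets, and `>=` at the threshold
by default (`strict = TRUE` for `>`). Loci with total hit weight below 25
form the low-expression stratum, which reproduces poorly and is reported
separately.

## Domain-combination enrichment

InterPro terms are hierarchical, so a gene annotated with a term implicitly
carries all its ancestors; testing every level would dilute power. Genes
are characterised by their **lowest terms** (every term that is an ancestor
of another member of the gene's term set is removed — an idempotent
reduction), and the exact set of lowest terms forms the gene's **domain
combination**, the unit of testing; unannotated genes carry the reserved
combination `unknown`. Each combination occurring in the test set is tested
for over-representation against a disjoint reference set with a one-sided
Fisher exact test, $p = P(X \ge a)$ under the hypergeometric null. Genes
(not annotations) are the sampling units. No multiple-testing correction is
applied by default — redundancy in the InterPro annotation makes correction
overly stringent — with Benjamini–Hochberg FDR as the high-stringency
option. The enrichment ratio $(a/n_{test})/(b/n_{ref})$ is undefined when
the combination is absent from the reference; the reported value is then
the occurrence count $a$ itself, a plotting convention that keeps such
combinations visible.

Because the test requires disjoint sets, the two "universe" variants that
separate sequencing sensitivity from genome coverage are built as: test =
genes expressed in RNA-seq but not on the array, reference = array-expressed
genes; the `probed_only` variant intersects both with the genes that have an
array probeset (sensitivity effect), the `all_genes` variant uses all genes
(adds the coverage effect).

## Colorspace prefiltering and double encoding

Reads destined for de novo assembly are removed, in order, when: total
per-color quality < 200; any ambiguous color `.`; repetitive; exact
duplicate (first occurrence kept; qualities ignored since assembly cares
about sequence only). The removal ledger balances by construction and the
filter is idempotent. "Repetitive" is read as one adjacent color pair
dominating the read: the most frequent pair accounting for more than 30% of
the `len - 1` overlapping pair positions. This is an interpretation — the
criterion could also count the color positions covered by the repeated pair
— so the alternative is exposed as `rep_mode = "covered"`. Double encoding
is the bijection 0↔A, 1↔C, 2↔G, 3↔T applied per color (primer base dropped),
letting base-space assemblers consume colorspace reads; decode inverts it
exactly.

## The synthetic-fixture generator

`simulate_annotation()` + `simulate_reads()` generate everything the
pipeline consumes with known ground truth, from a single seed (identical
seed, identical bytes). The default configuration — the package's standard
study conditions, used by the tests and the acceptance script — is:

| parameter | default | what it emulates |
|---|---|---|
| genome | 2 × 100 kb | desk-scale stand-in for a plant genome |
| `n_loci` | 30 | 1–3 exons each, random strand, ≥1 kb intergenic gaps |
| nested pair | 1 | expressed locus inside a silent single-exon locus whose 3' end extends 400 b past it |
| paralog family | 1 × 2 loci | byte-identical exonic sequence; reads emitted as 2-alignment multireads, 20% unique anchors |
| true expression | log-normal, meanlog = log 100, sdlog = 1 | wide dynamic range |
| `three_prime_decay` | 0.02 /base | exponential 3'-end placement, mean offset 50 b (0 = uniform) |
| `n_reads` | 10^4 (10^5 for recovery runs) | per replicate |
| `read_length` | 50 | SOLiD-class reads |
| `replicate_noise` | sdlog 0.2 | biological replicate variation |
| `background_fraction` | 0 | see below |
| TEs / novel intervals | 3 / 2 | transcribed features outside loci |

The exponential 3'-end model is an emulation, not a claim about the
amplification chemistry: real coverage shows maxima near 3' termini but was
never parameterised, so the decay rate is exposed as a parameter. Reads are
mapped from spliced to genomic coordinates through the exon structure, so
reads crossing introns become gapped alignments with exactly matching gap
coordinates; SAM is written directly (with `NH` alignment-count tags) so no
aligner is needed. A colorspace rendering uses the true dibase code (color =
XOR of 2-bit base encodings) with per-color qualities, and
`simulate_colorspace_fixture()` plants exactly one violator per filter rule
on demand.

A uniform spurious-alignment background is available
(`background_fraction`) but off by default: on a toy-sized genome even a
small read fraction amounts to an unrealistically dense per-base noise
level — dense enough to drop stray hits into the 3' window of the planted
silent locus, which then legitimately passes the anchoring filter. That
behaviour is faithful (the two-step procedure only mitigates the
nested-locus failure, it cannot survive genuine anchor evidence), but it is
not the construction the fixture exists to plant.

What passing tests on these fixtures does *not* show: robustness to
alignment error, indels and soft-clipping (alignments are emitted, not
computed), to annotation error, to strand-specific artefacts, or to the
amplification chemistry's sequence-dependent biases. The generator's
multinomial read sampling also makes per-locus counts slightly
negatively correlated, which real libraries are not.

## Numerical choices

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only at format boundaries (GFF3/SAM are 1-based
  closed, BED matches the internal convention).
* Scores are integers; weights are IEEE doubles computed as `s / sum(s)` in
  a fixed order, so the optimised and brute-force paths agree exactly.
* Mass-conservation checks use 1e-6 relative tolerance; per-read weight
  sums use 1e-9 absolute.
* "Distance below the flank" is strict; thresholds in the overlap counts
  are `>=` by default.
* Ties in `min` over multi-gap junction support and in `which.max` over
  color pairs resolve to the first element, deterministically.
* Every writer sorts its rows (by id or by chrom/start), so identical
  inputs give byte-identical files; all simulation randomness flows from
  the single seed in the configuration.

## Known limitations

* Isoform-level abundance is out of scope: transcripts are filters and
  assignment targets, expression is per locus.
* The weighting rescues multi-mappers only where unique coverage or unique
  junction support exists nearby; a paralog family with no uniquely
  mappable position keeps none of its reads (all scores zero).
* Hit/transcript compatibility requires exon overlap or an exact gap–intron
  match; near-miss splice gaps (off by one) count as unsupported.
* The nested-locus safeguard fails by design when the outer locus gains
  genuine 3'-window evidence; see the background discussion above.
* `fraction_te` and novel-interval counts are rounded to integers of
  `n_loci`, so very small configurations may contain neither.

## Problem sizes used in the checks

The test suite runs the weighting oracle on 200 random fixtures of ≤ 4
alignments per read over a 1 kb genome, the classification partition on the
default 30-locus / 10^4-read fixture, the recovery checks on 10^5 reads
(biased and unbiased), the Fisher oracle exhaustively on all 2×2 tables
with total ≤ 40, and byte-determinism of every CLI subcommand on a
400-read fixture. The acceptance script re-runs the same study conditions
from scratch under a caller-supplied seed.
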