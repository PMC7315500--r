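---
title: "Methods: miRNA–isoform target prediction and co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA–isoform target prediction and co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`mirisonet` links two layers of post-transcriptional regulation in plants:
miRNA-mediated repression and alternative splicing. This vignette is the
package's account of its methods — the models, the tunable parameters and
their defaults, the synthetic data the tests rest on, and the numerical
conventions a maintainer needs to know.

## 1. Target prediction by penalty scoring

Plant miRNAs pair with their targets with near-perfect complementarity, so
target prediction is a complementarity search under a mispair penalty
score. Each aligned column of a miRNA:target duplex contributes:

| column                      | penalty |
|-----------------------------|---------|
| Watson–Crick pair           | 0       |
| G:U wobble (either strand)  | 0.5     |
| mismatch                    | 1       |
| single-nucleotide bulge (extra target base) | 1 |
| single-nucleotide gap (missing target base) | 1 |

Penalties are **doubled** when the column falls at miRNA positions 2–13
counted from the miRNA 5′ end, reflecting the functional importance of the
5′ region in plant miRNA silencing. At most one bulge *or* gap is permitted
per duplex, and duplexes with total score ≤ 3 (inclusive) are retained.

Conventions the score definition leaves open, fixed here and tested:

* **G:U orientation** — a wobble counts regardless of which strand carries
  the G; wobble pairing is chemically symmetric.
* **Bulge position for doubling** — a bulge column carries no miRNA base;
  it takes the position of the adjacent miRNA base on its 5′ side. A bulge
  flanked by the pairs at miRNA positions 13 and 14 is therefore doubled.
* **Indels are internal** — a bulge or gap at the outermost columns of a
  duplex is equivalent to shifting or resizing the window, so the scanner
  only enumerates indels flanked by paired columns on both sides.
* **Tie-breaking** — per window the minimum-score alignment wins, with the
  gapless alignment preferred at ties; overlapping retained sites of one
  miRNA reduce to the best-scoring one, leftmost at ties.

`find_candidate_sites()` performs the scan exhaustively but vectorised: for
each of the `2m − 2` alignment variants (gapless, every internal bulge,
every internal gap) the scores of all window starts are computed at once
with an indexed penalty lookup and a weighted row sum, giving
`O(L · m · variants)` work with small constants. Exactness — not speed — is
the design goal at this scale; the test suite holds the scanner equal to a
brute-force enumerator on over a thousand random instances.

Region labels (5′UTR / CDS / 3′UTR) come from the GFF3-derived transcript
segmentation; a site straddling a boundary takes the segment of largest
overlap, with ties resolved in favour of the CDS.

## 2. Small-RNA catalogue

Reads are filtered to 18–29 nt (inclusive), N-containing reads dropped, and
identical sequences collapsed with summed counts. Quantification uses TPM;
because mature miRNAs share an effective length, TPM reduces to counts per
million over the per-sample miRNA total — a deliberate reading documented
here because length-normalisation is a no-op for uniform lengths. A miRNA is
"present" in a tissue when any replicate exceeds a TPM threshold
(default 0, exposed as `presence_threshold`). Precursors are TE-related
when their interval shares ≥ 1 bp with a transposable-element interval on
the same chromosome (half-open arithmetic, strand ignored); mature miRNAs
inherit the flag from any flagged precursor.

## 3. Differential expression

Two-group DE uses edgeR's exact negative-binomial test with a common
dispersion and TMM normalisation (composition bias from a handful of
strongly regulated features otherwise inflates fold changes of null
features). The decision rule is FDR < 0.05 (Benjamini–Hochberg) **and**
|log2FC| > 1, both strict — a fold change of exactly 2 is not called. The
fold change is computed on TMM-normalised per-million group means with a
pseudo-count of 1, which keeps it finite and exactly antisymmetric under
group swap. With a singleton group the dispersion cannot be estimated and a
fallback common dispersion of 0.1 is used (with a message).

## 4. Isoform expression and the variability filter

FPKM follows the direct formula
`count / (length/10^3) / (libsize/10^6)` with library sizes taken as column
sums (no external mapping statistics exist downstream of the count matrix).
The network's input filter retains isoforms with mean FPKM > 0.1 and
coefficient of variation > 2, both strict, where mean and C.V. (sample
standard deviation / mean, n − 1 denominator) are computed **across the six
per-tissue mean profiles**, not across raw replicates: the filter selects
tissue-variable isoforms, and replicate-level noise would inflate the C.V.
of uniformly expressed ones. Both choices are arguments.

qPCR support is the 2^−ΔΔCt statistic with a reference gene and a
calibrator sample; the calibrator's relative expression is 1 by
construction.

## 5. Co-expression network

* **Adjacency** — unsigned `|cor|^β` by default, signed
  `((1+cor)/2)^β` optionally; β defaults to 6, the conventional unsigned
  default, and matters mainly through the contrast it induces between
  within- and between-module correlations.
* **TOM** — `TOM_ij = (L_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)` with
  `L_ij` the shared-neighbour sum; the implementation is one matrix product
  plus elementwise operations and is tested against a literal triple-loop
  on an exhaustive grid of 3-node configurations.
* **Module detection** — average-linkage clustering on `1 − TOM`, a
  *static* tree cut at height 0.99 (default), clusters below
  `min_module_size` set to grey, then iterative merging of the module pair
  with the smallest eigengene dissimilarity while it is below 0.5,
  recomputing eigengenes after each merge. This replaces the full dynamic
  hybrid cut (with its PAM-like stages) by its two governing parameters —
  minimum size and merge threshold — which is sufficient for block-structured
  data and keeps the algorithm fully specified here. Surviving modules are
  named from the conventional colour palette in decreasing size order, so
  labels are stable under feature permutation.
* **Eigengene** — first right singular vector of the per-feature
  standardised member matrix, sign-oriented so the mean member correlation
  is positive.
* **Module–trait, kME, hubs** — traits are one-hot tissue indicators;
  r is Pearson correlation of eigengene and indicator with a t-distribution
  p (n − 2 df, checked against a permutation oracle at n = 15); kME is the
  member–eigengene correlation; each module's hubs are its top
  `min(150, module size)` members by own-module kME, ties broken by
  feature id.

The real-data default for `min_module_size` is 600; the synthetic analyses
in this package run at test scale (15–20), which is a data-size choice: the
planted blocks hold tens to hundreds of isoforms, not thousands.

## 6. Integration and divergence statistics

miRNA–target correlations are computed over **tissue means** (miRNA and
mRNA libraries come from different physical samples; tissue is the axis the
two designs share). The six bins partition [−1, 1] exactly as
`[-1,-.75], (-.75,-.25], (-.25,0), [0,.25), [.25,.75), [.75,1]`; 0 belongs
to weak-positive, and each interior boundary belongs to the bin whose
bracket closes on it. Zero-variance profiles are excluded with a message.

The DEMTG test builds the 2×2 table of DE status against
targeted-by-DE-miRNA status over the gene universe and applies a
Yates-corrected χ² (Fisher's exact test available via `method`). GIDDM
detection counts genes with ≥ 2 isoforms assigned to non-grey modules and
flags those occupying ≥ 2 distinct modules. Hub-targeting enrichment
compares targeted proportions between a module's hubs and its non-hub
members, with the module-wide count taken to include the hubs and non-hub
counts derived by subtraction (this avoids double-counting hubs in both
margins; with the table sizes involved the conclusion is insensitive to the
alternative reading). Targeted-vs-untargeted expression pairs the mean FPKM
of targeted and untargeted isoforms within genes that have both, and
summarises across genes with a Wilcoxon signed-rank test; fewer than five
qualifying genes flags the result low-power.

Homolog categories for multi-isoform genes: **I** — isoforms hit different
genes in the other species; **III** — the same gene through different
isoforms; **II** — one identical isoform. Precedence is I > III > II (any
cross-gene pair dominates), making the assignment order-invariant.

## 7. Term enrichment

Over-representation p-values come from the central hypergeometric upper
tail, or — when per-gene bias weights such as transcript lengths are
supplied — from the Wallenius noncentral hypergeometric upper tail with the
term's odds estimated as mean weight inside / outside the term. The
Wallenius pmf is evaluated from its integral representation

```
P(X = k) = C(m1,k) C(m2,n−k) ∫₀¹ (1 − t^(ω/d))^k (1 − t^(1/d))^(n−k) dt,
d = ω(m1 − k) + (m2 − n + k)
```

by adaptive quadrature; tests confirm the pmf sums to 1, collapses to the
central hypergeometric at ω = 1, and matches an exact enumeration of the
sequential weighted draw on small urns. GO-DAG propagation is out of scope:
the term map is taken as already-propagated flat annotation.

## 8. The synthetic-data generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes, with planted ground truth:

* **Design** — six tissues with replicates (default 5 + 2 + 2 + 2 + 2 + 2 =
  15 samples, a replicated-but-unbalanced layout typical of tissue panels).
* **Sequences** — each gene is a segmented transcript (5′UTR, four CDS
  segments, 3′UTR); isoforms beyond the first skip one internal CDS
  segment, so isoforms of a gene share sequence but can differ in whether
  they carry a planted site (exon-skipping is the only structural mechanism
  modelled; alternative starts are collapsed into it).
* **Sites** — planted as the exact reverse complement of a miRNA (score 0)
  or with one requested distortion (G:U, mismatch, bulge, gap), whose
  analytic expected score is recorded in the truth table and equals what
  the scanner computes on the generated sequence.
* **Expression** — module isoforms follow a spike profile (mean 2000 in the
  module's tissue, 5 elsewhere); a background population (default 40% of
  genes) is flat at mean 600. The background matters twice: it is the
  realistic "universally expressed" class the C.V. filter removes, and it
  keeps per-sample library sizes comparable so per-million normalisation
  does not flatten the planted blocks — without it, a transcriptome in
  which *every* gene is tissue-specific makes relative abundances nearly
  uniform. Targeted isoforms get a 4-fold boost (planting the
  higher-expression-of-targeted-isoforms effect). Counts are negative
  binomial (default dispersion 0.05).
* **Repression** — a targeting miRNA's mean profile is the reflection
  (max + min − profile) of its targets' profile, blended with a flat
  profile by `repression_strength` (default 0.9), producing the planted
  negative miRNA–target correlation.
* **Homologs, TE loci** — two pseudo-species best-hit tables plant
  categories I/II/III per multi-isoform gene; a configurable fraction
  (default 0.44) of precursors overlap planted TE intervals.

What the generator does **not** emulate: read-level sampling (FASTQ),
splice-graph realism, correlated gene–gene noise, batch effects, and
sequence composition biases. Passing tests therefore demonstrate that the
pipeline's inference is correct *when its model assumptions hold*, not that
the assumptions hold for any particular real dataset.

Determinism is a contract: the same configuration and seed produce
byte-identical datasets (`withr::with_seed` around the whole generation).

## 9. Degenerate inputs and numerical conventions

* Internal coordinates are uniformly 0-based half-open; GFF3 is converted
  on read, BED kept native. T and U are synonyms; the canonical alphabet is
  ACGU.
* Zero-variance features are an error in `adjacency()` (the filter should
  have removed them) but a logged exclusion in correlation helpers.
* TPM errors on all-zero samples, FPKM on non-positive lengths, naming the
  offender.
* χ² tests use Yates correction by default; degenerate hub tables (module
  no larger than its hub set) are flagged rather than tested.
* All thresholds are strict inequalities; features at exactly the
  mean-FPKM or C.V. boundary are dropped, a literal reading documented
  here.

## 10. Problem sizes

The packaged analyses run at desk scale by choice: the default synthetic
dataset holds 60 genes (~120 isoforms), 20 miRNAs and 15 samples; the
two-block network analysis in the acceptance script uses 500 genes
(1000 isoforms, ~800 of them module-structured) — sizes at which the
exhaustive scanner and dense TOM algebra finish in seconds to a couple of
minutes while exercising every code path at full fidelity.
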