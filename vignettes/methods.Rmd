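---
title: "Reference-based imputation of sparse single-cell ChIP-seq profiles: model and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based imputation of sparse single-cell ChIP-seq profiles: model and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipimpute)
```

## The problem

Single-cell ChIP-seq captures only a small fraction of a cell's true
protein–DNA interaction sites: a typical cell yields a few hundred detected
regions where the underlying profile has tens of thousands. Unlike
single-cell RNA-seq, where the feature universe is the transcriptome,
a chromatin interaction may fall anywhere in the genome — at 5 kb
resolution the human primary assembly alone tiles into more than 600,000
bins (`count_genome_bins(read_chrom_sizes("hg38"), 5000)`). Imputation
therefore cannot lean on a fixed, modest-sized feature set; it needs an
external source of structure. This package takes that structure from bulk
ChIP-seq: a compendium of peak profiles for the same protein target across
many tissues and cell lines.

## The model

All profiles are binarized onto fixed-size, non-overlapping genomic bins
(BED-style 0-based half-open coordinates; bin $k$ covers
$[k b, (k{+}1) b)$ for bin size $b$). A bin is *present* in a profile when
at least one peak overlaps it by at least 1 bp.

For a protein target, the **reference matrix** $RS = (a_{ij})$,
$1 \le i \le n$, $1 \le j \le m$, collects the $n$ bulk experiments for
that target as rows; its $m$ columns are the bins present in at least one
of them. Given one sparse cell $SC$ (a set of $s$ observed bins), the
columns of $RS$ split into

* **training features** $TF$: the columns for bins observed in the cell, and
* **candidate bins** $c_1, \dots, c_P$: every other column.

For each candidate bin $c_g$ an individual random-forest classifier is
trained with $TF$ as the feature matrix and the candidate's column as the
class vector: the model learns which combinations of the cell's bins
predict, across reference experiments, that $c_g$ is present. The trained
forest is then evaluated on an **all-ones probe vector** — a hypothetical
experiment in which every bin the cell observed is present. The resulting
**imputed probability** $\rho_g$ is the probability that $c_g$ is present
*given everything the cell is known to contain*, which is what makes the
ranking cell-specific rather than a frequency lookup. Candidates are
ranked by $\rho$ (ties: reference frequency, then genome position), and
the completed profile is the cell's bins plus the top candidates, filled
to the average bin count of the reference experiments — the footprint of a
typical bulk profile of the same target.

The probability rule is normative: $\rho_g$ is the unweighted mean over
trees of the class-1 fraction in the leaf reached by the probe. The
forests are probability forests (`ranger`) grown with bootstrap samples,
$\lceil\sqrt{s}\rceil$ features per split, nodes grown to purity, and 100
trees by default; the test suite verifies the probability against an
independent brute-force traversal of the stored tree structures. A
candidate whose class vector is constant short-circuits to exactly 0 or 1
without training.

Two design points deserve mention:

* **Per-bin seeding.** Each candidate's forest is seeded by a pure hash of
  (master seed, bin identity), so results are byte-identical regardless of
  the order in which candidates are evaluated, and safe to parallelize.
* **Cell bins outside the reference** carry no reference signal; they are
  excluded from $TF$ but never dropped from the cell's output profile —
  observed data is not discarded.

## Interpretation mode

For a single genomic position of interest, the same classifier is trained
once for the bin containing the position, and instead of only the
probability the model's normalized impurity-decrease feature importances
are reported over the cell's observed bins (permutation importance is
available as an option). Each feature bin is annotated with its nearest
gene by TSS–midpoint distance (ties to the lexicographically first
symbol; distances signed on the gene's strand). An optional
`max_tss_distance` restricts the feature set *before* training to
promoter-proximal bins. When co-expression scores are supplied, the
Pearson correlation between importances and co-expression of feature
genes with the query gene quantifies how biologically coherent the
model's reliance pattern is; duplicate feature genes are aggregated by
summed importance first, and missing gene pairs score 0 (absence of
evidence).

Importances are reported normalized to sum 1 (all zero in degenerate
constant-class cases). The query bin must be a reference column —
outside the reference universe the class vector would be all-zero and no
model exists; a query bin already observed in the cell reports
probability 1 with a flag.

## Validation machinery

* **Per-bin cross-validation** (`crossvalidate_bin`,
  `crossvalidate_reference`): stratified k-fold (default 10) over the
  reference rows, per-fold AUROC and average precision on held-out rows,
  reported as per-fold means with the bin's class balance. Folds reduce to
  the minority-class count when needed; bins with fewer than two minority
  rows are not evaluable. AUROC uses a fixed comparison direction; average
  precision is the step-wise integral (mean precision at the rank of each
  positive), the conservative choice for imbalanced classes.
* **Down-sampling simulations** (`run_simulation`): a bulk row plays the
  role of a full single-cell profile, is down-sampled to a sparse input,
  and the imputation must recover the rest of the origin with the origin
  held out of training (`leave_out_origin`) or its whole biosample held
  out (`leave_out_cell_type`). Input bins are excluded from the evaluation
  universe; negatives are the training reference's columns not in the
  input and not in the origin.
* **Single-cell specificity** (`simulate_specificity`, `specificity`):
  the completed profile is compared by Jaccard index to its origin and to
  the majority-rule consensus (> 50% presence) of the origin's
  same-biosample peers, after removing the input bins from all sets;
  specificity is the difference. The strict-majority consensus is this
  package's definition.
* **Randomization baselines**: `shuffle_reference` permutes each column
  across experiments (bin frequencies preserved, co-occurrence destroyed);
  `randomized_input` replaces the cell by uniformly sampled reference
  bins. Shuffling must collapse cross-validated AUROC to 0.5.
* **Clustering quality**: `davies_bouldin` scores a labelled embedding
  (lower is better); dimensionality reduction itself is left to standard
  libraries.
* **Frequency baseline**: `average_interaction` scores every bin by its
  reference frequency, identically for every cell — the no-learning
  comparator.

## The synthetic benchmark

`synthetic_spec()` / `generate_reference()` plant a fully known structure:
`C` cell types with `E` experiments each; per type `m_sig` signature bins
present with probability `p_signature` in that type's experiments and
`p_background` elsewhere; `m_shared` housekeeping-like bins present
everywhere with `p_signature`; `m_bg` background bins present anywhere
with `p_background`. All entries are independent Bernoulli draws given
these probabilities; all-zero columns are dropped to preserve the
reference-column invariant. The default benchmark (`default_benchmark()`)
uses C = 3, E = 10, 300/200/500 signature/shared/background bins,
p = 0.9/0.05, 5 kb bins, generator seed 1 — 30 experiments over ≤ 1600
bins, with ~505 bins per experiment. These sizes keep a full per-candidate
imputation of one cell at a few seconds and the whole validation suite at
desk scale, while leaving enough planted structure for the recovery
properties to be sharp (leave-out-origin AUROC > 0.9 from 100 input bins;
recall of 25% removed bins above 0.8; a planted perfectly co-occurring
feature tops the importances in ≥ 95% of seeds).

For importance-ranking ground truth, `plant_cooccurrence()` copies one
column onto another (optionally with flip noise). Note that the planted
*feature* should be a background bin: signature columns are collinear with
their 299 siblings, so impurity importance is legitimately diluted across
correlated features — a property of random forests, not a defect of the
test.

### What the generator does and does not emulate

The generator reproduces the *marginal* structure of a bulk compendium —
cell-type signatures, shared housekeeping bins, sparse noise — and that
suffices to validate classification, ranking, calibration, ablations, and
recovery. It deliberately omits two features of real data, and passing
synthetic tests therefore does not certify them:

* **Experiment-individual co-occurrence structure.** Given the cell type,
  bins are independent. The best possible imputation of a held-out
  experiment is therefore the *type consensus*: an origin's private
  Bernoulli noise is unlearnable in principle. On this benchmark the
  single-cell-specificity score — designed for real references, where an
  individual profile's co-occurrence structure is learnable from its own
  observed bins — is consequently near or below zero by construction, and
  the package reports it as such. Observing positive specificity requires
  references whose rows carry individual structure beyond the type label.
* **Small-sample calibration of average precision.** With 30 reference
  rows, stratified 10-fold CV scores held-out sets of ~3 rows, where
  average precision of a random ranking exceeds the class balance by
  ~0.2 — a known small-sample bias of the estimator, vanishing only at
  reference sizes of hundreds of experiments. The AUROC baseline (0.5) is
  unbiased at any size and is the calibration diagnostic to trust at this
  scale.

Origins drawn from this benchmark have ~505 bins, so down-sampling sizes
are meaningful up to ~400; requesting more input bins than an origin has
is an error by contract.

## Numerical choices and degenerate inputs

* Rounding of the average bin count: half-up.
* Ranking ties: imputed probability desc → reference frequency desc →
  (chromosome, bin index) asc; chromosome order is natural
  (chr1…chr22, chrX, chrY, chrM, then others).
* Jaccard of two empty sets is 1; specificity is computed after input-bin
  removal, so it is antisymmetric under swapping origin and consensus.
* Davies–Bouldin with coincident centroids of distinct clusters reports
  `Inf` rather than dividing by zero.
* Chromosome names are normalized to `chr`-prefixed form on input; sex
  chromosomes and chrM are excluded from single-cell count-matrix input by
  default and the same filter should be applied when building the
  reference, to keep feature spaces consistent.
* Serialization of the reference is a versioned plain-text container
  (magic line, header, coordinate block, per-row 0/1 strings) with header
  validation on read; text keeps fixtures portable and diffable.

## Known limitations

* Imputation cost is one forest fit per candidate bin: a full-genome
  reference (tens of thousands of columns) at 100 trees is minutes of CPU
  per cell. Candidate models are independent, so the per-bin seeding makes
  parallel or incremental evaluation safe.
* The binary presence model ignores peak strength; signal-level imputation
  is out of scope.
* Consensus construction (strict majority of peers) and the shuffling
  scheme (per-column permutation) are this package's definitions of
  otherwise under-specified procedures; both are stated here and in the
  function documentation.
* Assembly lift-over, peak calling, and downloading reference compendia
  are out of scope; references are consumed as peak BED files plus a
  metadata table.
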