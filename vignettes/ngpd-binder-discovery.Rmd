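---
title: "Methods: from phage-display deep sequencing to an ensemble SVM binder classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phage-display deep sequencing to an ensemble SVM binder classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngpdbindr)
```

## The problem

Biopanning a random peptide phage-display library (e.g. a 12-mer library)
against an immobilized protein target enriches peptides that bind the
target — but also peptides that bind the solid phase, the blocking agent,
or that simply out-propagate the rest of the library. Deep sequencing the
selection output (next-generation phage display, NGPD) turns each selection
round into a table of peptide read counts, so binders can be identified
statistically against control selections instead of by picking clones.
The peptides found this way are typically too few to be useful on their
own; a classifier trained on them can then screen large candidate pools
*in silico* and discard most non-binders before any wet-lab validation.

`ngpdbindr` implements that whole path: read processing, enrichment
calling, dataset preparation, descriptor encoding, filter feature
selection, and an ensemble of radial-basis-function support vector
machines (RBF-SVMs) whose averaged, Platt-calibrated probabilities score
candidate peptides.

## Enrichment calling

Counts are normalized per sample to parts-per-million (ppm): the count
divided by the sample's total accepted reads, times $10^6$. For each
peptide and each control condition the caller computes

* the enrichment ratio $R = \bar{a}_\text{target} /
  \max(\bar{a}_\text{control}, a_0)$ of mean ppm values, with a
  pseudo-abundance floor $a_0$ (default 1 ppm) because true binders often
  have zero counts in controls, and
* a one-tailed Welch (unequal-variance) $t$-test on the replicate ppm
  vectors, testing target > control.

A peptide is a hit only when $R \ge 2$ and $p \le 0.05$ against **every**
tested control condition (pre-selection library R0, round-1 output R1, the
bead-only arm, and the unrelated-antibody arm). Design choices worth
stating explicitly:

* Raw ppm values enter the test untransformed, and no multiple-testing
  correction is applied: the criterion is a per-peptide screen calibrated
  by the joint requirement across all control arms, not a family-wise
  inference.
* Each control arm is tested separately by default (`control_mode =
  "each"`); a pooled mode exists because pooling replicates across arms is
  a defensible alternative when arms are few. Separate testing is stricter
  and matches the logic "high in the target arm, low in *each* control".
* The Welch statistic handles zero-variance rows explicitly (equal
  constant groups give $t = 0$, $p = 0.5$; a constant excess gives
  $p \to 0$), since integer count data produce such rows routinely. The
  general case is numerically identical to `stats::t.test(...,
  var.equal = FALSE, alternative = "greater")`, which the test suite uses
  as the oracle.

Hits can be grouped for inspection by `cluster_hits()`: each equal-length
peptide is embedded as the concatenation of the BLOSUM62 substitution rows
of its residues ($20L$ dimensions) and average-linkage agglomerative
clustering on Euclidean distances is cut at a chosen number of clusters.
This is a pragmatic profile-similarity grouping, not a motif model.

## Dataset preparation

Redundancy removal follows the greedy incremental convention of CD-HIT:
sequences are visited longest-first (lexicographic tie-break, so the order
is fully deterministic), each joins the first representative it matches at
identity $\ge 0.8$, otherwise it founds a cluster. Identity between
equal-length peptides is the ungapped fraction of matching positions; for
unequal lengths it is the number of identical aligned positions in a
global alignment divided by the shorter length. Promiscuous peptides
recorded against four or more distinct targets in a user-supplied table of
known target-unrelated peptides (TUPs) are flagged and excluded.

Because selections yield few positives and very many negatives, training
uses balanced pairing: `build_sub_datasets()` samples
$k \times n_\text{pos}$ negatives without replacement (seeded), splits
them into $k$ disjoint groups, and pairs each group with the full positive
set — ten balanced sub-datasets by default. How the original negatives
were partitioned is not derivable from the published description, so a
seeded uniform random partition is used and the seed is stored.

## Descriptor encoding (519 dimensions)

Each peptide is encoded as the fixed-order concatenation

| block | dimensions |
|---|---|
| amino acid composition (AAC) | 20 |
| dipeptide composition (DPC) | 400 |
| pseudo amino acid composition (PseAAC, $\lambda = 4$, $\omega = 0.4$) | 24 |
| k-spaced amino acid group pairs (CKSAAGP, $k = 0,1,2$) | 75 |

AAC and DPC are plain frequency vectors (denominators $L$ and $L-1$).
CKSAAGP maps residues to five physicochemical groups (aliphatic, aromatic,
positive-charged, negative-charged, uncharged) and counts ordered group
pairs separated by $k$ residues, dividing by $L-(k+1)$; $k$ up to 2 suits
12-mers. PseAAC is Chou's type-1 construction: three residue property
scales (hydrophobicity, hydrophilicity, side-chain mass) are standardized
to zero mean and unit variance over the 20 residues (population standard
deviation, the convention of the original construction), the correlation
function is the mean squared difference of the standardized properties,
and $\lambda = 4$ correlation tiers are appended with weight
$\omega = 0.4$; all $20+\lambda$ components sum to 1. $\lambda$ must stay
below the shortest peptide length, which is why encoding requires at
least 5 residues.

Feature order within and between blocks is part of the model contract —
trained submodels store *indices* into the 519-dimensional layout — so the
ordering (alphabetical residues, alphabetical dipeptide double loop, fixed
group order) is frozen and covered by tests. The block concatenation order
is the conventional listing order of the four descriptors.

## Feature selection and scaling

Five univariate filter scores are available: absolute Pearson correlation
(the default, which performed best in the source study design), the
Chen–Lin F-score, and three binned statistics (Pearson chi-square,
information gain, and plug-in mutual information) computed on equal-width
5-bin discretizations. Two notes:

* Under the plug-in estimator, information gain and mutual information
  are the same number ($I(X;Y) = H(Y) - H(Y|X)$); both method names are
  kept because they are requested by name in practice.
* "MIC" in descriptor-toolkit parlance is taken to mean plain mutual
  information, not Reshef's maximal information coefficient.

The top 160 features (matching the 160 peptides of a balanced
sub-dataset) are kept and MinMax-scaled to $[0,1]$; out-of-range values at
prediction time are clamped. Whether the original toolchain fitted the
scaler before or inside cross-validation is ambiguous; the default here is
leakage-safe (selection and scaling re-fitted inside each training fold),
with `legacy_scaling = TRUE` reproducing the fit-once-on-everything
convention. The deployed model always uses selection and scaling fitted on
the full sub-dataset.

## The ensemble

One RBF-SVM is trained per balanced sub-dataset through `e1071` (the
LIBSVM binding), with Platt-scaled probabilities (`probability = TRUE`,
LIBSVM's `-b 1`). Hyperparameters $(c, \gamma)$ are grid-searched over the
canonical LIBSVM grids $c \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$,
$\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}$ by mean stratified 5-fold
CV accuracy.

**Tie-breaking.** On strongly separable data large parts of the grid tie
at perfect CV accuracy, and the extreme corners (tiny $c$ and $\gamma$)
then produce nearly flat decision functions: the hard classifier is
perfect, but the Platt sigmoid fitted to a degenerate range of decision
values yields probabilities pinned at 0.5 whose micro-ordering is
arbitrary — useless for averaging voting. Accuracy ties are therefore
broken toward the candidate closest in $\log_2$ space to the LIBSVM
default operating point ($c = 1$, $\gamma = 1/n_\text{features}$), with
smaller $c$ then smaller $\gamma$ breaking residual ties. Under
indifference of the objective, prefer canonical regularization.

Prediction is averaging voting: every submodel applies its own feature
subset, scaler, and SVM; the final probability is the arithmetic mean,
and a peptide is called a binder when the mean is **greater than or
equal to** the threshold `tp`. The default `tp` is 0.5; 0.55 is the
recommended operating point for screening use, where rejecting
non-binders matters as much as keeping binders. `votes` reports how many
individual submodels score the peptide at or above `tp`. Raising `tp` can
never increase the number of predicted binders (the mean is fixed;
only the cut moves), which is property-tested.

Each submodel refits on its whole sub-dataset after cross-validation;
the CV metrics stored with the submodel estimate generalization at the
chosen hyperparameters, they are not the deployed model's training error.
All randomness (fold assignment, Platt calibration's internal CV, negative
sampling) is derived from stored seeds, so retraining with the same seed
reproduces the model exactly.

## Evaluation metrics

`scalar_metrics()` computes sensitivity, specificity, precision, F1,
accuracy, and the Matthews correlation coefficient directly from the
confusion counts; any zero-denominator metric is reported as 0 with a
warning rather than NaN, so fold averages never propagate NaN. AUROC is
computed by the rank (Mann–Whitney) method with tie correction, AUPRC as
step-wise average precision without linear interpolation (the conservative
choice). Fold-averaged reports are arithmetic means over folds.

## What the synthetic data does and does not emulate

The generator exists so that every stage can be exercised end-to-end with
no external data:

* `gen_background_peptides()` draws i.i.d. residues (uniform by default) —
  a naive random library.
* `gen_motif_positives()` draws each position from
  `strength * motif + (1 - strength) * uniform`. The default motif is a
  deterministic 12-mer consensus, so the implant strength is the single
  separability dial: `strength = 1` gives identical motif copies,
  `strength = 0` gives pure background. A `consensus_weight < 1` adds
  within-motif diversity when wanted.
* `gen_ngpd_counts()` draws initial library abundances from a symmetric
  Dirichlet (concentration 1; smaller values give more skewed libraries),
  multiplies planted binders' weights by the enrichment factor once per
  selection round in target arms only (the round-2 control arms pan the
  round-1 pool and gain no further enrichment), jitters each replicate's
  weights lognormally (SD 0.05), and draws multinomial counts at the
  configured depth. Defaults — a 5000-peptide library, $10^5$ reads per
  sample, six target replicates and three replicates for each of R0, R1
  and the two control arms, enrichment factor 10 — mirror a realistic
  two-round screen at desk scale.
* `gen_benchmark()` combines both into a labeled set shaped like the
  canonical 80-positive / 800-negative training design.

Deliberately **not** modeled: sequencing error, PCR/amplification bias,
phage propagation-rate artifacts (the very TUPs the screening step
handles in real data), and chemistry-level read artifacts. Passing the
synthetic recovery tests therefore shows the statistics and the learning
machinery are correct, not that real screens are this clean; on real data
the enrichment caller's false-negative rate will be dominated by
biological noise sources absent here.

## Numerical and degenerate-input choices

* Constant features score 0 under every filter method; a feature constant
  within each class but split across classes gets a large finite F-score
  (the variance denominator is floored at $10^{-12}$) so scores stay
  finite and sortable.
* MinMax scaling maps features that were constant during fitting to 0.
* Ratio denominators are floored at the pseudo-abundance; Welch df
  degenerate cases are handled as described above.
* Insert extraction is exact-match on the flanks with the expected
  spacing, skips reads whose insert contains N or whose mean Phred
  quality over the insert is below 20 (configurable), and drops inserts
  containing stop codons; non-conforming reads are counted in a log
  summary, never errors. Exact matching loses reads with sequencing
  errors in the flanks, which enrichment statistics tolerate.

## Problem sizes used by the automated checks

The test suite and the acceptance script run at the study's stated desk
scales: descriptor invariants on 1000 random peptides (lengths 8–50),
metric oracles on 100 random confusions and 100 random score sets,
enrichment recovery on twenty seeded simulations of a 5000-peptide
library at $10^5$ reads/sample with 20 planted binders, and the full
ten-submodel ensemble on the 80/800 benchmark. Smaller fixtures (reduced
grids, 12–40 peptides per class) are used for unit-level behavior where
the property under test does not depend on scale.

## Known limitations

* The identity-based redundancy removal is exact greedy clustering; it
  does not reimplement CD-HIT's word-filter heuristics and is intended
  for the thousands-of-peptides scale, not millions.
* TUP screening is an exact-sequence lookup against a local table; it
  cannot flag novel propagation artifacts.
* The classifier backend is the RBF-SVM ensemble only; the ensemble
  container would accept other probabilistic backends, but none are
  provided.
* Hit clustering reconstructs a reasonable BLOSUM62 profile embedding +
  average linkage; other linkage/cut choices are defensible and will give
  different group counts.
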