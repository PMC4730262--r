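---
title: "Methods: GapDPC features, SVM-RFE selection and jackknife evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GapDPC features, SVM-RFE selection and jackknife evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmclass)
```

## The model

A protein's structural class (all-α, all-β, α/β, α+β) is strongly
constrained by which residue pairs occur near each other along the chain:
helices impose i/i+3–i+4 periodicities, strands alternate, and mixed folds
blend both. `pssmclass` encodes this from the evolutionary profile rather
than from the raw sequence. Given the PSI-BLAST PSSM of a query (an L×20
matrix of log-odds scores), every entry is mapped into (0, 1) by the
logistic function f(x) = 1/(1 + e^{−x}), and the scaled profile
p<sub>k,i</sub> is summarised by the gapped dipeptide composition

$$y_{i,j,g} \;=\; \sum_{k=1}^{L-g-1} p_{k,i}\; p_{k+g+1,j},
\qquad 1 \le i,j \le 20,\; g = 0,\dots,G,$$

a soft count of ordered residue pair (i, j) at separation g + 1. The g = 0
block is the classical dipeptide composition; stacking blocks g = 0…G gives
400·(G+1) features. The classifier stack is: linear-SVM recursive feature
elimination (SVM-RFE) to rank features, a top-K cut, and an RBF-kernel
one-vs-one SVM whose (C, γ) are grid-searched. Evaluation uses the
jackknife (leave-one-out) test with per-class accuracy,
one-vs-rest Matthews correlation, and pooled overall accuracy.

### Assumptions

* The profile is informative: for a query with no homologs the PSSM
  degenerates toward the BLOSUM row pattern and GapDPC carries mostly
  composition, not structure.
* Scores are signed log-odds, which is why the sigmoid (centred at 0) is a
  sensible squashing. The ASCII PSSM also carries a block of nonnegative
  weighted percentages; sigmoid-scaling that block would compress all
  values into [0.5, 1), so the log-odds block is the default and
  `parse_pssm(block = "percent")` is an explicit opt-in.
* Features are raw sums, so their magnitude grows with L. The default
  follows that definition verbatim; `normalize = TRUE` (divide by
  L − g − 1) is available when length confounding is a concern.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_gap` (G) | 8 | largest gap; 400·(G+1) features. Any profile must satisfy L ≥ G + 2, so G = 8 accommodates sequences as short as 10 residues. |
| `K` | user-chosen | retained top-ranked features. `sweep_top_k()` over K = 10, 20, …, 500 with 5-fold CV reproduces the canonical selection curve; on the benchmark-scale datasets the published operating points are K = 460 (large sets) and K = 110 (small sets). |
| `step` (RFE) | 0.1 | fraction of surviving features eliminated per round (floor, min 1). `step = 1` is the original one-at-a-time elimination; the fractional default is the usual accuracy/cost compromise and, on data with well-separated importances, selects the same top set. |
| `cost` (linear C) | 1 | ranking-SVM cost; the ranking, not the margin, is consumed. |
| `cost_grid`, `gamma_grid` | 2^−5…2^15, 2^−15…2^3 (steps of 2²) | the LIBSVM coarse grid; ties prefer smaller C, then smaller γ. |
| `folds` | 5 | stratified CV folds for tuning and sweeps; stratification keeps the smaller classes represented in every fold. |

## Numerical and design choices

**Feature order.** Flat 1-based index g·400 + (i−1)·20 + j, g-major then
first residue then second, with names `g{g}_{aa_i}{aa_j}` and columns in
the PSI-BLAST header order (A R N D C Q E G H I L K M F P S T W Y V).
Nothing downstream depends on the order beyond consistency, but ranking
reports must decode indices back to (g, aa<sub>i</sub>, aa<sub>j</sub>), so
the convention is frozen.

**Multiclass RFE criterion.** The original RFE criterion is the squared
weight of each feature in a two-class linear SVM. With four classes the
package sums squared weights over all one-vs-one pairs — the natural
pairwise decomposition matching LIBSVM's own multiclass scheme.

**Tie handling in RFE.** Exactly tied scores (e.g. duplicated columns) are
resolved by keeping the lower original index longer, so identical columns
rank 1, 2, …, d. Scores are compared after rounding to 10 significant
digits: the underlying quadratic-programming solver reproduces exact ties
only up to ~10⁻¹⁴ relative jitter, and without the rounding that jitter,
not the tie rule, would pick the order.

**Degenerate inputs.** Double sigmoid-scaling is refused (it silently
compresses values into (0.5, 0.73)); gaps with no admissible positions
(L < g + 2) raise an error rather than returning an all-zero block;
single-class datasets are rejected by ranking, training and evaluation;
an empty class yields NA per-class accuracy and MCC 0 by the standard
zero-denominator convention.

**Evaluation protocols.** The default pipeline mirrors the classical
sequence: rank once on the full dataset, fix K, tune (C, γ) once, then
jackknife with everything fixed. This is the protocol implied by ranking
curves computed before the jackknife, and it is optimistic: the held-out
sample influenced feature selection and tuning. `nested = TRUE` re-runs
ranking, selection and (optionally) tuning inside every fold and is the
honest estimator; both protocols are recorded verbatim in the report. The
distinction matters most on weak or null signal — see below.

## The synthetic generators

Real benchmark profiles require PSI-BLAST searches against NR, so the test
bed is synthetic and fully seeded.

`make_pssm()` draws rows as renormalized positive random vectors
(`sharpness` exponentiates the draws; large values approach one-hot rows),
and exposes the raw form through the inverse sigmoid so the raw→scaled
path is exercised end to end. Rows sum to one, which also yields the exact
identity Σ<sub>i,j</sub> y<sub>i,j,g</sub> = L − g − 1 used as an
analytical check.

`make_classed_profiles()` plants, for each class, a private set of
(i, j, g) dipeptide propensities: at randomly chosen non-overlapping
position pairs (k, k+g+1) the rows are mixed 10:90 with the indicator rows
of residues i and j. The number of planted sites per propensity is
binomial over ⌊(L−g−1)/(g+2)⌋ slots with probability min(1, signal/4) —
chosen so that signal 0 plants nothing (classes exactly exchangeable) and
signal ≈ 3–4 saturates the available slots, the regime a cleanly separable
4-class benchmark represents. Because the signal is injected at the
*pair* level, single-residue composition is nearly uninformative and the
GapDPC features are what carry the classes — matching what the
representation claims to exploit. Default sizes (30 proteins/class,
lengths 30–60, 8 propensities/class, G = 4) keep the full jackknife within
seconds while leaving the feature space (d = 2000) much wider than n.

`make_feature_dataset()` skips profiles entirely: standard-normal columns
with ± effect/2 class offsets (signs balanced across classes) on a random
informative subset — the direct test bed for RFE and the classifier.

What the generators do **not** emulate: substitution-matrix correlations
between amino acids, position-dependent conservation gradients, homology
between proteins, and realistic class overlap. A perfect synthetic score
therefore validates the machinery, not the biological difficulty of the
task; published-scale accuracies on real datasets additionally depend on
profile quality against a large sequence database.

### Null-signal calibration

With `class_signal = 0` the classes are exchangeable and jackknife
accuracy should be statistically indistinguishable from chance (1/4). This
comparison is only valid under the nested protocol. The non-nested default
fails it in *both* directions, for well-understood reasons: with a fixed
smooth configuration the leave-one-out training set always under-represents
the held-out class, so a prior-driven SVM votes against it (accuracy → 0,
the classic LOO-with-majority-classifier artifact, which a dedicated test
reproduces exactly against its closed form); with selection and tuning on
the full data, the held-out sample leaks into the top-K choice and
accuracy drifts above chance. The package's null-calibration check
therefore runs `jackknife(nested = TRUE, tune = TRUE)` and lands inside
the 3σ binomial band around 0.25, while the strong-signal check uses the
default protocol at `class_signal = 3` and reaches ≥ 0.95.

## Problem sizes used in the checks

The shipped tests and `scripts/acceptance.R` use: ≥100 random profiles
(L ∈ [3, 20]) against a brute-force triple-loop oracle at 10⁻¹⁰ relative
tolerance; the RFE recovery benchmark at d = 200, 10 informative columns,
effect 2.0 SD, 40 samples/class, averaged over 10 seeds (≥80% of planted
columns in the top 20); and the end-to-end pipeline at G = 4 with
120 proteins (strong signal) and 40 proteins (null). These sizes were
chosen to make every stage's behaviour visible at interactive timescales.

## Known limitations

* PSI-BLAST invocation is a documented convenience wrapper, not a tested
  stage; profile quality is the caller's responsibility.
* The non-nested default jackknife is optimistic by construction (see
  above); use `nested = TRUE` for honest error estimates.
* Raw GapDPC features scale with sequence length; on datasets with
  class-correlated length distributions the unnormalized default can
  exploit length rather than structure.
* MCC's zero-denominator convention (return 0) makes degenerate classes
  look "uncorrelated" rather than undefined; reports carry the raw counts
  so any other convention can be recomputed.
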