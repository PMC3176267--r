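---
title: "Physicochemical sequence classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical sequence classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`luxpred` classifies proteins as bioluminescent or not from primary
sequence alone. This vignette is the package's own account of the science:
the model, its assumptions, the parameters that matter, what the synthetic
benchmarks do and do not show, and the choices made where the design was
genuinely open.

## The encoding model

A sequence of length $L$ is represented by, for each amino-acid property
scale $j$,

$$x_j \;=\; \frac{1}{L}\sum_{i=1}^{L} v_j(a_i),$$

the mean property value over its residues. This is a *composition
statistic*: it is invariant to residue order, bounded by the scale's range,
and its between-class signal is exactly a weighted difference of residue
frequencies. The assumption behind the whole method is that bioluminescent
and non-bioluminescent proteins differ systematically in composition-level
physicochemistry even when they share no detectable homology.

Two boundary rules are ours, because the plain "sum over all residues"
recipe does not define them:

* **Non-standard residues** (`B`, `Z`, `X`, `U`, `O`, `J`) are kept by the
  FASTA reader (I/O is lossless) but excluded at encoding time from both
  the numerator and the divisor.
* **Missing scale values** (`NA` slots in AAindex1 records) are treated the
  same way. The divisor is therefore the number of residues that actually
  contribute, which keeps the statistic an unbiased mean under missingness
  rather than shrinking it toward zero.

A sequence with *no* contributing residue for some scale is an error, named
by sequence and accession, not a silent zero.

The feature dimension is whatever the supplied AAindex file contains; the
package never assumes a particular release size.

## Standardization

Raw AAindex scales differ by orders of magnitude, and two downstream
components — the Gaussian kernel and ReliefF's distance computations — are
scale-sensitive. Features are therefore z-scored with *training-set*
statistics (sample standard deviation, $n-1$ denominator) before selection
and classification; the stored model carries the scaling so prediction
reproduces the training-time transform exactly. Zero-variance training
features get scale 1 and become all-zero columns rather than being dropped,
so column indices stay aligned with accessions. Whether the original
protocol scaled features is unknowable from the outside; standardization is
the defensible default and `standardize = FALSE` switches it off for
sensitivity analysis.

## Feature selection

Three filter selectors are implemented by hand (no installed package
provides them) and verified against independently coded brute-force oracles
in the test suite.

**ReliefF.** Continuous-attribute ReliefF with $m = n$ samplings in a fixed
order (every instance once), making the weights deterministic and row-order
invariant. For each instance, its $k$ nearest hits and $k$ nearest misses
(per opposite class, weighted by class prior) update each feature weight by
the range-normalized difference `diff`, with Manhattan distance on the same
normalized differences for neighbor search. Defaults $k = 10$ neighbors,
matching common toolkit practice; $k$ must be smaller than the smaller
class. Constant features have `diff = 0` everywhere and score exactly 0.

**Information gain.** Each feature is discretized by the Fayyad–Irani MDL
recursive binary-split criterion on the training data; the score is
$H(\text{class}) - H(\text{class}\mid \text{bins})$ in bits. Features the
MDL criterion refuses to split score 0 — an aggressive but standard guard
against spurious gain on continuous noise.

**mRMR.** Features are discretized into three states at mean ± one standard
deviation (the classical variant), and greedy forward selection maximizes
the MID (difference) criterion
$I(f;\text{class}) - \tfrac{1}{|S|}\sum_{s\in S} I(f;s)$. The ranking is
the selection order with stepwise criterion values.

Ties everywhere break by ascending original feature index, so all rankings
are exactly reproducible.

The frozen-subset protocol (selection on the full training set, then
cross-validation) mirrors the historical workflow of this method family but
lets selection see the CV folds' held-out points, which can bias the CV
estimate upward. `nested = TRUE` recomputes the standardizer and the
ranking inside every fold for an honest estimate; the deployed model still
uses the frozen subset.

## The classifier

A soft-margin SVM with Gaussian kernel
$K(x, x') = \exp(-\gamma\lVert x - x'\rVert^2)$; the class is the sign of
$f(x) = \sum_i y_i \alpha_i K(x_i, x) + b$. The dual quadratic program is
delegated to LIBSVM via `e1071`; everything needed to evaluate $f$ is
extracted and stored (support vectors, $y_i\alpha_i$, $b$, $\gamma$,
feature subset, scaling), and decision values are recomputed from those
stored fields by package code — the JSON model file is self-sufficient, and
serialization fidelity is tested to $10^{-9}$. One subtlety: LIBSVM orients
its decision function toward whichever class appears first in the training
data, so `train_svm()` normalizes the stored coefficients to make $f > 0$
always mean class $+1$. The boundary case $f(x) = 0$ maps to $-1$,
documented and tested.

**Grid search.** Defaults follow the LIBSVM-guide lattice
$C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$,
$\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}$, scored by mean held-out
accuracy over stratified $k$-fold CV ($k = 5$ by default). Stratification
keeps class balance in every fold for the balanced designs this method uses;
ties on CV accuracy (within $10^{-9}$) prefer the smallest $C$ — the lowest
model complexity — then the smallest $\gamma$. All fold randomness flows
from one explicit seed recorded in every artifact.

## Evaluation

Accuracy, sensitivity and specificity are reported in percent (printed to
two decimals), MCC to four. A zero in any MCC marginal makes the
coefficient undefined; the package reports 0 with a warning flag, the common
convention. ROC curves are built from continuous decision values by a
threshold sweep with tie groups collapsed, and AUC by the trapezoid rule,
which equals the normalized Mann–Whitney statistic (concordant + half-tied
pairs) — both facts are exercised by pair-counting oracles and a `pROC`
cross-check.

One documentation note on the historical benchmark this package's worked
examples reconstruct: the narrative describes an independent test set with
18,202 negatives, yet every printed metric row is arithmetically consistent
only with 141 positives and 190 negatives (e.g. 84.21% = 160/190,
80.06% = 265/331). The worked examples use the 190-negative reconstruction
(TP = 105, FP = 30, TN = 160, FN = 36), which reproduces all four printed
values at printed precision; the "all features" row is consistent with
neither count and is not used. The discrepancy is documented, not resolved.

## The synthetic benchmark

`synth_spec()` describes a two-class benchmark in which the negative class
draws residues i.i.d. from a base frequency vector (uniform by default; a
20-vector of natural abundances can be supplied) and the positive class
receives a total of $\delta$ extra frequency mass split over the first
`n_informative` residues of the canonical order, renormalized. Because the
encoder measures exactly residue composition, the feature-level signal is
analytically controllable: $\delta = 0$ makes the classes exchangeable, and
selector/classifier power grows smoothly with $\delta$.

`make_benchmark()` additionally designates the first `n_informative`
property tables as **marker scales** — their values on the informative
residues are set to `marker_contrast` (default 3, i.e. three standard
deviations of the synthetic scale distribution) — so tests have an exact
ground-truth informative feature set, which is empty under the null. A
configurable rate of `X` residues (default 0.5%) exercises the encoder's
non-standard-residue path, and 2% of table entries are missing by default
to exercise the missing-value path.

Default study shape follows the historical design: 300 + 300 training
sequences, 100 + 100 held-out, lengths uniform on 80–300 residues (typical
domain lengths). The package's calibration runs use these sizes for the
strong-effect benchmark (with 100 tables and ReliefF top-50, grid
$C = 2^{-3..11}$, $\gamma = 2^{-11..1}$) and a deliberately smaller null
benchmark (60 + 60 / 40 + 40, 40 tables, top-20, a 3×3 grid, ten seeds) —
chance-level accuracy needs replication across seeds more than scale.

What the generator does *not* emulate: homology structure, domain
architecture, profile/HMM-style positional dependence, realistic length and
abundance distributions, or label noise. Passing the synthetic suites
therefore demonstrates that the pipeline is correct, leak-free and able to
recover composition-level signal — not that any particular accuracy will
transfer to real proteins, where the class signal is weaker and confounded
with phylogeny.

## Numerical choices and degenerate inputs

* Range-normalization in ReliefF uses the observed range; constant features
  divide by 1 and score 0.
* MDL split search compares gains with a $10^{-12}$ slack and takes the
  lowest cut on ties.
* Mutual information uses $0\log 0 = 0$ and base-2 logs throughout.
* Standardizer: constant columns get scale 1; applying parameters to a
  matrix with different features is an error, not a silent subset.
* `feature_matrix()` refuses NaN/Inf entries, duplicated feature ids, and
  labels outside $\{+1,-1\}$; the TSV reader names the offending row or
  token.
* Full determinism: identical spec or config + seed gives byte-identical
  FASTA/TSV/JSON artifacts (tested).

## Known limitations

* The composition encoding discards all positional information; motifs,
  dipeptide composition and profile features are out of scope by design.
* Frozen-subset CV estimates are optimistically biased; use
  `nested = TRUE` when the CV number itself is the quantity of interest.
* mRMR implements the MID criterion with the three-state discretization;
  other variants (MIQ, finer discretizations) would need new code paths.
* The SVM is binary only, without probability calibration.
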