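---
title: "Rough-set reducts and a backpropagation classifier for clinical tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-set reducts and a backpropagation classifier for clinical tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsbpnn)
```

## The problem

Clinical prediction tables — a few hundred patients, a dozen or two
mixed categorical and binned-numeric attributes, a binary outcome — are
small enough that exhaustive, assumption-free feature selection is
feasible and interpretable. `rsbpnn` implements a two-stage workflow:
a rough-set stage that enumerates *reducts* (attribute subsets carrying
the same discriminating information as the full set) and a neural stage
that trains a small backpropagation network on each chosen reduct.

## Stage one: the rough-set model

An information system `I = (U, A ∪ D)` holds objects `U`, condition
attributes `A`, and one decision attribute `D`. All analysis happens on
categorical values; numeric attributes are first discretized against
per-attribute cut-points, a value mapping to the label of the greatest
cut-point at or below it and values under the first edge clamping to the
first label. That convention is monotone and total, and applying it
twice is the identity (the output schema marks the attribute
categorical). Cut-points for the bundled clinical schemas are the
conventional binned domains of those datasets; for the Statlog heart
attributes no published binning exists, so the bundled file carries
decile-style bins over the published ranges and is explicitly editable —
reduct counts on that dataset depend on this choice.

**Missing values** are handled before anything else, in a fixed order:
(1) reject every attribute with ≥ 25 % missing cells over the original
rows; (2) reject every tuple with ≥ 25 % missing cells over the
*retained* attributes; (3) impute each remaining hole with the most
frequent value of its attribute among same-class tuples, ties broken by
first occurrence in the data (deterministic). Attributes go first
because a single hopeless lab column (e.g. a coagulation time recorded
for barely half the patients) would otherwise drag down many tuples that
are complete elsewhere. The comparison is ≥, with a `strict` flag, and
the pass order is switchable for sensitivity analysis. A class-by-
attribute stratum that is entirely missing raises a named error rather
than guessing.

**Reduct acceptance.** The reference universe is the positive region of
the full attribute set, `Pos_A(D)` — the objects on which the data are
internally consistent. A proper nonempty subset `P` is accepted when
`IND(P)` and `IND(A)`, both restricted to that region, coincide. Two
details of this choice deserve comment:

* *Why restrict to the positive region?* On an inconsistent table the
  full-attribute partition already fails to separate the conflicting
  objects; demanding equality there would let the conflict zone veto
  subsets arbitrarily. On the bundled six-patient table
  (`heart_toy()`), restriction is exactly what admits both
  `{Chp, Vessel}` **and** `{ECG, Vessel}` — the latter merges the
  conflicting pair with a consistent object and would fail a whole-`U`
  comparison (and also fails the classical positive-region-preservation
  test, available here as `semantics = "pos"`).

* *No minimality filter.* Acceptance is monotone: any proper superset
  of an accepted subset is accepted (restriction to a fixed universe
  makes refinement squeeze between `IND(P)` and the finest partition).
  Reduct reports therefore show superset-closed families, and the
  interesting structure is in the minimal-size members and the core
  (the intersection of all accepted sets; empty when nothing is
  accepted).

* *Which semantics for which question?* The restricted-equality
  criterion asks "does P discern everything A discerns?", which on a
  fully consistent table means discerning every object pair —
  including pairs separated only by noise attributes. For
  parameter-recovery questions ("which attributes does the decision
  actually depend on?") the decision-preserving `semantics = "pos"`
  criterion is the right tool, and it is what the synthetic
  planted-reduct tests use: on generated tables its minimal accepted
  subsets are exactly one attribute per informative slot, with
  bijective recodings interchangeable with their sources.

**Approximate reducts.** The similarity of `IND(P)` to `IND(A)` is the
fraction of unordered object pairs on which the two partitions agree
(both joined or both separated), computed on the reference universe.
It is symmetric, reaches 1 only at equality — so approximate mode with
threshold → 1 converges to exact mode — and costs O(n²) pair checks.
Acceptance is strictly greater than the threshold (default 0.90). The
dependency-degree ratio γ_P/γ_A is available as an alternative measure
(`similarity = "gamma"`). Nothing in the similarity definition is
forced by the published description, which names the 90 % bar but not
the measure; pairwise agreement was chosen for the three properties
above.

Enumeration is exhaustive over all `2^n − 2` candidates (sizes
ascending), with a configurable hard cap (`max_attrs`, default 20)
beyond which a `size_range` must be given. The per-size candidate
counts `C(n, k)` and total are reported alongside the accepted tallies.

## Stage two: the network

The classifier is deliberately minimal: inputs (one per reduct
attribute, integer-coded, min–max scaled to [0, 1] on the training fold
only, test values clipped), one hidden layer of 25 `tanh` units, one
linear output regressing the 0/1 label, decision threshold 0.5.
Training is full-batch gradient descent on the MSE — the plainest
faithful reading of "backpropagation" — with optional momentum, seeded
uniform(−0.5, 0.5) initialization, stopping at an MSE goal or an epoch
budget. The published configuration pins only the topology and
activations; learning rate 0.05, 1000 epochs and goal 10⁻³ are this
package's defaults, all exposed in `bpnn_config()`. Scaling is likewise
an implementation choice: unscaled integer codes saturate `tanh` units
and stall the gradient.

The module's primary correctness oracle is independent of the
implementation: the analytic backpropagation gradient is compared
against central finite differences on small random networks and must
agree to 10⁻⁵ relative error (in practice it agrees to ~10⁻⁹).
Determinism is part of the contract: same data, configuration and seed
give bit-identical weights, and permuting training rows changes nothing
because the batch gradient is a sum.

## Evaluation

Splits are simple random (unstratified, matching a plain
random-division protocol) with `round-half-up(fraction · N)` training
rows — 147 patients at 0.8 give 118/29 — and an optional stratified
mode. k-fold cross-validation runs *inside* the training portion to
validate training; the final model is refit on the whole training
portion before the held-out evaluation. Metrics come from the 2×2
confusion matrix: accuracy, sensitivity, specificity (percent), TPR and
FPR (fractions). A zero denominator flags the metric undefined rather
than reporting 0. ROC curves sweep the distinct scores with ties
stepped simultaneously; AUC is trapezoidal and equals the Mann–Whitney
pair-counting statistic, which the tests verify exhaustively on small
instances.

One published inconsistency is worth documenting: in the summary table
of best-reduct results, the hepatitis sensitivity/specificity cells are
transposed relative to their own confusion counts (TP/(TP+FN) on the
printed counts is 92.86 %, which appears in the specificity column, and
vice versa). The formulas here are applied literally, and the computed
accuracy 143/147 = 97.28 % is reported rather than the printed 97.30.

## The synthetic generator

`gen_info_system()` builds tables whose ground truth is known: the
decision is a seeded random lookup table over the value-tuples of the
informative attributes (so it cannot depend on noise attributes even
accidentally); redundant attributes are random *bijective* recodings of
informative ones — the precise condition under which their
indiscernibility partitions are identical and reduct search treats them
as interchangeable; noise attributes are independent; an inconsistency
rate flips that fraction of labels, manufacturing class-mixed blocks
and a proper positive region; `inject_missing()` masks condition cells
independently at a stated rate, never the decision. Default study
conditions are 50 objects, 2 informative + 1 redundant + 2 noise
attributes of cardinality 3 — small enough for brute-force verification
of every subset, structured enough to exercise recoding equivalence.
`gen_classification()` emulates integer-coded cytology-style features
(1–10) as two Gaussian clusters at a stated separation.

What the generator does *not* emulate: real marginal distributions,
correlated noise, informative missingness (MCAR only), multi-class
outcomes. Passing tests therefore certify the machinery — partitions,
acceptance logic, gradients, splits — not clinical performance on any
real dataset; headline accuracies on the UCI tables additionally depend
on a discretization and hyperparameters the source never specifies, and
are reproducible only approximately.

## Problem sizes and numerical choices

The test suite and acceptance script run on deliberately small
instances — tables of 5–100 objects and ≤ 6 attributes (brute-force
range), networks of ≤ 25 hidden units, 120-sample classification sets —
chosen so every oracle (all-pairs discernibility, exhaustive pair
counting, finite differences) stays exact. Mode ties in imputation
break by first occurrence; partition blocks are kept in first-object
order and compared after canonical sorting; the empty attribute set
induces the one-block partition; `2^n − 2` of 0 candidates (single
attribute) yields an empty report with empty core. Gradient checks use
central differences at ε = 10⁻⁶ with denominators floored at 10⁻⁴ to
avoid 0/0.

## Limitations

Exhaustive enumeration is exponential by design — the point of the
method on these datasets — and the default cap refuses more than 20
attributes without an explicit size range. Reduct selection for the
classifier stage is the user's decision (or an explicitly circular
`top_k_by_cv` convenience); no automatic rule is claimed. The network
has no regularization and no early stopping beyond the MSE goal;
on separable toy data it overfits happily, which is what the
recovery tests rely on.
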