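# rsbpnn

Rough-set feature selection chained to a from-scratch backpropagation
neural network, for mining binary-outcome clinical tables (hepatitis
survival, breast-tumor malignancy, heart-disease presence, and the like).
It is aimed at analysts who want an interpretable attribute-selection
stage — *which* clinical measurements carry the diagnostic signal — in
front of a small neural classifier, with every step reproducible from a
seed.

## The method

A classified table is an *information system* `I = (U, A ∪ D)`: objects
`U`, categorical condition attributes `A` (numeric measurements are
first binned against cut-points), one decision attribute `D`. For any
`P ⊆ A`, the indiscernibility relation

    IND(P) = {(x, y) : a(x) = a(y) for every a ∈ P}

partitions `U` into equivalence blocks. For a decision class `X`, the
*lower approximation* under IND(P) is the union of blocks inside `X`,
the *upper approximation* the union of blocks meeting `X`, and the
*positive region* `Pos_A(D)` is the union of all classes' lower
approximations under the full attribute set — the objects classifiable
with certainty.

**Reducts.** Every proper nonempty subset `P ⊂ A` (there are `2^n − 2`
of them) is examined; `P` is accepted when `IND(P)` restricted to
`Pos_A(D)` equals `IND(A)` restricted to the same region — or, in
approximate mode, when the pairwise partition similarity exceeds a
threshold (default > 0.90). No minimality filter is applied, so accepted
sets are superset-closed; the *core* is the intersection of all accepted
sets. A classical positive-region-preserving criterion is available via
`semantics = "pos"`.

**Classifier.** Accepted reducts feed a single-hidden-layer perceptron —
25 tangent-sigmoid hidden units, one linear output regressing the 0/1
label — trained by full-batch gradient descent on the MSE with seeded
uniform(−0.5, 0.5) initialization and min–max input scaling fitted on
the training fold. Evaluation: seeded train/test splits (0.8/0.7/0.6),
10-fold cross-validation inside the training portion, confusion-matrix
metrics (accuracy, sensitivity, specificity, TPR, FPR) and trapezoidal
ROC/AUC.

Missing values are handled first: any attribute, then any tuple, with
≥ 25 % missing cells is rejected; the rest are imputed with the most
frequent value of the attribute within the tuple's class.

## Worked example

The bundled six-patient heart-disease table (chest-pain type, resting
ECG, vessel count):

```r
library(rsbpnn)
h <- heart_toy()
ind_partition(h, "Chp")
#> <partition> 6 objects in 3 block(s)
#>   { P1, P4 }
#>   { P2 }
#>   { P3, P5, P6 }

find_reducts(h, mode = "exact")
#> <reduct_report> mode=exact, 2 reduct(s) of 6 candidates
#>   per size: 2:2
#>   core: { Vessel }
```

Patients P5 and P6 agree on every measurement but not on the outcome, so
the positive region is P1–P4; of the six candidate subsets, exactly
`{Chp, Vessel}` and `{ECG, Vessel}` reproduce the full-attribute
indiscernibility there, and `Vessel` — their intersection — is the core:
no reduct can discard the vessel count.

Published confusion counts run through the metric formulas:

```r
metrics(confusion_matrix(tp = 26, fn = 2, fp = 2, tn = 117))
#> accuracy     97.28 %
#> sensitivity  92.86 %
#> specificity  98.32 %
#> TPR           0.93
#> FPR          0.017
```

An end-to-end synthetic run (planted two-attribute signal, one
redundant recoding, two noise attributes):

```r
g <- gen_info_system(synth_spec(n_objects = 30, seed = 7))
r <- find_reducts(g$table, semantics = "pos")
min(vapply(r$reducts, `[[`, numeric(1), "size"))
#> [1] 2        # the planted pair (or its recoding) and nothing smaller
```

Real UCI datasets (hepatitis, Wisconsin breast cancer, Statlog heart)
are not redistributed; fetch them yourself and pair them with the schema
files under `inst/extdata/` (`read_schema()` + `read_table()` +
`run_pipeline()`).

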