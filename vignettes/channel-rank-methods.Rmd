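---
title: "Channel-rank EEG features, INCA selection, tkNN and Lobish: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-rank EEG methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelpat)
```

This vignette explains the model implemented by `channelpat`, the choices
behind its defaults, and what the test suite does and does not establish.

## The model and its assumptions

The pipeline treats a `C × N` EEG segment purely through the per-timepoint
ordering of its channels. The working assumption is that class-relevant
information is carried by *which regions dominate and how dominance hands
over in time*, not by absolute amplitudes. That buys three properties:

* invariance to monotone amplitude rescaling (gain, impedance and unit
  differences vanish — `channel_transform(exp(X))` equals
  `channel_transform(X)`);
* a fixed, dimension-independent feature space: whatever `N` is, a segment
  maps to `C²` transition counts summing to `C·N − 1`;
* direct anatomical interpretability, since every feature is an ordered
  channel pair and channels live on a named montage.

The cost is equally clear: any class signal expressed as a *common* amplitude
shift across channels is invisible to the transform. Data whose classes
differ only in overall power will not be separated.

The stages are independent and composable: `channel_transform()` →
`extract_features()` → `inca_select()` → `tknn()`, wrapped by
`channel_model()`, with `lobish_report()` decoding the selected features into
lobe-pair symbols.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `size_range` (INCA) | `c(10, C²)` | prefix sizes scored by the loss kNN; 10..196 gives 187 candidates for `C = 14` |
| `lambda` (NCA) | `1/n` | L2 penalty on feature weights; the standard scale-free default for the softmax LOO objective |
| `maxit` (NCA) | 60 | L-BFGS iteration cap; the objective plateaus well before this on the matrix sizes involved |
| loss kNN | `k = 1`, L2, equal | the minimal reading of "kNN with 10-fold CV"; overridable via `loss_k`, `loss_distance`, `loss_weight` |
| `nfolds` | 10 | stratified folds, shared by the INCA loss and all 60 tkNN configurations so every outcome is scored on the same splits |
| `seed` | 1 | drives the single fold split and the synthetic generator; every fitted object records it |

The tkNN grid itself is fixed by construction (60 = 10 k-values × 2
distances × 3 weight schemes) and is not a tuning surface.

## Numerical and convention choices

* **Tie-breaking in the rank transform** is stable: among equal amplitudes
  the lower channel index comes first, so a constant column yields
  `1, 2, …, C`. This makes the transform a deterministic function and is
  asserted against a permutation-enumeration oracle in the tests.
* **Pair coding** is base-`C`, 0-based codes, 1-based bins
  (`bin = C·(a−1) + (b−1) + 1`), and `pair_decode()` /
  `feature_to_symbols()` implement its exact inverse; the round trip is
  tested exhaustively over all 196 bins. The inverse used is the
  self-consistent one — a `mod`-based decoding that shifts the second
  channel by one would disagree with the coder at block boundaries
  (e.g. bin 14 is the pair (1, 14), not (1, 1)).
* **Standardization.** Transition counts are heavy-tailed, so features are
  z-scored before NCA (whole matrix) and inside every CV fold using
  training-fold statistics (constant features get unit scale). This is
  declared, configurable behavior, not a silent step.
* **NCA** learns per-feature scales `w` on the distance
  `d_ij = Σ_r w_r² |x_ir − x_jr|`; the reported weight is `w_r²`. The
  analytic gradient is used (checked against finite differences to 1e-10
  during development) and the fit starts from the flat `w = 1`.
* **kNN weight semantics:** equal = unweighted vote, inverse = `1/d`,
  squared-inverse = `1/d²`; exact matches (distance 0) carry infinite
  weight, so the prediction is the majority among zero-distance neighbors.
  Vote ties break toward the label of the nearest neighbor holding a tied
  label, then the smallest level.
* **IMV mode ties** break toward the label predicted by the most accurate
  contributing outcome, then the smallest label; the accuracy sort is
  stable (earlier configuration first); only the 60 classifier-wise
  outcomes enter the sort, voted outcomes are not re-entered.
* **Greedy pooling ties** resolve classifier-before-voted, then lower
  index.
* **Accuracy ties across INCA sizes** go to the smallest size (parsimony).
* **Entropies** are in bits; the symbol entropy of a 4-letter alphabet is
  bounded by 2, the 16-cell transition entropy by 4, and both bounds are
  attained on uniform fixtures in the tests.
* **Degenerate inputs:** single-class labels, constant feature matrices,
  empty manifests, folds that exhaust a class, all-zero count vectors and
  out-of-alphabet symbols are rejected with specific errors; an empty
  feature-id set yields an empty sentence with a warning.

## The synthetic generator

No recordings ship with the package, so `synth_eeg_dataset()` provides the
study conditions for validation. Its design principle: the class signal must
live in the channel-amplitude *ordering*, because that is all the transform
can see — a mean-shift-only signal would be a vacuous test. Class A assigns
channels a linearly ascending gain ramp `1 + effect·δ`, class B the reversed
ramp (`δ` spans ±0.5); each channel then follows a shared rectified sinusoid
with per-segment random phase plus Gaussian noise. At `effect = 0` the
classes are exchangeable (tested via rank tests on the busiest feature
bins); at `effect = 1` with small noise the per-timepoint ordering is nearly
class-deterministic and the pipeline must recover labels almost perfectly.

Defaults — 14 channels, 256 samples, 30 segments per class, `effect = 0.8`,
`noise_sd = 0.2` — are one fixed operating point: large enough for stratified
10-fold CV with three samples per class per fold, small enough that the full
pipeline runs in seconds. The validation runs in the acceptance material use
`effect = 1.0`, `noise_sd = 0.05`, 30 per class and 128 samples (60-segment
fits, 30-segment held-out sets); the planted-feature recovery study uses
40 × 12 matrices with an XOR-geometry informative pair over 10 seeds. The
planted pair is *complementary* (each feature alone is uninformative, the
pair is jointly decisive) because redundant planted features are correctly
pruned by the parsimony tie rule — recovery of a redundant pair would be the
wrong thing to demand of a prefix selector.

What the generator does **not** emulate: 1/f spectra, alpha peaks, channel
correlation structure from volume conduction, artifacts, non-stationarity.
Passing tests therefore show that the algorithms implement their definitions
and can recover a rank-encoded class signal; they do not certify performance
on real EEG.

## The selection protocol and its optimistic bias

The pipeline reproduces its source protocol exactly: NCA ranks features on
the *full* data set, candidate prefixes and the 118 tkNN outcomes are scored
by CV on those same labels, and the greedy step keeps the best outcome. Two
consequences must be understood:

1. `final_accuracy` is a model-selection quantity, optimistically biased by
   the max over 118 outcomes. For unbiased assessment use `predict()` on
   held-out data (the acceptance script reports such a held-out accuracy).
2. Because the feature ranking sees every label before cross-validation,
   the *end-to-end* pipeline scores above chance even on permuted labels at
   small `n`; the bias shrinks as `n` grows but is intrinsic to the
   protocol. The classifier stage by itself is honest: `tknn()` refit on
   permuted labels with a fixed feature set lands within binomial noise of
   the majority rate, which is what the test suite asserts, and the
   acceptance script reports both permuted-label quantities side by side so
   the gap is visible rather than hidden.

The implementation deliberately does not "fix" the protocol (e.g. by nesting
the selection inside the folds); it implements it as defined and documents
the bias.

## Known limitations

* Feature counts grow as `C²`; montages much denser than 14 channels make
  the histogram sparse for short segments.
* NCA materializes an `n² × p` pairwise-difference matrix; fits beyond a
  few thousand segments need chunking that the package does not implement.
* The EDF reader covers standard EDF (16-bit, equal sampling rate across
  the selected channels); EDF+ annotations and discontinuous records are
  out of scope.
* Metrics follow the macro-average convention (overall = unweighted mean of
  per-class values, accuracy global); per-class geometric mean is
  `sqrt(sensitivity × specificity)`. Under that formula the macro geometric
  mean of a two-class table equals the macro sensitivity, which is what the
  package reports.
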