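---
title: "Methods: a shallow convolutional classifier for 6mA site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a shallow convolutional classifier for 6mA site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snn6ma)
```

## The prediction problem

N6-methyladenine (6mA) prediction is cast as binary classification of
fixed-length DNA windows: a 41-bp sequence whose central base is an adenine
is labeled positive if that adenine is methylated and negative otherwise.
The model sees nothing but the base composition of the window — no genomic
coordinates, conservation or chromatin context — so everything it can learn
is local sequence preference around the modified site. That is the central
modelling assumption: 6mA deposition is sufficiently determined by the
surrounding ~20 bp of sequence for a position-aware pattern detector to
separate methylated from unmethylated adenines.

## Sequence encodings

Two encodings are provided, both producing a 4-row × L-column matrix so the
same architecture consumes either.

**One-hot** maps A, T, C, G to the four unit indicator vectors (row order
A, T, C, G). It is information-free in the sense that it injects no prior
knowledge; the convolution filters must discover everything.

**Feature encoding** augments three binary chemical properties per base —
ring structure (purine: A, G), hydrogen-bond strength (weak: A, T) and
functional group (amino: A, C) — with a fourth row carrying the cumulative
nucleotide frequency: at position i, the fraction of positions 1..i holding
the same base as position i. The first element is always 1 and the row lies
in (0, 1]. The frequency row is the only non-local feature in the package:
its value at a position depends on the prefix, which lets the network see
composition drift along the window. The source formulation of this quantity
is typeset ambiguously in the literature; we implement the standard
cumulative-density reading (count of the focal base in the prefix, divided
by the prefix length), which is the only reading that yields a per-position
profile.

Ambiguity codes (N, etc.) are rejected rather than imputed, because both
encodings are defined on the four-letter alphabet only; silently imputing
would corrupt the one-hot contract. Lowercase input is accepted and
uppercased. Window length defaults to 41 but is configurable, so other
fixed-length benchmarks load unchanged.

## Architecture

The network stacks eight components: a one-dimensional convolution (16
filters of length 4, ELU activation, L2 penalty 1e-4 on weights and bias),
group normalization (4 groups), max pooling (window 4), dropout (rate
0.25), flatten, a dense layer (32 units, ELU, same L2 penalty) and a single
sigmoid output. Each convolution filter acts as a learned motif detector
scanned along the window. A `large` variant doubles capacity (32 filters,
64 units) for datasets two orders of magnitude larger.

Numerical and structural choices that the published description leaves
open were fixed as follows, each exposed as a configuration parameter where
reasonable:

* **Padding.** Valid (no) padding, stride 1. Filters are motif detectors;
  zero-padding would have them respond to fabricated boundary context. The
  convolution output is therefore 41 − 4 + 1 = 38 positions.
* **Pooling.** Non-overlapping windows (stride = pool size), floor
  semantics: 38 positions pool to 9, the trailing 2 are dropped.
* **Normalization placement.** The component order is taken literally:
  ELU belongs to the convolution component and group normalization is the
  second component, i.e. normalization *after* activation. This is
  unconventional (normalization usually precedes the nonlinearity), so
  `model_config(gn_position = "before_activation")` exposes the
  conventional order; the default is the literal one. The backward pass of
  both variants is verified against numerical gradients.
* **Group-norm epsilon** is 1e-3; statistics are per sample over each
  group's channels × positions, using the population variance.
* **ELU α = 1**; weight initialization is Glorot-uniform under a caller
  seed; biases start at 0, normalization scale/shift at 1/0.
* **Decision rule.** A window is called positive when the output
  probability strictly exceeds 0.5; exactly 0.5 goes to the negative class
  (only the strict inequalities are defined by the decision rule, so the
  boundary needed a convention).

With the defaults this yields 272 + 32 + 4640 + 33 = 4,977 trainable
parameters, a number the test suite recomputes from closed-form arithmetic
and compares against the allocated arrays over a grid of configurations.

The whole engine — forward pass, backpropagation (including through the
per-sample group-normalization statistics and the max-pool argmax routing)
and the SGD-with-momentum update — is implemented in vectorized base R.
A batch is held as a filters × (positions · samples) matrix, and the
convolution is an im2col gather followed by one dense multiply, which keeps
the per-batch cost at a handful of small BLAS calls.

## Training recipe

Optimization is plain SGD with momentum 0.95 (velocity
v ← μv − η∇, w ← w + v; not Nesterov) at initial learning rate 0.005 on
binary cross-entropy plus the L2 penalty, for at most 100 epochs of batches
of 32, reshuffling each epoch under the run seed. An incomplete final batch
is used as-is. Dropout is inverted (activations scaled by 1/keep during
training) and inactive at inference, so prediction is deterministic.

Three callbacks govern the run, with two deliberately different monitors:

* **Early stopping** watches validation *accuracy* and halts once
  `patience = 30` epochs pass without strict improvement of the running
  best (zero minimum delta).
* **Checkpointing** keeps the weights of the best-validation-accuracy
  epoch; the returned model always carries those, not the final-epoch
  weights, which makes the question of whether early stopping "restores"
  weights moot.
* **Reduce-on-plateau** watches validation *loss*: after
  `patience = 20` epochs without improvement the rate is multiplied by
  0.1, the plateau counter resets (the best-so-far does not), and the new
  rate takes effect from the next epoch. There is no rate floor by default
  (`min_lr = 0`).

The counter semantics follow the dominant deep-learning-framework
convention, and the standalone functions `early_stopping_decision()` and
`reduce_lr_on_plateau()` replay them on recorded traces; a test confirms
the training loop and the replays agree epoch for epoch on real runs. The
configured patiences may exceed `max_epochs` (the callbacks then simply
never fire); this is intentional so short diagnostic runs can keep the
default patiences.

With a fixed seed a training run is exactly reproducible in a given
BLAS/R environment: all stochastic sources (shuffling, dropout,
initialization) flow from the seed, and execution is single-threaded.

## Evaluation protocol

`run_cross_validation()` implements k-fold cross-validation with three
roles per iteration: fold i is the test set, the cyclically next fold the
validation set, the remaining k − 2 folds the training set. The rotation
rule is a fixed convention (the protocol requires *a* held-out validation
fold but does not dictate which), and the plan is fully determined by
(n, k, seed). Folds are stratified by label by default: the benchmarks are
exactly class-balanced, and stratification prevents degenerate single-class
validation folds at small n; `stratify = FALSE` gives the plain random
partition. Across iterations the test folds partition the data, so each
sample is tested exactly once.

Metrics are accuracy, sensitivity, specificity, MCC and ROC AUC. MCC with
a zero denominator factor is defined as 0 (the no-information value; it
also equals the Pearson correlation of the two binary label vectors, which
the tests exploit as an independent oracle). The ROC is built by a
threshold sweep that groups tied scores into a single step and is
integrated by the trapezoidal rule, making the AUC equal to the normalized
Mann–Whitney statistic with ties counting one half. Fold metrics are
averaged arithmetically; pooled-prediction metrics are reported alongside
because it is ambiguous which convention a given published AUC uses — with
equal fold sizes the averaged and pooled accuracies coincide exactly.

`cross_species_evaluate()` scores a frozen model on an independent dataset
with no weight update, the protocol used to ask whether a model trained on
one species (or one motif regime, in the synthetic setting) transfers to
another.

## The synthetic benchmark generator

`generate_dataset()` emulates the *shape* of the rice 6mA benchmarks:
balanced classes, fixed 41-bp windows, adenine-centered. Class structure is
purely statistical — positives carry a short motif (default `GAGG`)
planted at a fixed offset two positions right of the center with
probability `planting_probability`; the offset is deliberately off-center
so the convolution must learn position-local context rather than reading
the central base. The center-adenine rule applies to *both* classes, as in
the real benchmarks, whose negatives are unmethylated adenine-centered
windows; consequently `planting_probability = 0` makes the class
distributions exactly identical, giving a proper null dataset. The
background is i.i.d. uniform by default; a first-order Markov background is
available for harder fixtures. Defaults (uniform background, a distinctive
4-mer matching the filter length, full planting) were chosen once as a
regime where a position-weight-matrix scan — and hence any adequate
implementation of the network — separates the classes almost perfectly.

What the generator does *not* emulate: real 6mA sequence preferences are
soft, distributed and partially redundant rather than a single planted
k-mer; real backgrounds have composition bias and repeat structure; and
real negative sets carry ascertainment quirks. Passing the end-to-end
tests therefore demonstrates that the implementation trains, checkpoints
and evaluates correctly — not that it reaches any particular accuracy on
biological data, for which the README's external-benchmark recipe applies.

## Validation problem sizes

The package validates itself end to end on an 800-sequence planted-motif
benchmark (400 + 400): 10-fold cross-validation with the full default
recipe reaches mean test accuracy ≥ 0.95 and mean AUC ≥ 0.97, while a
5-fold run on the `planting_probability = 0` null stays at chance
(mean AUC within [0.4, 0.6]). These sizes were chosen as the smallest at
which the separable/null contrast is statistically unambiguous; the same
quantities are recomputed by `scripts/acceptance.R`.

## Known limitations

* Pure-R training is adequate for benchmark-scale data (hundreds to a few
  thousand windows) but not for the 308,000-window regime, where a
  compiled backend would be the natural extension.
* Exact run-to-run reproducibility holds within one R/BLAS build;
  across different BLAS implementations results may differ in the last
  floating-point digits.
* The model offers no feature attribution; filters can be inspected via
  `coef()` but no saliency machinery is included.
* Only the two described encodings are implemented; k-mer or
  pseudo-nucleotide-composition schemes are out of scope.
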