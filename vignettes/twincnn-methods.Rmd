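---
title: "Twin convolutional networks for drug response prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin convolutional networks for drug response prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twincnn)
```

## The problem

Phenotypic screens such as the GDSC panel measure, for hundreds of
anti-cancer compounds and around a thousand cancer cell lines, the
concentration at which a drug inhibits a cell population's growth by half
(IC50, stored as a natural-log value). Predicting these responses for
unmeasured drug–cell pairs supports drug repurposing and prioritization.
`twincnn` models the response directly from the drug's *structure* — its
canonical SMILES string — and from the cell line's binary genomic profile
(mutation states and copy-number alterations), rather than from
precomputed molecular descriptors.

## Input representations

**Drugs.** A SMILES string is tokenized into chemically meaningful
symbols: bracket atoms like `[Au]` or `[nH]` are single tokens, the
two-letter halogens `Cl` and `Br` outside brackets are single tokens, and
every other character stands alone. The paper-gap here is real — "symbol"
is not a self-defining notion — and this rule is chosen because a
convolution that slides along the string only makes chemical sense when
each channel is one element or structural mark, not half of one. The
corpus vocabulary is the sorted set of distinct tokens plus a dedicated
padding token (a literal space). Each drug becomes a binary
`n_tokens x max_len` grid: column *j* activates the row of the token at
position *j*, columns past the end of the molecule activate the padding
row, so every column sums to exactly one. On the GDSC panel this grid is
72 x 188; both numbers are corpus properties, never constants of the
package.

**Cell lines.** A binary feature vector (by default up to 735 entries on
the GDSC export). Cell lines with fewer defined features than the
catalogue are removed rather than imputed, mirroring the panel's own
990 → 948 filtering; imputing binary genomic calls would fabricate
genotypes.

**Responses.** Log-IC50 values x are mapped to (0, 1) by
`1 / (1 + exp(x)^(-0.1))`, a logistic in x with slope 0.1. The gentle
exponent spreads the typical IC50 range roughly uniformly over the unit
interval; the map is strictly increasing and exactly invertible
(`denormalize_ic50()`), so predictions can always be reported back on the
log scale.

## The model

Two 1D convolutional branches with identical layout process the two
inputs:

* three layers, each: convolution of width 7, stride 1, followed by max
  pooling of width 3, stride 3;
* 40, 80 and 60 channels respectively;
* the drug branch treats each vocabulary row as an input channel; the
  cell branch reads its feature vector as a single channel.

Convolutions use length-preserving (same) zero padding and pooling uses
ceiling windows. This choice is load-bearing: with an input of length 188
the per-layer lengths go 188 → 63 → 21 → 7, giving a flattened drug
representation of 7 x 60 = 420 dimensions, and 735 → 245 → 82 → 28 gives
1680 dimensions for cells — the widths of the learned feature spaces this
architecture is known by. Valid padding would give 240 instead of 420 and
is available via `branch_config(padding_mode = "valid")`.

The two flattened branch outputs are concatenated (2100 dimensions at
full scale) and fed to a fully connected head of three hidden layers with
1024 rectifier units each and dropout 0.5 during training. The output
unit is logistic, because the labels live in (0, 1); hidden activations
are rectifiers (the reference description names no nonlinearity, and
rectifiers are the standard choice for deep convolutional regressors).
The output layer is initialized with small weights (sd `1/n_in`) so the
initial predictions sit near 0.5, the center of the label range; with a
generic He initialization the logistic output starts saturated for many
inputs, gradients vanish or explode, and for some seeds training
collapses to a constant predictor. Hidden layers use He initialization.

Training minimizes mean squared error with Adam (default learning rate
1e-4, batch size 128 — both configurable; the reference description says
only "gradient descent"). After every epoch the validation RMSE is
computed with dropout disabled; training stops when it has not decreased
for 10 consecutive epochs (the patience), and the parameters of the best
validation epoch are returned. Pool width 2 is reported to score higher
but destabilize training, so the stable width 3 is the default and the
aggressive setting remains available through `branch_config()`.

The network itself — im2col convolutions backed by BLAS matrix
multiplication, max pooling with argmax routing, inverted dropout, Adam —
is implemented in this package (R with a few C++ kernels for the gather/
scatter loops). Backpropagation is verified against central finite
differences in the test suite, and the architecture arithmetic of
`branch_output_dim()` is property-tested against actual forward passes of
the layer stack.

## Evaluation protocols

* **Pair split (rediscovery)**: known pairs shuffled 80/10/10 into
  train/validation/test. Drugs and cells may appear on both sides; only
  pairs are held out.
* **Drug-blind / cell-blind**: whole entities held out — every known pair
  of 10% of drugs (or cells) forms the test set; the remaining pairs
  split 90/10 into train/validation. The reference panel counts (23/223
  drugs, 94/948 cells) round a 10% fraction in opposite directions, so
  the API takes an explicit `n_test_entities`, with fraction-based
  rounding as fallback.
* **Tissue-blind**: all pairs of one tissue type held out; 13 coarse
  tissue types rather than 49 sub-tissues, which maximizes the distance
  between training and test distributions.
* **Learning curves**: the training set of a fixed split is subsampled.
  Subsets at a common seed are nested (a fixed random order is truncated
  at each fraction), so curve points differ by training size only.

`validate_split()` checks disjointness and entity leakage and is part of
the public API, not only of the tests. Metrics are the coefficient of
determination `R2 = 1 - SS_res/SS_tot`, Pearson correlation (population
moments; identical to the sample-moment form), and RMSE; repeated runs
are summarized by mean and top quartile (75th percentile, linear
interpolation).

## The synthetic corpus

Real GDSC data cannot be redistributed with the package, so a seeded
generator emits desk-scale corpora in exactly the CSV schemas the loaders
consume. Default conditions: 60 drugs, 120 cell lines, 64 binary features
(Bernoulli 0.3), SMILES-like token strings of 20–40 tokens over a
16-token alphabet, 85% of pairs observed, 40% of observations flagged
below the maximum screening concentration.

The response is a planted structure–activity function on the log scale:
three short token motifs planted into drugs (presence probability 0.4,
effects −3, +2, −1.5), eight non-zero feature effects (±2, ±1.5, ±1,
±0.5), one motif × feature interaction of strength 1, and Gaussian noise
(sd 0.4). Two design points matter. First, the drug signal sits in
*positional motifs*, not in global symbol composition, so recovering it
genuinely requires the convolutional drug branch. Second, noise is added
on the log-IC50 scale before normalization, where assay noise plausibly
lives. Effect sizes were chosen once so that the deterministic part
dominates the noise (signal sd ≈ 2.6 vs noise sd 0.4 on the log scale)
— a strong-signal regime appropriate for verifying that the machinery
learns, not for estimating real-data performance.

What the generator does **not** emulate: chemically valid molecules,
GDSC's marginal distributions, correlated genomic features, tissue
structure in the features, heteroscedastic assay noise. Passing tests on
this corpus therefore demonstrate correctness of the pipeline and
learnability of convolution-detectable structure; they do not forecast
the R² ≈ 0.83 / Rp ≈ 0.91 reported at full scale on GDSC v6, which
requires the real download and hours of training and is deliberately out
of the desk-scale envelope.

## Desk-scale problem sizes

The shipped tests and the reproduction script run the full-scale
*architecture* (the 40/80/60 stack with the 3 × 1024 head, ~2.5M
parameters on the default corpus) but desk-scale *budgets*: the default
synthetic corpus above, 3–6 training epochs at learning rate 1e-3 for the
learnability checks, five seeds for the pair vs drug-blind comparison,
and tiny 2-layer configurations for pure plumbing tests. On the default
corpus one epoch processes ~4,900 training pairs in ~39 minibatches.
These profiles were chosen as the smallest runs that make the qualitative
claims stable across seeds: the planted signal is recovered (held-out
Rp > 0.5 within a few epochs), permuted labels are not learnable
(|R²| < 0.1), and drug-blind evaluation scores below pair-level
evaluation in the median — the same ordering the full-scale study
reports, where blind-test performance "drops significantly".

## Numerical choices and edge cases

* Ceiling pooling windows may overhang the sequence end; overhanging
  positions are simply absent from the window (equivalently, padded with
  −∞). Pooling ties route the gradient to the first maximum.
* Inputs longer than `max_len` are rejected, never truncated — truncation
  would silently destroy molecular structure.
* `evaluate_predictions()` refuses constant labels (R² and Rp are
  undefined); constant *predictions* leave only Rp undefined, which is
  returned as `NA` with a warning so the null model can still be scored.
* Training, splitting and generation consume explicit integer seeds;
  repetition *i* of an experiment uses `base_seed + i - 1`, so any single
  repetition can be reproduced in isolation.
* The below-max_conc flag defaults to 1 when the column is absent from an
  IC50 file, so tables without screening-concentration annotation behave
  as fully verified.

## Known limitations

* No GPU path and no multi-threaded training; the engine targets
  single-CPU desk-scale corpora. Full-scale GDSC training is possible in
  principle but slow.
* The drug-blind gap on the synthetic corpus is smaller than on real
  data: with only three motifs, held-out drugs usually contain motifs
  seen in training, whereas real chemical novelty is harsher.
* SMILES canonicalization is out of scope; inputs are assumed canonical.
  Uncanonical inputs are encoded as given.
* Row-shuffle invariance of training is exact only as a *forward*
  symmetry (permuting input rows together with the first-layer kernels);
  as a statement about independently initialized training runs it is an
  empirical finding probed by `run_perturbation()`, not a theorem.
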