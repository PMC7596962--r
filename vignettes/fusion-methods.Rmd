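---
title: "Multi-modal patient representations: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal patient representations: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ehrfusion)
```

## The prediction problem

An intensive-care admission produces three very different kinds of data in
its first 24 hours: static facts known at admission (age group, gender,
marital status, ethnicity, insurance, admission type), irregularly sampled
numeric observations (7 vital signs and 19 laboratory tests), and
free-text clinical notes of several categories (Nursing, Nursing/Other,
Physician, Radiology). `ehrfusion` learns a single patient vector from all
three modalities and uses it for three binary risks: in-hospital
mortality, 30-day readmission, and long length of stay (a stay of more
than 7 days).

The package implements two fusion networks plus the machinery around them:
cohort filtering and preprocessing, PV-DBOW note embeddings, flattened
baselines (logistic regression, random forest), a multi-run evaluation
protocol with modality ablations, and a synthetic cohort generator so the
entire pipeline runs and is testable without access to a real clinical
database.

## Model

Let $z_{static}$ be the concatenated one-hot encoding of the static
fields, $z_{temporal}$ the encoding of the $24 \times 26$ hourly signal
grid, and $z_{text}$ the encoding of the admission's sequence of note
embeddings. The patient representation is the concatenation

$$z_p = [z_{static};\, z_{temporal};\, z_{text}],$$

of size $d_{static} + d_{temporal} + d_{text}$, restricted to whichever
modalities are active (that restriction is the ablation mechanism: model
inputs $U$, $T{+}S$, $U{+}T{+}S$ and so on). A single sigmoid unit maps
the representation to an event probability

$$o = \sigma(W z_p + b),$$

trained by minimizing the binary cross-entropy
$L = -\bigl(y \log o + (1-y)\log(1-o)\bigr)$ with Adam. Each task is
trained independently.

Two encoder families are provided:

* **Convolutional variant.** The temporal grid passes through two blocks
  of 1-D convolution over time (variables as channels), ReLU and width-2
  max-pooling, then is flattened. Note sequences pass through two
  convolution+ReLU blocks with one intermediate max-pooling; the final
  representation is a *masked global max-pool over time*, so padded
  positions can never contribute.
* **Recurrent variant.** The temporal grid feeds a 2-layer LSTM with
  dropout on the non-recurrent connections (between layers and before the
  output); the last hidden state of the top layer is $z_{temporal}$. Note
  sequences feed a bidirectional LSTM; per-step forward and backward
  hidden states are concatenated $h_i = [\overrightarrow{h_i};
  \overleftarrow{h_i}]$ and max-pooled over the valid time steps.

The networks, their gradients and the Adam optimizer are implemented in
the package itself in vectorized R (the linear algebra is delegated to
BLAS); correctness is pinned by numerical-gradient tests rather than by
reliance on an external framework.

### Handling variable-length note sequences

Note sequences are truncated/padded to a fixed `L_max` with a prefix
mask. Two details keep padding inert:

* the backward direction of the BiLSTM consumes each admission's notes
  reversed *within* its valid prefix (the analogue of packed sequences),
  so trailing padding is never folded into a real state;
* both note encoders pool only over positions whose receptive field
  touches at least one real note.

Consequently the note encoding is invariant to the choice of `L_max`
whenever the real sequence fits without truncation — exactly, not
approximately. For the convolutional path "fits" accounts for the
downsampling pyramid: with kernel $k = 3$ an admission with at most
$2\,\bigl(\lfloor (L_{max}-k+1)/2 \rfloor - k + 1\bigr)$ real notes
(10 notes at $L_{max} = 16$) encodes identically at any larger `L_max`.
An admission with no eligible notes encodes to the zero vector.

## Preprocessing

* **Cohort filter.** Admissions with age < 18 years, length of stay
  < 1 day, no temporal observations or no notes are removed.
* **Age groups.** Ages are bucketed into [18,25), [25,45), [45,65),
  [65,89), [89,∞). The bucket boundaries are printed as open tuples in
  the clinical literature without a boundary rule; half-open intervals
  make every adult age land in exactly one bucket.
* **Hourly binning.** Cell $(h, v)$ of the temporal grid is the
  arithmetic mean of all observations of variable $v$ in hour $h$ of the
  admission; observations at offset ≥ 24 h are discarded. Multiple
  observations with identical timestamps all enter the mean.
* **Normalization.** Per-variable min–max statistics are fit on the
  *training split only* and applied everywhere; held-out values outside
  the training range are clipped to [0, 1]. A degenerate range
  (max = min) maps to 0, indistinguishable from "no information". After
  normalization, unobserved cells are imputed with exactly 0 (imputation
  after scaling makes 0 the post-normalization floor; doing it before
  would let imputed zeros distort the per-variable minima).
* **Unseen categories.** One-hot layouts are frozen from the training
  split; a category unseen at training encodes as an all-zero block
  rather than an error.
* **Baseline aggregations.** For each variable, (mean, min, max, sd,
  count) over the observed hourly cells of the *raw* grid; sd uses the
  population formula (a single observation has sd 0) and a variable with
  no observations contributes (0, 0, 0, 0, 0). The aggregation block is
  standardized with a train-fit scaler before entering the baselines.

## Note embeddings

Each note is mapped to a 200-dimensional paragraph vector with PV-DBOW
(the document vector predicts the note's tokens through negative
sampling; 5 noise words from the unigram distribution to the 0.75 power).
Defaults: 30 epochs, initial learning rate 0.025 with a per-epoch
decrement of 0.0002. The stated decay constant is ambiguous between a
per-epoch decrement and a terminal floor; we read it as the decrement,
which reaches a similar terminal rate over 30 epochs either way. The
trainer is single-threaded C++ with its own deterministic generator, so a
seed fixes every embedding bit-for-bit.

The model is fit on the training split's notes only. *All* notes —
training ones included — are then embedded by inference against the
frozen token matrix: inference-produced vectors have a slightly different
scale and geometry than co-trained document vectors, and mixing the two
(lookup for training notes, inference for held-out notes) puts the
training and evaluation inputs of the downstream network in measurably
different distributions, which we observed as validation degradation from
the first epoch. Inference is seeded from a hash of the note's token ids,
so it is a pure function of content. Notes with no in-vocabulary tokens
embed to the zero vector.

## Evaluation protocol

Metrics are F1 (threshold 0.5), AUROC (rank form: the probability a
positive outranks a negative, ties half-counted) and AUPRC
(interpolation-free step summation over distinct thresholds). Each
benchmark configuration is run `n_runs = 5` times with different data
splits (70/10/20 at the admission level); reports carry per-metric means,
95% t-distribution confidence intervals
($\bar{x} \pm t_{0.975,n-1}\, s/\sqrt{n}$) and a pairwise p-value matrix
of AUROC between all (model, modality set) pairs. The t-tests are
unpaired Welch tests: the flavour is not pinned by the protocol we
mirror, and Welch is robust to the unequal variances typical across model
families; the matrix is symmetric with unit diagonal, and a pair of
zero-variance run vectors gets p = 1 when the means agree and 0
otherwise. Run seeds are drawn deterministically from a master seed, so a
report is reproducible byte-for-byte.

## The synthetic cohort generator

The generator emulates the *statistical shape* the method consumes, not
physiology or clinical language. Each admission draws static fields from
realistic marginals; three latent factors carry the outcome signal:

* $g_S$: a standardized static summary (age plus an emergency-admission
  shift),
* $g_T$: a severity factor loading on every temporal variable (per-
  variable loadings in [0.3, 0.8], values on the marginal scale of the
  standard ICU panel),
* $g_U$: a note factor tilting each note's tokens toward a risk topic
  (the vocabulary is split into risk and background halves with Zipf-like
  within-topic frequencies).

The latent risk is $r = w_S g_S + w_T g_T + w_U g_U + \epsilon$ with
$\epsilon \sim N(0, 0.5^2)$, and each task label is Bernoulli with
probability $\sigma(\alpha_{task} + r)$, the intercept calibrated by
bisection so the cohort-mean probability equals the configured prevalence
(defaults 9.6% mortality, 5.7% readmission, 49.9% long stay — the base
rates of a large adult ICU cohort). Length of stay is drawn consistently
with the long-stay label. Observation times are uniform within each hour
with per-(hour, variable) Bernoulli missingness (default 50%);
observation values mix the severity factor with independent noise.
Generated admissions are eligible by construction (adult, ≥ 1 day,
≥ 1 observation, ≥ 1 note); the cohort filter is exercised by handcrafted
records in the tests.

What passing tests on this generator do show: the pipeline recovers
cross-modal signal it is supposed to recover, ignores data it must ignore
(post-24 h records, held-out splits, padding), and reproduces the
qualitative ablation ordering when signal is genuinely split across
modalities. What they cannot show: performance on real clinical notes and
signals, whose token statistics, missingness mechanisms and label noise
are far richer — no claim of clinical validity follows from the synthetic
results.

## Regularization

Dropout sits on the non-recurrent connections of the recurrent paths
(between the two temporal LSTM layers and before their output), on the
flattened temporal CNN output, and — in both variants — on the note
encoder's embedding input and pooled output. The note-path rate is
configurable separately (`note_dropout`): the 200-dimensional embedding
path holds most of the trainable capacity and is the first thing to
memorize a small training split, so it typically wants a substantially
higher rate than the temporal path. Rates are design parameters of this
package (defaults 0.2); the placement on non-recurrent connections
follows the reference architecture, its extension to the convolutional
and note paths is ours.

## Scaled benchmark configuration

The reference protocol (tens of thousands of admissions, 50-epoch cap,
Adam at learning rate $10^{-4}$, batch 64) implies on the order of $10^4$
parameter updates. The package's self-contained experiments run on
synthetic cohorts of ~2000 admissions for ≤ 15 epochs, which with the
reference batch size would allow only ~330 updates — too few for the
encoders to leave their initialization, and the regime where the networks
memorize 1400 training admissions within a few epochs. The scaled
protocol therefore uses batch 16 with learning rate $3\times10^{-3}$
(approximately preserving the update count), compact encoders
(64 temporal channels, hidden sizes 16–32, `L_max = 8` matching the
generator's 2–8 notes per admission), asymmetric dropout (0.1–0.3 on the
temporal path, 0.6 on the note path), and checkpoint selection by
validation AUROC within the 15-epoch cap. These are configuration values of the scaled experiment, not changes
to the package defaults, which remain the reference values. The
acceptance experiments use signal weights $w_S = w_T = w_U = 2$ — strong
signal in every modality — so that the combined-modality Bayes ceiling is
clearly above any single modality's and the ablation ordering is a
property of the data, not of noise.

## Numerical choices and edge cases

* Probabilities entering the cross-entropy are clamped to
  $[10^{-12}, 1-10^{-12}]$.
* Max-pooling ties resolve to the earliest position; pooling windows mix
  padded positions only where the receptive field also contains real
  data (see above).
* AUROC/AUPRC require both classes / at least one positive and fail
  loudly otherwise; F1 is 0 by convention when there are no predicted or
  no true positives.
* The degenerate split (fewer than 10 admissions) and the empty training
  set are validation errors, not silent misbehaviour.
* All stochastic components (generator, splits, embedding trainer and
  inference, network initialization, shuffling, dropout, random forest)
  are seeded; two runs from one configuration are byte-identical, which
  the test suite asserts on serialized reports.

## Known limitations

* The ridge-penalized logistic baseline is fit by coordinate descent to
  convergence while the networks get a fixed small step budget; at
  synthetic scale the baseline is therefore a strong opponent, just as
  logistic regression is reported to be on real data.
* PV-DBOW here has no frequent-word subsampling and no hierarchical
  softmax; corpus sizes in scope do not need them.
* The convolutional note encoder's `L_max` invariance has the capacity
  precondition derived above; sequences longer than the pipeline
  capacity are truncated by design.
* Training is single-threaded by construction (determinism over speed);
  the experiment sizes in the package are chosen to fit that budget.
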