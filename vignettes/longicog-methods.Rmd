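---
title: "Methods: longitudinal cognitive-status prediction with longicog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal cognitive-status prediction with longicog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

`longicog` predicts a person's cognitive status — cognitively normal
(Control), amnestic mild cognitive impairment (aMCI), or Alzheimer's disease
dementia (AD) — 3 to 10 years after their most recent clinic visit, from the
longitudinal record of visits before that point. Each visit contributes two
kinds of measurements: per-visit cognitive test scores ("cognition"
features) and health/history variables ("health" features), many of which —
family history above all — never change across visits. Records are short
(2–10 years, roughly annual visits), raw codings are strictly positive, and
missingness is pervasive, both cell-wise within a visit and systematically
for all visits of a participant.

Long-horizon prediction is the hard version of this task: most published
models target 1–3 years. Two premises drive the design. First, AD pathology
begins years before symptoms, so a prodromal signal should be present in the
record long before conversion. Second, *intrapersonal variability* — change
relative to a person's own baseline — is an early marker of MCI, so deviation
from the first visit deserves its own representation rather than being folded
into population-normalized scores.

## Data pipeline

**Eligibility.** `filter_eligibility()` keeps patients with at least two
dated visits whose first-to-last span lies in [3, 10] years. Spans are
fractional years under a 365.25-day convention; the boundaries are inclusive.
Patients who ever progress to a non-AD dementia are removed wholesale
(`drop_non_ad_and_reversions()`).

**Prefix augmentation.** A record with visits $x_1, \dots, x_t$ becomes the
$t-1$ training pairs $(\{x_1..x_{j-1}\},\, x_j)$ for $j = 2..t$: every proper
prefix predicts the diagnosis at the next visit. This multiplies the training
data and exposes the model to horizons of roughly 1–10 years. Pairs whose
target is *less* severe than the last prefix label (reversions, order
Control < aMCI < AD) are dropped individually (`drop_reversion_pairs()`);
the patient's other pairs survive.

**Evaluation pairs.** At evaluation time augmentation is *not* applied:
the target is the patient's last visit and the prefix is every visit dated
3–10 years before it (`build_eval_pairs()`), zero or one pair per patient.
Each evaluation prefix is by construction a subset of that patient's
training-prefix union, so train and test distributions are aligned while the
patients themselves never overlap. When several non-final visits could also
serve as targets we still use only the last visit — one test point per
patient keeps the evaluation unit unambiguous.

**Balancing and folds.** Stable controls dominate such cohorts (a constant
"Control" predictor would be over 90% accurate unbalanced), so
`balance_classes()` down-samples patients — before augmentation, at the
patient level — to the minimum final-status class count, uniformly without
replacement. `split_folds()` then assigns *patients*, never samples, to
folds (sorted ids, seeded permutation, round-robin), so all pairs derived
from one patient share a fold and no validation information leaks into
training.

## Feature engineering

Two normalizations are applied, producing the model's two input sets.

**Baseline.** Values are z-scored against the cognitively normal population
of the *training* split: `fit_control_stats()` pools all visits of
training-split patients whose final status is Control (sample SD, $n-1$).
Validation data are normalized with the same statistics — never refitted.
Features with fewer than two observed control values, or zero variance, are
flagged and passed through as missing. The baseline vector of a pair is the
last prefix visit's z-scored values — the most recent snapshot of the
patient.

**Change.** `change_ratios()` divides each prefix visit's *raw* value by the
same feature's first-visit raw value, giving the matrix
$x'_j(t) = x_j(t) / x_j(1)$: column 1 is identically 1 where observed and
later columns measure proportional deviation from the patient's own
baseline. Ratios are taken on raw, not z-scored, values — a ratio of
z-scores is ill-defined near zero, while raw codings are strictly positive.
A zero or missing denominator masks the whole feature row rather than
producing infinities. Static features are masked out of the change set
entirely (`mask_static_in_change()`): a constant ratio of 1 is
uninformative, and they remain available in the baseline set.

Missingness is carried as explicit binary masks from the raw data through
every step; the $-1$ sentinel is injected only *inside* the encoders, after
engineering. This matters because z-scored values are no longer strictly
positive: substituting $-1$ into raw data and then normalizing would break
the "missing values are the only negatives" property, whereas an explicit
mask plus late sentinel keeps the intent intact regardless of the scale the
encoder sees.

## The two missing-data encoders

**Masked transformer attention.** Each scalar feature is embedded by a
shared $1 \to H$ affine map; three layers of 4-head scaled-dot-product
self-attention run across the feature axis, with missing features excluded
from every softmax (their logits set to $-\infty$). Each feature's new
representation is thus a weighted average over the *available* features
only; the $K \times H$ output is mean-pooled into one $H$-vector. The
printed form of the attention equation in the source has inconsistent
subscripts; the implementation is the standard masked attention that its
"rolling average across available features" description defines. Pooling
over feature positions (mean) and the absence of feed-forward sublayers keep
the encoder exactly as specified — attention layers only.

**Linear-attention reweighting.** The lighter alternative: missing values
are set to $-1$ (legitimate values are positive, so missingness is linearly
separable in input space); each scalar is embedded and passed through
$f(x) = S \cdot \phi(T \cdot x)$ with learnable $S, T \in \mathbb{R}^{H
\times H}$ and $\phi = \mathrm{ReLU}$; the $H$-vector is reduced to a scalar
score by a mean and made strictly positive by a softplus; scores are
normalized to weights summing to exactly 1; and the output is $x'_k = x_k
w_k$, projected $K \to H$ by one affine map. The scalar reduction (mean),
the positivity transform (softplus) and $\phi$ (ReLU) are design choices the
source leaves open; softplus guarantees the weight denominator never
vanishes, and positivity makes the weights interpretable as a distribution
over features. At equal hidden size this encoder has strictly fewer
parameters than the transformer ($2H^2 + KH + H$ vs. $12H^2$ beyond the
shared embedding), asserted by direct count in the tests.

Both encoders are *exactly* invariant to the stored values of masked cells
— the test suite perturbs masked cells with arbitrary finite values and
requires a bit-identical output. If every feature is missing, both return a
flagged zero vector rather than NaN.

## Late-fusion classifier

The change matrix (minus its uninformative first column) feeds a 3-layer
LSTM: each timestep's input is the masked change vector (missing cells as 0)
concatenated with its mask. Cell and hidden states start at zero and the
final top-layer hidden state, passed through a bias-free $H \times H$
projection, is the temporal encoding. A bias-free linear gate
$\delta = w \cdot \mathrm{temporal}$ mixes the branches:

$$\mathrm{fused} = \delta \cdot \mathrm{Temporal} + (1 - \delta) \cdot \mathrm{Baseline}.$$

Neither the gate nor the post-temporal projection carries a bias, and
$\delta$ is deliberately *not* squashed by a sigmoid: a patient with a
single visit has no change features, the LSTM hidden state stays zero, and
$\delta = 0$ exactly, so the model reduces bit-for-bit to the pure baseline
path. A sigmoid would map zero to 0.5 and destroy this property; the price
is that the mix is affine rather than convex, which we accept and document.
The fused encoding passes through dropout (0.5, training mode only), an
$H \to H$ affine map, ReLU, an $H \to 3$ affine map and a softmax; training
minimizes mean cross-entropy computed from logits.

Because no deep-learning framework is part of this package's stack, the
forward and backward passes are implemented directly in R. The backward pass
is verified in the test suite against central finite differences on both
arms, with and without the temporal branch, at a relative error of about
$10^{-5}$ — the finite-difference noise floor.

## Training and evaluation protocol

`train_config()` defaults follow the published protocol: batch size 64, up
to 55 epochs, AdamW (decoupled weight decay 0.01), learning rate
$5\times10^{-5}$ for the transformer arm and $5\times10^{-6}$ for the
linear arm — values tuned at hidden sizes 512 and 2048 on the full-scale
task. Early stopping watches dev-set accuracy with patience 10 and restores
the best weights; by default the dev set is the held-out fold itself (the
protocol names no third split). This is optimistic: selecting the best of
many noisy epoch accuracies on a small evaluation fold inflates the
reported accuracy — visibly so on null cohorts, whose measured accuracy can
drift a few points above chance purely through this selection.
`crossval(nested_dev_frac = ...)` carves a patient-level nested dev split
out of the training patients instead, giving unbiased held-out estimates at
the cost of training data; the default 0 matches the protocol as published. Desk-scale experiments in
this package use hidden size 32 and a learning rate of $3\times10^{-3}$,
chosen once as appropriate for that model size; the small hidden size makes
the paper-scale rates undertrain within 55 epochs.

`crossval()` partitions patients into $k = 10$ folds, trains on nine and
evaluates on the held-out fold's evaluation pairs. Per fold it reports the
confusion matrix, overall accuracy, per-class one-vs-rest precision, recall
and accuracy (class under test positive, everything else negative), and
rank-based (Mann–Whitney, midrank ties) one-vs-rest AUC with a macro
average. Across folds each metric is summarized as mean ± the two-tailed
95% Student-t band $t_{0.975,k-1}\, s/\sqrt{k}$. Predictions are argmax
probabilities with ties broken toward the less severe class. Folds with no
evaluation pairs are excluded from the bands with a warning.

## The synthetic cohort simulator

Restricted clinical registries cannot be bundled, so `simulate_cohort()`
generates structurally matched cohorts: 2–8 visits per patient at roughly
annual spacing rescaled to a span drawn from 1–11 years (covering both
eligible and ineligible records so the filters have work to do), strictly
positive shifted-log-normal feature codings, cell-level MCAR missingness
(default 10%; `inject_missingness()` adds a visit-block mechanism that
silences a feature for all of a patient's visits), and three trajectories
in configurable proportions.

Converters follow a change-point model. Labels are Control before a random
conversion visit and the converted state after (AD converters may pass
through an aMCI stage). Cognition features of converters carry three
signal components, all scaled by `effect_size` $\times$ the feature's
nominal control SD and by a severity weight $w$ (1 for AD converters, 0.5
for aMCI, making aMCI trajectories intermediate): a constant prodromal
shift (weight 0.5), a slow linear decline beginning at the first visit
(ramping to 0.5), and an accelerated decline after the change point
(ramping to 0.5). The first-to-last drift therefore totals exactly
`effect_size` SD for AD converters. The early components encode the
premise that pathology precedes diagnosis; without them the 3–10-year
evaluation window — which largely predates the change point — would be
uninformative by construction and no model could beat chance. Static
health features of converters are shifted upward by $0.4 \times$
`effect_size` SD $\times\, w$ (elevated risk coding). With `effect_size =
0` every feature is independent of the labels; `null_cohort()` forces
this, providing the chance-level control.

What the simulator does *not* emulate: real variable dictionaries or coding
schemes, demographic structure, informative (non-random) missingness,
measurement floors/ceilings, site effects, or label noise. Passing tests
therefore demonstrate that the pipeline and model behave as specified and
can recover a planted longitudinal signal — not that any particular accuracy
would transfer to a real registry.

## Numerical and degenerate-input choices

- Sentinel substitution happens inside the encoders; engineered values keep
  explicit masks, so correctness never depends on sign conventions.
- Zero or missing first-visit denominators mask the change row; no ±Inf.
- Softmax and cross-entropy are computed via max-subtraction / log-sum-exp.
- All-missing baseline input: flagged zero encoding, never NaN.
- Argmax ties break toward the lower (less severe) class index,
  deterministically.
- AUC uses midranks for ties; degenerate classes (no positive or no
  negative) are excluded from the macro average with a warning.
- Every stochastic step (simulation, balancing, folds, initialization,
  shuffling, dropout) draws from a seeded RNG whose state is restored
  afterwards; identical seeds give identical results under single-threaded
  execution.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on cohorts of 25–1000 patients with tiny models
(hidden 8–16). The signal-recovery experiments — the package's own
end-to-end check — use a 300-patient cohort with `effect_size = 2`, hidden
size 32, one 80/20 patient-level holdout, up to 55 epochs with patience 10:
the strong-signal cohort must beat 0.60 three-class accuracy (chance 1/3)
on held-out patients in both encoder arms, and the matched null cohort must
land inside the 95% binomial interval around 1/3. These sizes were chosen as
the smallest at which the planted signal is comfortably recoverable;
`scripts/acceptance.R` reruns the same experiments from scratch at an
arbitrary seed.

## Known limitations

- The implementation is plain R; a GPU-scale replication (hidden 512–2048,
  tens of thousands of pairs) is out of scope, and published full-scale
  accuracies on restricted registry data are not reproduction targets.
- Early stopping on the evaluation fold is optimistic relative to a nested
  dev split (inherited from the protocol as published).
- The affine (unclamped) gate can in principle leave [0, 1]; training keeps
  it useful in practice, and the exact zero-bypass property depends on it.
- Variable-length change sequences are processed per sample rather than as
  padded batches; correctness is unaffected, throughput is.
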