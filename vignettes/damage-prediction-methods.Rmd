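---
title: "Predicting chronic damage accrual in SLE from visit sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chronic damage accrual in SLE from visit sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Survival in systemic lupus erythematosus (SLE) now exceeds 90%, which has
shifted the clinical burden toward *chronic damage*: irreversible organ
impairment, scored by the SLICC/ACR Damage Index (SDI) as a cumulative,
non-decreasing integer. Predicting which damage-free patients will accrue
damage is a stratification problem over *longitudinal* clinic data: each
patient contributes an ordered sequence of visits carrying demographics,
binary clinical/laboratory/treatment flags, and a binarized disease-activity
indicator (SLEDAI-2K = 0 versus >= 1).

`lupusrnn` implements this analysis end to end: a synthetic cohort
simulator, the visit-table interchange format, case/control eligibility
rules, an Elman-style recurrent network trained by backpropagation through
time, pooled eight-fold ROC validation with operating-threshold reporting,
static baselines, and descriptive cohort statistics.

## The recurrent model

For patient $j$ with visit features $x_t^j \in \mathbb{R}^p$, the model is

$$h_t^j = \tanh(W_r h_{t-1}^j + W_i x_t^j), \qquad h_0^j = 0,$$
$$y_t^j = \frac{1}{1 + \exp(-W_o \cdot h_t^j)},$$

with $W_r$ ($n \times n$), $W_i$ ($n \times p$) and $W_o$ (length $n$),
$n = 100$ hidden units by default. Only the final output $y_T^j$ is
supervised; it is read as the probability of developing organ damage within
the next two years. Sequences of different lengths are processed natively —
nothing is ever padded. There are no bias terms, because the model
equations contain none; `rnn_config()` deliberately has no switch that
would change the model class.

Shapes are defined so that every matrix–vector product in the equations is
well-formed ($W_i$ maps $p$-vectors to $n$-vectors, $W_o$ maps $n$-vectors
to a scalar). Textual shape statements that conflict with the products
themselves (a known hazard when transcribing such equations) are resolved
in favour of the products.

### Training

Training minimizes the binary cross-entropy of the final-step output by
plain per-example stochastic gradient descent over epoch-wise shuffles,
with exact gradients from full (untruncated) backpropagation through time.
After every epoch the training-pool AUC is computed, and training halts
once it exceeds 0.95 — an early-stopping rule that limits over-fitting by
refusing to polish training predictions past that point — or at
`max_epochs`.

Parameters the protocol leaves open were fixed as follows, and why:

* **Learning rate 0.005.** At 0.05 the training AUC oscillates between
  0.5 and 0.8 for hundreds of epochs without ever reaching the stopping
  criterion; at 0.005 it rises monotonically and stops within tens of
  epochs on cohort-sized problems. Chosen from training-side behaviour
  only.
* **Initialization uniform on [-0.17, 0.17].** For $n = 100$ this puts the
  spectral radius of the random recurrent matrix near 1
  ($\rho \approx s\sqrt{n/3}$), the longest-memory regime of a random
  recurrence — appropriate when the discriminative signal accumulates
  across visits. An i.i.d. uniform draw keeps the initializer a pure
  function of the seed.
* **`max_epochs` 500** as a non-convergence guard; the analyses in this
  package run with 150 (30 for label-permutation nulls, where the
  stopping rule cannot fire early and the expectation is 0.5 regardless
  of training length).
* **No momentum, no rate decay, no minibatching, no clipping**: the
  protocol names plain SGD and the sequences are short.

Gradient correctness is established against central finite differences
(relative error below $10^{-4}$ over random small instances) and the
forward pass against an independent plain-R implementation; both oracles
live in the test suite, not in the package.

## Validation

Validation is a stratified eight-fold cross-validation that *pools*
held-out scores: per-fold case counts differ by at most one (likewise
controls), each fold's model is trained on the other seven parts, and all
held-out scores are concatenated into a single ROC curve. Pooling is the
primary estimate — per-fold AUCs are diagnostics only. The ROC sweeps
thresholds over the observed distinct scores (score >= threshold classifies
positive), and the trapezoidal AUC is algebraically identical to the
tie-aware concordance probability, a property the tests verify by explicit
pair enumeration. The threshold report lists the operating points whose
sensitivity and specificity both reach 0.7, sorted by decreasing
threshold.

Age standardization is re-fitted on each fold's training part and applied
to its held-out part, so held-out visits never influence the encoding — an
invariant the tests assert fold by fold.

All randomness derives from one master seed: the fold assignment uses it
directly, and fold $f$ trains with master + 1000 + $f$.

### Static baselines

The comparison models score a *single* vector: the features of the last
$L$ visits of each sequence, concatenated chronologically (sequences
shorter than $L$ repeat their earliest visit; zero-padding is available).
`fit_logistic()` is an unpenalized maximum-likelihood binomial GLM.
`fit_ffnn()` is exactly the recurrent model evaluated at $T = 1$ — with
$h_0 = 0$ the recurrence contributes nothing to a single step, leaving one
hidden tanh layer and a logistic output — trained with the same SGD and
stopping rule, which makes the recurrent-versus-static comparison a
controlled experiment on *input representation* rather than on training
protocol. Both baselines are validated with the identical pooled-fold
machinery, on identical folds for the same master seed.

The phrase "up to the second to last available visit" in descriptions of
such static windows is ambiguous; both readings are implemented
(`drop_last` flag), defaulting to using the selection windows as produced,
and neither is asserted as the original intent.

## Cohort selection rules

From a visit table, **cases** are patients with SDI = 0 at their first
visit who later show SDI >= 1; their model input is the visit prefix
strictly before the first positive-SDI visit (label 1). **Controls** show
SDI = 0 throughout, have at least 5 visits, and keep only visits up to
24 months before their last visit — the reserved window is what certifies
"no damage in the next two years", making the control label semantically
parallel to the case label. Patients damaged at baseline, and never-damaged
patients with insufficient follow-up, enter neither group. Binary features
ever-positive in fewer than 4 patients are dropped before modelling
(patient-level counting by default; per-visit counting behind a flag, since
published per-patient frequency tables suggest the patient-level reading).

## The synthetic cohort simulator

No patient-level data accompany the published analysis this package
re-implements, so every claim is exercised on simulated cohorts with the
same statistical skeleton:

* **Visit schedule**: quarterly on average (3 ± 1 months, uniform jitter),
  follow-up drawn uniformly from 12–96 months — consistent with cohorts
  observed "at least twice a year, mostly quarterly".
* **Features**: static per-patient binary flags drawn at published control
  -group prevalences (33 clinical/serological/treatment/comorbidity flags;
  two aPL-sequel flags without published rates set to 0.10/0.08); sex at
  5/94; age at first visit Normal(35.6, 10.9), advancing deterministically.
* **Disease activity**: a symmetric two-state Markov chain with
  self-transition 0.85 per visit, giving persistent activity runs.
* **Damage**: a discrete-time logistic hazard per visit,
  $\mathrm{logit}^{-1}(\beta_0 + \beta^\top z + \gamma\,
  c_{t-1})$ with $c_{t-1}$ the count of active visits so far. The first
  event sets SDI to 1 permanently; further accrual is not modelled because
  the analysis only distinguishes SDI = 0 from SDI > 0.

The hazard makes planted effects interpretable as log-odds ratios, and the
$\gamma$ (trajectory) term carries signal that no single-visit snapshot
exposes — the regime in which a recurrent model should beat static ones.
Defaults $\beta_0 = -7.5$, $\gamma = 0.25$ (with a sparse set of
clinically motivated static effects around 0.4–0.6) were calibrated once so
that a 413-patient cohort yields roughly 40–55 progressors and a few
hundred eligible controls, mirroring the 38-case/66-progressor scale of the
motivating cohort; they were then frozen. All generated patients start at
SDI 0, so eligible controls outnumber the motivating study's 94 (that
cohort excluded 148 patients already damaged at baseline).

What the simulator does *not* emulate: missing data (the file format
forbids it; real-data adapters must impute upstream), treatment switching,
death or dropout censoring, multi-organ SDI itemization, and
patient-specific activity propensities. Passing tests on this simulator
therefore demonstrate that the pipeline recovers signal of the planted
kind at cohort scale — not that the published effect sizes are correct.

## What desk-scale replication can and cannot show

With ~40 cases, eight-fold pooled validation of a 100-unit network is
noisy: per-fold held-out AUCs range roughly 0.5–0.9 around a pooled value
near 0.7, and which side of 0.70 the pooled AUC lands on varies with the
master seed. The package reports what it computes. Operating points with
sensitivity and specificity both >= 0.7 typically require a pooled AUC
around 0.75 or higher, so at this scale the threshold report is often
empty — consistent with the threshold table being a property of the
original full cohort rather than of any desk-scale mirror.

Problem sizes used by the shipped analyses (chosen as the package's own
defaults): 413 simulated patients; eight folds; 150-epoch cap (30 for
permutation nulls); 20 permutation seeds for null calibration; 5 seeds for
the architecture sweep and the static-gap comparison.

## Descriptive statistics

`sdi_summary()` computes weighted mean, sample SD ($n-1$; 0 for a single
patient by convention), cumulative-count median (midpoint convention) and
range from an SDI histogram. `proportion_pct()` rounds half-up to one
decimal — matching how such tables are typically printed — and group
comparisons use the chi-square test without continuity correction
(correction behind a flag), Fisher's exact test where expected counts fall
below 5, and the tie-corrected Mann-Whitney test (exact by enumeration up
to combined n = 12, where the classical no-tie exact tables do not apply).

## Known limitations

* The pooled-fold protocol re-trains a non-convex model per fold; fold
  -level training noise propagates into the pooled ROC. Averaging over
  master seeds is recommended for any substantive comparison.
* The logistic hazard simulator has a single activity chain shared by all
  patients; real cohorts have between-patient activity heterogeneity that
  would make static snapshots more informative than they are here.
* Early stopping on *training* AUC (the reproduced protocol) is a weak
  regularizer; it controls polish, not capacity, and at 100 hidden units
  the network reaches the stopping criterion largely by memorization when
  the planted signal is weak.
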