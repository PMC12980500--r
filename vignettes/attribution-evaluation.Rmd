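---
title: "Evaluating attribution methods for deep ECG classifiers: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating attribution methods for deep ECG classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: what
the synthetic data emulate, how the task models and the twelve attribution
methods are defined, how the four evaluation experiments are scored, and
which design decisions were genuinely open — with the reasoning behind the
choices made.

## The problem

Post hoc attribution methods assign each input sample of a classified ECG a
relevance value for one model prediction. Their trustworthiness is usually
asserted from a few visually pleasing examples. The package operationalizes
four harder questions — do methods agree with each other, with themselves
across retrainings, with the model's weights, and with the features the
model demonstrably uses — as reproducible experiments on synthetic data
where the discriminative features are planted and therefore known.

Working on synthetic median beats is a deliberate trade: every experiment
runs on one CPU core in minutes, and ground-truth relevance masks exist, at
the price of physiological realism (see *Limitations*).

## The synthetic median-beat generator

A median beat is modelled as a sum of five Gaussian bumps (P, Q, R, S, T)
per lead over 8 leads (I, II, V1–V6) at 500 Hz for 1.2 s (600 samples):

$$s_\ell(t) = \sum_{w} a_{\ell w}\, e^{-(t - c_w)^2 / 2\sigma_w^2} + \varepsilon_{\ell t},
\qquad \varepsilon_{\ell t} \sim \mathcal N(0, \sigma_\text{noise}^2).$$

Wave timing is controlled by two intervals: the P center sits
`pr_interval` (default 160 ms) before the R apex, the T center
`rt_interval` (default 300 ms) after it. Amplitudes are ordinary adult
surface-ECG magnitudes; P-wave amplitudes sit at the upper-normal range
(0.06–0.12 mV) so that the P-dependent classes remain machine-separable at
the default noise level — the generator's contract is that every planted
class is learnable, since all four experiments presuppose working
classifiers. The default measurement noise is `noise_sd = 0.03` mV,
a typical residual noise level for an averaged median beat.

The nine diagnostic classes are morphological modifiers of this baseline:

| class | modifier |
|---|---|
| sinus rhythm | none (baseline) |
| atrial fibrillation | P amplitude set to 0 in all leads |
| sinus bradycardia / tachycardia | R–T interval ±80 ms |
| first-degree AV block | PR interval forced to 240 ms |
| right bundle branch block | QRS widths ×2.2, offsets ×2, tall R in V1, deep lateral S |
| left bundle branch block | QRS widths ×2.2, offsets ×2, dominant S in V1, tall lateral R |
| low QRS voltage | QRS amplitudes ×0.33 (below 0.5 mV) |
| left ventricular hypertrophy | QRS amplitudes ×1.8 |

Two of these deserve comment. A median beat carries no rhythm strip, so the
rate-based diagnoses (bradycardia, tachycardia, fibrillation) are
*single-beat morphology proxies* — shifted T–P spacing and an absent P —
not simulations of irregular rhythm. This is a documented deviation: the
classes exercise the same kinds of features (timing, presence/absence) at
the same signal locations a clinician would name, which is all the
attribution experiments need.

**Labels.** Measured prevalences of the emulated cohort
(`default_prevalences()`: sinus rhythm 62.9%, AF 6.2%, … low QRS voltage
3.6%) sum to more than 1 because records are multi-label. Labels are drawn
from a structured scheme — a rhythm categorical (with an unlabeled
"other atrial rhythm" remainder rendered with an inverted P wave),
AV block conditional on P-wave presence with its probability inflated so
the marginal stays exact, and categorical right/left-bundle and
low-voltage/hypertrophy pairs — so that (a) each class marginal equals its
configured prevalence exactly, and (b) no record violates the
compatibility table `class_compatibility()` (no AF + sinus rhythm, no
AF + AV block, etc.). The unlabeled remainder rhythm gets a distinct
morphology on purpose: if it looked exactly like sinus rhythm, the
sinus-rhythm classification task would be ill-posed by construction.

**Patient grouping.** Each patient draws one latent offset vector (global
amplitude scale, per-wave amplitude factors, ±8 ms timing shifts) shared by
all their records; record counts per patient follow a shifted Poisson
`1 + Pois(mean - 1)` (strictly positive, mean 4.5). Splits are always at
the patient level.

**Ground truth.** A record's relevance mask is computed by differencing its
noiseless waveform against the baseline beat rendered with the *same*
patient latent: the mask is exactly where the class modifiers changed the
signal (threshold 0.01 mV). Sinus-rhythm-only records have empty masks —
the baseline has no "discriminative region" of its own.

One caveat the perturbation experiment must respect: for
*absence* features (AF's missing P wave) the input equals the zero baseline
inside the mask, so baseline-difference methods (Gradient*Input, IG,
DeepLift) are exactly zero there — correctly, since the contribution of a
zero difference is zero. Localization and oracle-ranking checks therefore
use a presence feature (the bundle-branch-block QRS) where the mask covers
high-energy samples.

## Task models

The classifier is a 1D ResNet: residual blocks of two kernel-7
convolutions, each followed by batch normalization, ReLU and dropout; the
channel dimension doubles and the spatial dimension halves every two
convolutional layers (stride-2 first convolution, 1-kernel projection
shortcut — the standard ResNet treatment of dimension changes); global
average pooling feeds one linear unit with a sigmoid. One binary model per
class. The builder validates that the input length survives all halvings
(the reference-scale 22-layer schedule needs inputs of ≥ 2048 samples; on
600-sample beats it underflows, so depth is an explicit configuration, not
a guess).

The forward/backward engine is written directly in R (im2col gathers +
BLAS matrix products) and is deterministic given seeds; dropout is active
only in training, and batch-norm uses running statistics at inference, so
the attribution target is a fixed differentiable function.

Training choices (unreported in the source architecture and therefore
package decisions): Adam at `lr = 1e-3` default, binary cross-entropy with
a `pos_weight` of the negative/positive count ratio ("balanced") —
prevalences down to 3.6% otherwise make the rare classes slow to learn —
early stopping on validation AUROC (patience 5), best-epoch snapshot
returned, Youden's J threshold fitted on the validation split. Batch-norm
statistics and affine parameters are *reset* when a layer is randomized in
the cascading-randomization experiment; preserving trained statistics
would leak learned information into a nominally random layer.

**Desk profiles.** The default configuration uses 8 convolutional layers
with base 16 channels. The test suite and the acceptance script use the
same depth with base 8 channels and learning rate 3e-3: depth is kept at 8
because the receptive field must span the P-to-T extent (~500 ms) for the
timing classes (AV block, brady/tachycardia) to be learnable at all, while
the narrower channel budget keeps one training run in the tens of seconds.
Problem sizes there: 450 patients (~2000 records), 60 + 60 held-out
patients, batches of 128, at most 10 epochs with a stop at validation
AUROC 0.93.

## The twelve attribution methods

All methods attribute the *pre-sigmoid score* (configurable): near-saturated
probabilities have vanishing sigmoid gradients that would flatten every
gradient-based map. One backward engine serves three semantics — plain
gradients, guided backpropagation (ReLU passes gradient only where forward
input and incoming gradient are both positive), and DeepLift rescale
multipliers (per-unit Δoutput/Δinput at each ReLU, linear layers passed
exactly) — and the methods compose it:

* Saliency `|∂s/∂x|`; Gradient*Input `x ⊙ ∂s/∂x`;
* Integrated Gradients: midpoint Riemann path integral from a baseline
  (default 64 steps, zero baseline); completeness
  `Σ map = s(x) − s(baseline)` is checked, not assumed;
* DeepLift (rescale): exact summation-to-delta on this architecture, since
  convolution, inference batch norm, pooling, the residual add and the head
  are all linear;
* SmoothGrad and IG + SmoothGrad: mean map over 32 Gaussian-perturbed
  inputs, noise SD = 0.1 × signal range;
* Guided backpropagation; GradCAM (channel weights = time-averaged
  gradients at the last residual block, ReLU-clamped weighted activation
  sum, linearly upsampled and replicated across leads — post-convolution
  channels mix leads, so GradCAM genuinely has no per-lead information);
  Guided GradCAM = elementwise product;
* Shapley value sampling over 32 contiguous time segments spanning all
  leads jointly (keeping the coalition space tractable; per-lead
  segmentation is a config option), 256 sampled permutations, absent
  segments replaced by baseline; the estimator is unbiased and is tested
  against exhaustive enumeration at 3 segments;
* GradientSHAP (expectation over baseline draws and path positions) and
  DeepLiftSHAP (mean DeepLift over baselines), default 16 training-set
  baseline draws.

Defaults follow the stabilization heuristic of raising each budget until
maps stop visibly changing on desk models; every map records a
configuration hash. Experiment-level runs may use reduced budgets (stated
in their run manifests): Shapley sampling at full budget costs ~10^4
forward passes per record, which is the single most expensive object in
the package.

## Map processing and scoring

Maps are smoothed with a Savitzky–Golay filter (31 samples, order 3) before
the correlation-based experiments 1–3 — the filter reproduces polynomials
up to degree 3 exactly, so smooth structure is preserved while
high-frequency gradient noise is suppressed. Whether the original analyses
smoothed in experiments 2–3 is not stated anywhere; smoothing is a
documented switch, default on for 1–3, and the experiment-4 ranking always
uses raw absolute values (its definition ties it to the raw attributions).

"Correlation pointwise across samples and leads, then averaged" admits two
readings; the package correlates within each lead and averages the 8
coefficients without weights (matching "then averaged"), with the pooled
flattened variant behind `pooled = TRUE` for sensitivity analysis. A
constant row (GradCAM can emit all-zero maps) contributes 0 and raises a
degenerate flag; flag counts are reported rather than silently dropping
pairs, which would bias aggregates. Identical rows score exactly 1 —
floating-point correlation of a vector with itself can round to 1−1e−16,
and the self-consistency contract for identical models is exact.
Aggregate SD is the sample SD (n−1): seeds are a sample of possible
initializations.

## The four experiments

1. **Inter-method similarity**: all method pairs per record on smoothed
   maps; symmetric matrix, unit diagonal, aggregated over records (and
   seeds/classes when run across the grid).
2. **Self-consistency**: all s(s−1)/2 unordered seed pairs per method per
   record.
3. **Cascading randomization**: layers re-initialized output-first (the
   classification head, then each convolution with its batch norm; the
   block's first convolution owns the projection shortcut), fresh maps
   correlated against step-0 maps, model AUROC re-measured per step. Step 0
   must sit at correlation 1 by construction — it is asserted, as is
   chance-level AUROC at full randomization.
4. **Remove-and-debias perturbation**: points ranked once per record from
   raw |attribution|; each step replaces the next 1% (configurable) of
   points by linear interpolation between nearest unmasked neighbours on
   the same lead, multiplied by `N(1, 0.25)` noise. The noise wording in
   the source material admits a multiplicative and an additive reading;
   the figure caption's "multiplied with Gaussian noise" is taken as the
   default and the additive mode is provided and logged. Boundary points
   extend the nearest unmasked value; a fully masked lead falls back to
   zero. The ranking is computed once and held fixed (inference, not
   attribution, is re-run per step); a per-step re-ranking mode would
   measure a different, adaptive quantity and is deliberately not the
   default. Controls `random_ranking` and `oracle_mask` (ground-truth mask
   first) bracket the methods from below and above.

Experiment 3 runs on a single class's model by default (atrial
fibrillation), and experiment 4 averages over available seeds; both are
configurable.

## Numerical and engineering choices

* All randomness flows from one global seed through deterministic
  derivations (`derive_seed`), so any stage can be re-run in isolation and
  two identical runs produce byte-identical CSVs (floats fixed to 6
  significant digits in reports).
* The DeepLift rescale rule switches to the gradient rule where
  |Δpre-activation| < 1e−10 (the multiplier is ill-defined at 0/0).
* Ranking ties break by (lead, time) ascending — a total, deterministic
  order.
* Youden's threshold scans observed score cut-points; ties resolve to the
  lowest maximizing threshold.
* AUROC is the midrank Mann–Whitney statistic (ties count one half), AUPRC
  is step-function average precision; "micro F1" of a binary task equals
  the positive-class F1 and is reported as such.

## What passing tests do and do not show

The generator produces exactly the structure the experiments need —
separable planted features, known masks, patient grouping, exact label
marginals — and nothing more. Real median beats have correlated,
non-Gaussian noise, baseline wander, heteroscedastic amplitudes,
beat-alignment artifacts, and diagnoses whose evidence is distributed and
interacting; none of that is emulated. Consequently, green tests here
certify the *machinery* (methods implemented to their definitions, axioms
holding, experiment mechanics measuring what they claim) and the
*directions* the evaluation is built to detect (maps decorrelate under
weight randomization; oracle-ranked perturbation degrades performance
faster than random). They do not certify any quantitative agreement level
between attribution methods on clinical data, and the package makes no
such claim.

## Known limitations

* Rhythm diagnoses are morphology proxies on one beat; no rhythm-strip
  analysis.
* Dense Shapley budgets are expensive in pure R; the full 32 × 256 default
  is practical per record, not per grid.
* GradCAM's lead replication means per-lead correlation against lead-specific
  maps is structurally penalized — an honest property of the method on
  multi-lead signals, but one to remember when reading experiment 1.
* The engine is CPU-only by design; the reference-scale 22-layer model on
  4096-sample inputs builds and runs, but grid-scale training at that size
  is out of scope.
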