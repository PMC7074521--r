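---
title: "Methods: chickpea variety classification from color and texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chickpea variety classification from color and texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seedvision re-implements a complete machine-vision pipeline for telling
apart three visually similar chickpea cultivars (Adel, Arman, Azad) from
photographs of seed bunches on a dark background. This vignette is the
package's own account of the model: what each stage computes, which
parameters matter, which choices were genuinely open and how we made
them, and what the synthetic experiments do and do not demonstrate.

## 1. Segmentation

A pixel is foreground when **any** of three clauses on the [0, 1]-scaled
HSI planes holds: hue < 0.4, saturation > 0.15, or intensity > 0.07
(`hsi_threshold()`). Intensity is `(R+G+B)/(3·255)`, saturation is
`1 − min/mean`, and hue is the geometric (acos) definition normalized to
[0, 1]; achromatic pixels receive hue 0 by convention. The thresholds'
magnitudes (0.4, 0.15, 0.07) only make sense on the unit scale, which is
why all three planes are normalized; this is our reading of the
originally stated rule, which did not spell out its scale.

The disjunctive rule is permissive: *any* bright, or saturated, or
warm-hued pixel is called seed. On an arbitrary natural image most
pixels pass. We deliberately keep the rule exactly as stated and instead
require of test imagery what the original imaging rig guaranteed
physically: a dark, unsaturated, cool-hued background. The synthetic
generator (Section 6) enforces that by construction.

After thresholding, 8-connected foreground components smaller than
`min_pixels = 100` are removed (`remove_small_objects()`); the threshold
is the original study's trial-and-error value, exposed as a parameter.
Connectivity was unstated; 8-connectivity is the standard choice for
blob cleanup and is what we implement (EBImage's 4-connected labeling
plus a diagonal-merge pass).

## 2. Features

`extract_features()` produces a named 128-vector:

* **48 color features** — for each of RGB, HSV, HSI, YCbCr, YIQ, CMY:
  mean and standard deviation of channels 1–3 and of the per-pixel mean
  of the three channels, over foreground pixels only.
* **80 texture features** — the 20 GLCM statistics of `glcm_features()`
  at angles 0°, 45°, 90°, 135° (distance 1).

Fixed numerical conventions, chosen once and documented:

* Statistics use the **population** standard deviation (divide by *n*).
* All statistics are restricted to foreground pixels; a GLCM pair counts
  only when both pixels are foreground. The alternative — statistics
  over the masked image including its black background — would let
  background area dominate every feature.
* Gray levels are quantized linearly into 8 bins over [0, 255]
  (configurable); the co-occurrence matrix is unsymmetric at distance 1
  by default.
* Logarithms are base 2 and `0·log 0 := 0`.
* Two of the listed texture statistics ("diagonal moment" and "second
  diagonal moment") have no canonical formula in the GLCM literature; we
  define them as `Σ|i−j|·p` and `Σ|i−j|(i−j)²·p` respectively, the
  latter chosen so it does not duplicate contrast. Correlation is set to
  0 for degenerate (zero-variance) marginals, and the coefficient of
  variation to 0 when the grand mean is 0.

The originally stated color-space definitions contain several printed
forms we treat as typos, because they are degenerate or contradict the
relevant standards: the HSV hue normalizer (we use the standard hexcone
formula), the HSI saturation (we use `1 − min/mean` on the unit scale),
and the sign of the YIQ I red coefficient (we use the NTSC +0.595716).
The YCbCr luma, omitted in the original table, is BT.601
(`0.299R + 0.587G + 0.114B`), which also serves as the GLCM gray plane.

The published five discriminant features are frozen as
`feature_preset("paper5")`: mean of the per-pixel RGB channel average,
mean of the per-pixel HSI channel average, GLCM sum entropy at 90°, GLCM
standard deviation at 0°, and mean of the third YCbCr channel (Cr). The
original description is ambiguous about the HSI term ("mean of the
components" vs "first channel"); `paper5_alt` carries the hue-mean
variant. Likewise "entropy of the GLCM" is not a listed statistic; we
read it as sum entropy.

## 3. The MLP core

The classifier is a 1–3-hidden-layer perceptron with per-layer transfer
functions from the classic 13-name vocabulary (tansig … tribas), a
3-unit softmax output, one-hot targets, and MSE loss. Output encoding
was unstated in the source; softmax + one-hot is the conventional
choice and keeps scores interpretable as confidences for the ensemble.

Implemented training rules: `traingd`, `traingdm`, `traingda`,
`traingdx`, `trainrp`, and `trainlm` (Levenberg–Marquardt with adaptive
damping on an exact Jacobian). These are the rules that appear in the
selected architectures; the remaining vocabulary names alias to the
nearest implemented rule with a warning. The separate "weight/bias
learning function" of the MATLAB idiom is redundant with the trainer in
batch mode; configurations carry it for fidelity, but updates are
governed by the trainer. Defaults: `max_epochs = 300`, early stopping on
validation MSE with `patience = 20` (best-validation weights restored),
goal MSE `1e-5`. Weights initialize Glorot-style,
uniform on ±√(6/(fan_in+fan_out)), reproducibly per seed. `netinv` is
guarded at |x| < 1e−12 so forward passes stay finite. Non-differentiable
transfers (hardlim, hardlims, compet) have zero gradient; candidate
architectures using them simply train poorly and are discarded by the
architecture search on fitness, which mirrors how such candidates would
behave in the original MATLAB toolchain.

## 4. Metaheuristics

Four population optimizers share one interface over mixed
integer/categorical spaces (`search_space()`): PSO (global-best, on
continuous random-key encodings), ACO (archive-based ACOR-style with
rank-weighted Gaussian sampling; categorical dimensions sampled from
rank-weighted frequencies), HS (memory consideration / pitch adjustment
/ random, one harmony per iteration), and CA (population plus belief
space: situational best and per-dimension normative ranges from the top
20%). The source gave no population sizes, iteration counts or
coefficients; we default to canonical literature values (PSO n = 30,
w = 0.72, c1 = c2 = 1.49; ACO archive 30, q = 0.1, ξ = 0.85; HS
HMS = 30, HMCR = 0.9, PAR = 0.3; CA pop = 30, acceptance 20%), all
overridable. Because HS evaluates a single candidate per iteration, its
default iteration count (500) is higher so budgets are comparable.
Variable-length architecture candidates (4–8 entries) are realized as
fixed-length 8 with layer presence implied by a zero neuron count.

All four optimizers are deterministic given a seed, reject non-finite
objective values with a warning, and keep a monotone best-so-far trace.
On exhaustively enumerable spaces (≤ 200 candidates) each matches the
brute-force optimum within 5% in ≥ 90 of 100 seeded runs — this is a
tested property, not an assumption.

## 5. Selection, hybrid classifiers, ensemble

`select_features()` wraps the CA around the fixed scoring network
(hidden layers 8 and 19, `tribas`/`tansig`, `trainlm`), with a
stratified 70/15/15 split drawn once per run and z-scoring fit on the
training block. Subsets are encoded as a cardinality dimension plus
fixed index slots with deterministic duplicate repair; fitness values
are cached per canonical subset. The per-subset training budget (100
epochs, patience 10) bounds the wrapper's cost; it was not specified in
the source.

`run_experiment()` implements the repeated-split protocol: per
iteration a fresh stratified split (30% test, 15% validation), the
three hybrid classifiers trained on the remainder, majority vote on the
test set, pooled (summed) confusion matrices and per-iteration
CCR/AUC. Architectures are tuned **once**, on the first split, and the
fixed configurations are re-trained every iteration — our reading of
"after selecting the optimal structure … repetitions were performed" —
with `retune_each_iteration = TRUE` available. Stratification itself is
an assumption (the source says only "randomly divided"), but it is the
only splitting scheme consistent with the fixed per-class totals of the
published pooled matrices. Three-way voting ties are broken by the
highest softmax confidence, then by the HS member (the best single
classifier in the published comparison); the rule is deterministic and
documented rather than being left to chance.

## 6. The synthetic generator

`generate_image()` emulates the imaging setup: ~60 convex bright
ellipses (possibly touching — features are mask-global, so no overlap
resolution is attempted) on a dark background. Background pixels are
`(b, b+1, b+2)` with b ∈ 8–14: blue-leaning hue ≈ 0.58 ≥ 0.4,
saturation ≤ 0.12, intensity ≤ 0.06 — verifiably background under the
segmentation rule, which makes generator and segmenter exactly
consistent (tested Jaccard ≥ 0.95; in practice ≈ 1.0). Varieties differ
in mean seed color (default profiles are ~20–40 gray levels apart,
against a per-image color jitter of 4) and in the grain scale and
amplitude of a smoothed multiplicative noise field, so both color and
GLCM features carry class signal — mirroring the original finding that
the discriminant set mixes both families.

What passing synthetic tests shows: that segmentation, feature
extraction, selection, tuning, voting and evaluation compose correctly
and recover planted, well-separated class structure. What it does not
show: performance on real chickpea images — real seeds vary in shape,
specularity, dust and illumination in ways the generator does not
model, and the original dataset is not available. The published
accuracies are therefore treated as *evaluation oracles* (their pooled
confusion matrices ship as fixtures and every printed rate is
recomputed from them), never as targets our synthetic runs could
legitimately reproduce.

## 7. Problem sizes and numerical choices

Desk-scale defaults keep the full pipeline in the minutes range: the
end-to-end experiment in the tests and the acceptance script uses 30
images per class at 192×192 pixels, a 60-evaluation tuning budget per
optimizer, 80-epoch training, and 20 split iterations — large enough
for pooled accuracies to be stable, small enough to run anywhere. The
published protocol (1000 iterations, ≥ 2500 tuning evaluations) is
reachable by turning the same knobs (`n_iterations`, `tune_budget`).

Degenerate inputs are handled explicitly: fewer than 2 foreground
pixels, empty GLCM pair sets, zero matrices, single-class truth vectors
and empty splits are signaled errors; division-by-zero metrics return 0
with a warning. Splits missing a class are redrawn (logged). All seeds
fan out deterministically from one master seed per run, so any stage is
reproducible in isolation.

## 8. Known limitations

* The evaluation fixtures reproduce printed rates to their printed
  precision, with two documented quirks of the source tables: the
  recall and precision columns of the published per-class comparison
  are swapped relative to their own confusion matrices (we compute both
  correctly; F1 is symmetric and unaffected), and the published
  specificity values are reproducible under neither the standard nor
  the source's idiosyncratic TN definition (both are implemented;
  standard is the default).
* GLCM "diagonal moment" statistics follow our stated formulas, not a
  verified original intent.
* The wrapper-selection and tuning procedures are stochastic; their
  guarantees are statistical (tested over seeds), not per-run.
* No color calibration or illumination correction: the pipeline assumes
  controlled acquisition, as the original rig provided physically.
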