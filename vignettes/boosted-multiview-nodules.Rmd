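---
title: "Boosted self-normalizing multiview CNNs for nodule candidate classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted self-normalizing multiview CNNs for nodule candidate classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodboost)
```

## The problem

Computer-aided detection of pulmonary nodules in CT typically produces a large
set of *candidate* positions, most of which are not nodules: vessel cross
sections, scars and noise closely mimic small lesions in both intensity and
local morphology. nodboost implements the false-positive-reduction stage of
such a system: given a candidate voxel in a CT-like volume, classify it as
nodule (+1) or nonnodule (−1).

The classifier is an AdaBoost ensemble whose base learner is a small
*self-normalizing multiview CNN*: each candidate is presented to the network
as several co-centered crops of different physical extent ("views"), resized
to a common input size and stacked as channels. Small views resolve the lesion
itself; larger views add the surrounding context that distinguishes a compact
blob from a segment of vessel.

## Pipeline

`run_pipeline()` chains the stages:

1. **simulate** — `generate_phantom()` renders a synthetic CT-like volume with
   labeled candidates (or you supply a NIfTI volume + candidate CSV);
2. **extract** — `extract_multiview()` builds the per-candidate channel stack;
3. **split** — stratified 80/20 train/test partition (`split_80_20()`);
4. **train** — `fit_ensemble()` boosts `M` CNN rounds on the training split;
5. **evaluate** — confusion-matrix metrics and ROC/AUC on the held-out split.

Every stochastic stage derives its seed from one master seed, so a run is
reproducible byte-for-byte from its saved configuration.

## The phantom

The generator emulates the *geometry* of the discrimination task rather than
CT physics. Nodules are isotropic Gaussian blobs (peak `nodule_contrast`,
`sigma = diameter/4`, diameter uniform in `nodule_diameter_range`) added to
Gaussian background noise. Confusers are bright tubes of radius 1–2 voxels
drawn with a flat core profile; half of the nonnodule candidates sit on
vessel voxels, half on pure background. Candidate centers are rejection
sampled under a minimum pairwise separation (default 40 voxels, the largest
view crop) so no candidate's context window contains another candidate;
placement failure after a bounded number of attempts raises an explicit
error rather than degrading silently.

Two geometric choices deserve explanation:

* **Vessel inclination.** Vessel directions are drawn with their out-of-plane
  (z) component shrunk by a factor 0.3 before normalization. A vessel
  crossing the axial plane steeply projects onto an axial slice as a compact
  bright disc — indistinguishable *in principle* from a small nodule in a 2D
  axial view. Since the classifier sees only axial views, near-isotropic
  vessel orientations would make a fraction of negative labels unrecoverable
  by construction, and classification difficulty would no longer vanish at
  high contrast. Shallow inclination keeps the intended cue (blob vs
  elongated structure) present in every confuser.
* **Intensity units are arbitrary.** Patches are z-scored before entering the
  network, so no Hounsfield calibration is attempted; `nodule_contrast` is
  expressed in multiples of `background_noise_sd`. Vessel brightness is tied
  to `nodule_contrast`, which also makes contrast a clean separability knob:
  at contrast 0 the volume carries no label information at all.

What the phantom does **not** emulate: reconstruction kernels and dose,
lobar anatomy and lung boundaries, part-solid/ground-glass morphology,
spacing anisotropy, and the candidate-detector biases of real CAD front
ends. Passing tests on the phantom demonstrate that the pipeline's machinery
(extraction, weighting, boosting, evaluation) is correct and that the model
can exploit shape-vs-context cues — not that real-data headline accuracy
would be reproduced.

## Multiview extraction

For each candidate, `crop_view()` takes the axial `size × size` window at
the candidate's z, centered at its (y, x); for even sizes the candidate
voxel occupies 0-based index `size/2` along each axis. Out-of-volume pixels
are filled by edge replication, avoiding artificial zero-intensity edges at
volume borders. `resize_spline()` resamples each crop to the common input
size with separable interpolation (nearest, linear, or natural cubic —
default cubic) on an align-corners grid: output index `i` samples input
coordinate `i·(n−1)/(t−1)`, so equal sizes are an exact identity and
corners are preserved. Each view plane is then z-scored with a variance
floor of 1e−8 (constant patches map to all-zeros), because SELU's
self-normalizing behavior assumes standardized inputs. Views are stacked
smallest-crop-first as channels; default crops are 20/30/40 pixels.

## The base learner

The network is `[conv (valid, 3×3) → SELU → 2×2 max-pool]` blocks over the
channel stack, a flatten, fully connected SELU layers with alpha-dropout,
and one sigmoid output unit giving P(nodule). SELU is

$$\mathrm{selu}(x) = \lambda x \;(x>0), \qquad
  \lambda\alpha(e^{x}-1) \;(x\le 0),$$

with $\alpha = 1.6733$, $\lambda = 1.0507$; it is continuous at 0 (the
implementation assigns 0 to the negative branch) and saturates at
$-\lambda\alpha \approx -1.7581$. With weights drawn from
$\mathcal N(0, 1/\mathrm{fan_in})$ — the initialization used here — SELU
keeps activation means near 0 and variances near 1 through depth, which the
test suite checks empirically through ten stacked random layers.
Alpha-dropout drops activations to $-\lambda\alpha$ (rather than 0) with an
affine correction that preserves mean and variance; default rate 0.05.

Training minimizes sample-weighted binary cross-entropy with Adam. The
boosting weights $S(i)$ (a probability vector) enter as per-sample loss
weights $n\,S(i)$, rescaled to mean 1 — so uniform weights reproduce the
unweighted loss, rescaling all weights is a no-op, and a zero-weight sample
is exactly invisible to the loss. Weighting the loss rather than resampling
keeps training deterministic given the seed. Gradients are exact
(finite-difference-checked backpropagation through pooling argmaxes, SELU
and dropout masks).

Two hyperparameter profiles exist. The constructor defaults of
`base_learner_spec()` mirror full-scale training: input 224×224, batch 128,
Adam learning rate 1e−4 with first-moment decay 0.9. The **desk profile**
(`run_config(profile = "desk")`, used by all examples and tests) is sized
for minutes on one CPU: 32×32 input, two conv blocks of 8 and 16 3×3
filters, one hidden layer of 32, batch 4, learning rate 0.005, 3 epochs.
The batch and learning rate were chosen so that a base learner reliably
converges within that short budget (about 60 updates on an 80-sample
training split); the architecture is the package default at both scales.

## Boosting

With labels and predictions in {−1, +1}, round $m$ computes the weighted
error $\varepsilon_m = \sum_i S_m(i)\,[f_m(x_i) \ne c_i]$, the vote
$d_m = \tfrac12 \ln\frac{1-\varepsilon_m}{\varepsilon_m}$, and the update

$$S_{m+1}(i) = \frac{S_m(i)\,e^{-d_m c_i f_m(x_i)}}{Z_m},$$

where $Z_m$ restores normalization. Correct samples shrink, errors grow;
after an exact update the misclassified set carries exactly half the mass,
and the training error of the weighted vote is bounded by
$\prod_m 2\sqrt{\varepsilon_m(1-\varepsilon_m)}$ — both identities are
asserted in the tests, and the whole transcript is checked against an
independently coded naive AdaBoost with decision stumps.

Numerical choices: $\varepsilon$ is clamped symmetrically to
$[10^{-10}, 1-10^{-10}]$ before the logarithm (the vote is undefined at 0
and 1); a round with $\varepsilon \ge 0.5$ warns and, by default
(`epsilon_policy = "continue"`), is kept with its non-positive vote for the
fixed number of rounds — an optional `"stop"` policy ends boosting there.
Inference returns the margin $\sum_m d_m f_m(x)$ (or the unweighted vote sum
under `voting = "simple"`); the hard label is its sign with 0 mapped to +1,
and the margin doubles as the ROC score. The default ensemble size M = 3 at
desk scale keeps the three-round structure inside a CPU budget; M is fully
configurable.

## Evaluation

`confusion()` uses nodule = positive. `metrics()` raises on zero
denominators instead of returning 0, so degenerate folds cannot silently
bias averages. `roc()` sweeps thresholds over unique scores descending,
groups ties (one operating point per unique score), anchors (0,0) and
(1,1), and integrates by trapezoid; the resulting AUC equals the
Mann–Whitney statistic P(score₊ > score₋) + ½P(tie), which the tests verify
by brute force and against pROC. `split_80_20()` and `cross_validate()`
provide stratified partitions; fold sizes differ by at most one and each
sample is tested exactly once.

## Problem sizes used by the tests

The standard study run is: 100 candidates (50/50) in a 160×288×288 volume,
contrast 6 at noise SD 1, 30 vessels, views 20/30/40 → 32×32, M = 3 rounds
of 3 epochs, stratified 80/20 split. This completes in well under a minute
on one CPU and typically yields held-out accuracy 0.90–1.00 and AUC ≥ 0.95;
smaller volumes and learners are used where a test only exercises plumbing.

## Known limitations

* 2D axial views only: no 3D or sagittal/coronal context (3D cubes can be
  archived for bookkeeping but are not consumed by the network).
* The phantom's simplicity means results on it upper-bound nothing about
  clinical data; it validates machinery, not clinical performance.
* Decision-stump base learners ship for verifying the boosting math; they
  are not intended as a practical classifier for images.
* Training is single-threaded R; the full-scale profile (224×224, batch
  128) is provided as configuration surface and is not practical to train
  in this implementation.
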