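---
title: "Sparse-view CT reconstruction with a learned CNN penalty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view CT reconstruction with a learned CNN penalty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The reconstruction problem

In few-view computed tomography the scanner acquires far fewer projection
angles than the image resolution calls for (a 128-pixel image needs roughly
`pi/2 * 128` ≈ 200 views; a 45-view scan is under-sampled by a factor of
four).  The linear system `A X = Y` — `A` the projection operator, `X` the
attenuation image, `Y` the measured sinogram — is then severely
underdetermined, and analytic inversion by filtered backprojection (FBP)
produces the familiar angular-aliasing streaks.  The classical remedy is
variational: minimize a data-fidelity term plus penalties that encode prior
knowledge about plausible images.

This package implements such a variational reconstruction whose distinctive
penalty is *learned*.  A small convolutional network is first trained as a
binary classifier to distinguish full-view ("good", label 0) from few-view
("bad", label 1) FBP reconstructions.  After training, the output sigmoid is
discarded, leaving the raw logit — a real number, unbounded in both
directions, that is large for streaked images and small for clean ones.
That logit, written `CNN(X)`, becomes a penalty in the objective

```
F(X) = alpha1 * ||A X - Y||^2  +  alpha2 * CNN(X)  +  alpha3 * TV(X)
```

minimized by steepest descent.  `TV(X)` is the usual total-variation norm.
`F` may be negative, since the logit may be.  Minimizing `F` pulls the
iterate toward images the classifier would call "good" while staying
consistent with the measured data.

The appeal of the construction is data-economy: a classifier needs only
labelled *single* images, never registered good/bad *pairs* from the same
subject, so it can be trained where an image-to-image regression network
cannot.

## Geometry and the projection operator

The acquisition model is 2-D parallel-beam: `n_views` angles equally spaced
over `angular_span_deg` (endpoint excluded, so a 180° span never duplicates
an opposing view), a flat detector of `n_bins` bins whose width equals the
pixel spacing.  The reference scan pair is 45 views over 180° ("incomplete")
versus 360 views over the same span ("complete").  For the complete scan a
360° span would also be a defensible reading; 180° was chosen so that the
two scans differ *only* in angular density — the quantity under study —
with the 360-view scan simply eight times denser.

`forward_project()` applies a Joseph-style ray-driven projector: each ray
steps along its dominant axis, linearly interpolating the image across the
perpendicular axis, each sample weighted by the step length along the ray.
The operator is assembled once per geometry as a sparse matrix and cached,
which buys two things:

* `back_project()` is literally the transpose, so the adjoint identity
  `<Ax, y> = <x, A'y>` — which the data-term gradient `2 A'(AX - Y)`
  depends on — holds to machine precision rather than to discretization
  accuracy;
* repeated projections inside the iterative solver are single sparse
  matrix-vector products.

`fbp()` implements the standard parallel-beam inversion: ramp filtering of
each view in the frequency domain followed by pixel-driven backprojection
with linear interpolation, scaled by `pi / (2 n_views)`.  Two numerical
choices matter.  The projections are zero-padded to at least twice the next
power of two before the FFT, suppressing circular-convolution wrap-around.
And the Ram-Lak ramp is constructed as the DFT of its band-limited
*spatial-domain* kernel (`1/4` at lag 0, `-1/(pi n)^2` at odd lags) rather
than by sampling `|f|` directly; direct sampling under-weights the lowest
frequencies and produces a visible DC bias and cupping (with it, a smooth
test object reconstructs with ~6% error at *any* view count; with the
kernel construction, ~0.5%).  No apodization window is applied — this is
deliberately the "naive" FBP whose artifacts the classifier learns.

FBP is quantitatively valid only inside the circle inscribed in the image
square, so all image metrics in the package (`rmse_in_circle()`) are
evaluated there.

## Synthetic phantoms standing in for patient data

The classifier in the original setting was trained on 4756 patient CT
slices, reconstructed half from 45-view and half from 360-view sinograms.
Patient data cannot ship with a package, so `generate_phantom()` draws
random anatomy-like slices: an elliptical soft-tissue body (intensity 1.0,
semi-axes 30–42% of the grid) containing 3–8 random ellipses with contrasts
drawn from [-0.4, 0.6], clipped to nonnegative attenuation, everything
inside the inscribed circle.  Each phantom is a pure function of
`(seed, index)`, so corpora are bit-reproducible and train/test splits are
made by disjoint index ranges rather than stored files.

What the generator preserves is the one image property the method's own
analysis identifies as operative: piecewise-smooth regions bounded by sharp
edges, which few-view FBP decorates with streaks.  The trained network
behaves as an edge-and-streak detector, and that behaviour is what the
phantoms exercise.  What the generator does *not* reproduce: textured soft
tissue, bone/air extremes, anatomy-specific structure, detector noise and
beam physics.  Consequences for interpretation: the synthetic task is
*easier* than the clinical one (the background is exactly constant, so
streaks are maximally conspicuous), and classifier accuracies here
overstate what the same architecture would achieve on patients.  Passing
tests demonstrate that the mechanism works — the classifier separates the
classes, its score orders artifact severity, and descending the penalized
objective reduces artifacts — not that clinical image quality is attained.

`build_corpus()` uses the *same* phantom for the good and the bad member of
each pair.  Distinct populations would also be defensible; the shared
phantom makes the pairwise comparisons in the test suite exact and does not
inform the classifier, which never sees pair structure.  An optional
Gaussian sinogram noise model is provided for robustness experiments and is
off by default, matching the noiseless framing of the reference study.

## The classifier and its score

The network is deliberately minimal (7,580 weights at defaults):

* 3×3 convolution, 40 channels, ReLU ("same" zero padding, stride 1);
* 3×3 convolution, 20 channels, ReLU;
* global average pooling to a 20-element vector;
* dense weighted sum to one scalar;
* sigmoid — *only* in classifier mode.

No bias terms anywhere.  Besides matching its reference design, the
bias-free choice has a useful consequence: the score is positively
homogeneous, `CNN(c X) = c CNN(X)` for `c > 0`, so the overall intensity
normalization of inputs only rescales the score by a constant that the
penalty weight `alpha2` absorbs.  Inputs are normalized by a single
corpus-level constant (the maximum absolute intensity of the training
split) stored in the model, so that during reconstruction the score is a
fixed, deterministic function of the image.

Padding is "same" so that the per-channel feature maps (`feature_maps()`)
remain full-size images, inspectable as edge/streak detectors.  Pooling
reduces each channel to its spatial mean; the "flatten" stage of the
original design is a no-op at this point and is not materialized.

Convolutions are evaluated as patch-matrix GEMMs (`im2col`/`col2im` in
C++, multiplication via BLAS), and all gradients — with respect to weights
for training, with respect to the input image for the reconstruction
penalty — are exact backpropagation, verified against central finite
differences in the test suite.  At exactly-zero ReLU pre-activations the
subgradient 0 is used; finite-difference tests sample away from kink
neighbourhoods.

### Training protocol and the desk-scale deviation

Training minimizes binary cross-entropy with Adam (`beta1 = 0.9`,
`beta2 = 0.999`, `eps = 1e-8`), holding out the last 10% of a seeded
shuffle for validation.  The package defaults (`train_config()`: 200
epochs, learning rate 1e-3, batch 32) mirror the reference protocol, which
processed ~4,700 images — roughly 30,000 Adam steps.

The package's own experiments run at desk scale: a 400-pair corpus of
64×64 images, i.e. ~500–600 Adam steps.  At that step count the default
learning rate has barely moved the weights (the loss sits at `log 2` and
the classifier predicts one class), so the scaled-down experiments raise
the learning rate to 1e-2 and drop the batch to 16.  The choice is a
compensation for the shorter schedule, not tuning toward any particular
accuracy figure; the unit-test fixture at 32×32 uses the same reasoning
(3e-2, batch 8).  Weight initialization is fan-in-scaled uniform,
`U(±sqrt(6/fan_in))`, seeded; training is reproducible bit-for-bit for a
fixed seed in single-threaded execution.

Two optional schedule controls make short-schedule training dependable.
`stop_val_acc` ends training after the first epoch whose validation
accuracy reaches the given level — the synthetic task usually converges
well before the epoch cap.  `restarts` addresses a genuine pathology of
the bias-free architecture: without bias terms the decision threshold
cannot translate, and for occasional initialization/data combinations
every pooled score sits on one side of zero and Adam crawls along a
plateau for tens of epochs.  A fresh seeded initialization escapes
immediately, so the trainer re-attempts (deterministically, from seeds
derived from the training seed) when an attempt ends below 90% validation
accuracy, keeping the best attempt.  Both controls are off by default.

## Total variation

`tv_norm()` uses forward differences with replicate boundary.  The default
variant is isotropic, `sum sqrt(Dx^2 + Dy^2 + eps^2)`, with `eps = 1e-6`
relative to unit-intensity images; the anisotropic variant sums the
eps-smoothed absolute differences.  `eps > 0` makes the norm smooth
everywhere, so `tv_gradient()` is an exact gradient rather than a chosen
subgradient; requesting the gradient at `eps = 0` is refused.  On a
constant image the isotropic norm equals its smoothing floor `N^2 eps`
exactly, which the tests use as a closed-form check.  Reconstruction runs
use `eps = 1e-3`: large enough that the gradient is well-scaled near flat
regions, three orders of magnitude below the phantom contrast scale.

## The iterative solver

`reconstruct()` performs plain steepest descent, `x <- x - tau * grad F`,
for a fixed number of iterations.  Defaults: start from the FBP of the
measured sinogram (the natural "refine the artifact-laden image" framing);
backtracking step rule — the trial step starts at
`min(step_size, 2 * tau_prev)` and halves until `F` does not increase, at
most 20 times, so the objective trace is monotonically non-increasing by
construction.  If no acceptable step exists the iterate is kept, the
failure is recorded in the trace, and iteration continues.  A fixed-step
mode and an optional nonnegativity clamp are available; the clamp is off by
default since the objective carries no constraint.  A non-finite objective
aborts with an error naming the iteration.

Every iteration appends `(F, data term, CNN score, TV term, step)` to a
trace with `n_iter + 1` rows (row 0 is the start).  The CNN-score-versus-
iteration curve is the method's main diagnostic: on few-view data with
`alpha2 > 0` it should fall from its streaked starting value.  The score is
evaluated and recorded even when `alpha2 = 0`, so baseline runs produce
comparable curves.

Plain steepest descent on the pure data term converges quickly for
low-frequency image content but crawls for the high-frequency components
(the Radon operator's small singular values), so sharp-edged objects are
not driven to machine-precision data consistency in a few hundred
iterations.  This is inherent to the method reproduced here; accelerated
solvers are explicitly out of scope.

### Penalty weights at synthetic scale

The reference weights `alpha1 = 1e-8`, `alpha2 = 0.002`, `alpha3 = 1e-11`
(600 iterations) belong to clinical-range intensities and remain the
`recon_config()` defaults.  They do not transfer to unit-intensity
phantoms, so `synthetic_recon_config()` fixes `alpha1 = 1` and
recalibrates the penalties on three *calibration* phantoms disjoint from
every phantom used in tests, by reconstruction error against the known
truth.  Two lessons from that calibration are worth recording.

First, the TV weight must be kept small (`alpha3 = 0.1`).  Random ellipse
phantoms are exactly piecewise constant — TV's ideal object — so a strong
TV term (`alpha3 = 5`, the gradient-balance choice) solves the problem
essentially alone, and any extra penalty can only degrade the image.  The
weak setting restores the hierarchy of the reference configuration, where
the TV contribution is orders of magnitude below the CNN term: data
dominate, the learned penalty does the streak removal, TV only damps
residual oscillation.

Second, the CNN weight has a clear interior optimum (`alpha2 = 2` from the
sweep {0, 2, 5, 10, 20, 50, 100}).  Because the logit is unbounded below,
a heavy weight keeps paying the optimizer for pushing the score *past* the
range typical of clean images (means around −4 at this scale) down to −10
and beyond, visibly distorting the reconstruction: the penalty should pull
the image into the "good" class, not out the far side of it.  At the
optimum, the 45-view reconstructions improve on both the FBP baseline and
the matched `alpha2 = 0` run on every calibration phantom, and the score
trace falls over the iterations.  Desk-scale experiments run 200
iterations at 64×64, where the trace has visibly flattened.

## Problem sizes used by the package's experiments

* Unit tests: 32×32 grid, 16-view vs 96-view scans, 40-pair corpus —
  chosen so the under-sampling ratio (≈3×) matches the study design while
  every fixture trains in under a minute.
* Acceptance-style experiments and the reproduction script: 64×64 grid,
  the study's own 45-view vs 360-view scans, 400 training pairs, 100
  fresh test pairs, 200-iteration reconstructions of 5 held-out phantoms.
* FBP view-ordering checks: 128×128, the reference image size.

## Known limitations

* The learned penalty is nonconvex; steepest descent finds a stationary
  point, not a global minimum, and different initializations can end at
  different images.
* The score's meaning is tied to the training distribution: a model
  trained on 64×64 ellipse phantoms scores other image families (or other
  resolutions, despite the fully convolutional trunk) on an uncalibrated
  scale.
* The projector and FBP are 2-D parallel-beam only; fan/cone beam,
  detector physics and noise modelling are out of scope.
* Serialization favours portable text formats (CSV/JSON/TIFF-with-sidecar);
  corpora use RDS.  Float TIFF samples are stored normalized to [0, 1]
  with the affine range in a JSON sidecar, restoring values to 32-bit
  float precision.
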