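---
title: "From muscle ultrasound to ankle moment: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From muscle ultrasound to ankle moment: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sonomoment)
```

## The problem

During walking, the plantarflexor muscles (lateral/medial gastrocnemius and
soleus) generate the push-off torque at the ankle. Estimating that net
plantarflexion moment continuously and non-invasively is the key sensing
problem for assist-as-needed control of ankle exoskeletons and prostheses.
The conventional route — motion capture plus force plates plus inverse
dynamics — is lab-bound and offline. `sonomoment` implements an imaging
route: ultra-fast plane-wave B-mode ultrasound of the plantarflexors,
acquired at the analog sampling rate (one frame per 1 kHz trigger), feeds a
per-subject convolutional network that regresses the instantaneous moment
from each image, with surface EMG scalogram images as the comparative
modality.

The package covers the full chain: raw RF channel data to B-mode
(delay-and-sum, envelope detection, log compression), physical-coordinate
ROI cropping, stance segmentation from vertical ground reaction force,
sliding-window CWT spectrum imaging of sEMG, the 31-layer CNN regressor
with leave-one-speed-out cross-validation, the evaluation metrics, and a
seeded synthetic walking-data generator that stands in for motion-lab
recordings (none are distributed with the protocol this package
operationalizes).

## Beamforming model

Each frame is a single zero-angle plane-wave transmit. For a pixel at
lateral position $x$ and depth $z$, the delay-and-sum image is

$$ b(x, z) = \sum_{e} r_e\!\left(\frac{z + \sqrt{(x - x_e)^2 + z^2}}{c}\right), $$

with $r_e$ the RF trace of element $e$ at lateral position $x_e$ and $c$
the speed of sound. Sub-sample delays are linearly interpolated
(nearest-neighbor is an option); delays beyond the recording contribute
zero; no apodization is applied, which keeps the operator linear (a tested
invariant). Choices the acquisition description leaves open, fixed here as
the ubiquitous conventions:

* speed of sound 1540 m/s (standard soft tissue);
* envelope = magnitude of the axial analytic signal; display mapping
  $\mathrm{clamp}(1 + 20\log_{10}(\mathrm{env}/\mathrm{env}_{\max})/DR, 0, 1)$
  with a 60 dB default dynamic range (an all-zero frame maps to zero);
* an isotropic 0.1 mm/px grid, giving 500 × 380 px for the 50 mm depth ×
  38 mm aperture footprint — the smallest regular grid that contains a
  300 × 300 px ROI centered at 0 mm lateral / 20 mm depth;
* mm-to-pixel conversion takes the nearest pixel center with ties broken
  toward the smaller index (tested explicitly); ROI cropping is pure
  windowing, never resampling.

## Stance segmentation

Heel-strike and toe-off are threshold crossings of the vertical GRF at 5%
body weight. Forces are measured in newtons, so the "5% body mass" rule is
implemented as $0.05\,m\,g$ with $g = 9.81\ \mathrm{m/s^2}$ (for 70 kg:
34.335 N). Two choices are ours: a 0.2 s debounce discards super-threshold
runs too short to be stance, and percent-stance resampling uses 101 points
(the biomechanics convention), linear interpolation, endpoints preserved
exactly.

## sEMG spectrum images

The comparative route band-passes each channel at 20–450 Hz (4th-order
Butterworth, applied forward–backward for zero phase; the order is our
choice) and slides a 100-sample window with step 1. Each window is
transformed with an analytic Morlet CWT ($\omega_0 = 6$) at integer scales
1–50 — the wavelet and scale spacing are not dictated by the protocol, so
both are configurable; Morlet is the scalogram default and 50 integer
scales at 1 kHz span pseudo-frequencies 955–19 Hz, covering the EMG band.
The LGS and SOL scalograms (50 × 100 each, coefficient magnitudes, not
squared power) are stacked vertically into a 100 × 100 image — the only
orientation that yields 100 × 100 from two 50 × 100 matrices without
resampling. Min–max normalization uses extrema frozen from the training
split only, so no information leaks from validation or prediction data.

## The network

`build_cnn()` constructs the 31-layer regressor: one image input; seven
sets of convolution (stride 1, 'same' padding) + batch normalization +
ReLU, with average pooling (stride 2, no padding) after sets 1–6; dropout
(p = 0.20) after set 7; one fully connected unit; a regression output.
Filter counts are 8, 16, then 32. Two geometric hyperparameters are not
recoverable from the source material and are fixed as the standard choices
consistent with per-set spatial halving: 3 × 3 kernels and 2 × 2 pooling
windows; both are arguments, not constants. Under those defaults the
pooled spatial track for a 300 × 300 input is
300 → 150 → 75 → 37 → 18 → 9 → 4, so the fully connected layer sees
4 · 4 · 32 = 512 inputs (32 and 288 for 100- and 200-px ROIs), all checked
against an independent shape-propagation oracle in the tests.

Training is stochastic gradient descent with momentum (0.9, the
conventional coefficient) on the mean-squared-error loss, mini-batch 128,
30 epochs, learning rate 0.001 dropping to 0.0001 after epoch 20,
shuffling every epoch, validation every `floor(n_train / mini_batch)`
iterations. Weights are He-uniform (the ReLU-network convention for
"randomly generated" initial weights), batch-norm offset 0 / scale 1.
Inputs are zero-centered by the training-set mean image; that image, like
the batch-norm running statistics, derives from training data only.
Images stream through a datastore interface in mini-batch chunks, so the
full image tensor is never materialized. Every random draw (initialization,
shuffling, dropout masks) comes from named substreams of one root seed,
making training bit-reproducible; the conv/pool arithmetic itself is
written in C++ (im2col + GEMM) and verified against numerical
differentiation.

The cross-validation design is leave-one-speed-out: per held-out speed,
training uses the first five cycles of each other speed (20 cycles),
validation the first five cycles of the held-out speed, prediction the
remaining three cycles of all speeds (15 cycles) — 62.5% of cycles for
fitting, 37.5% for prediction, five folds in all.

## Evaluation

For paired truth/prediction series: regression loss (mean squared
residual), RMSE, N-RMSE (RMSE divided by the subject's peak ground-truth
moment over the prediction cycles), and the coefficient of determination.
Because the defining equations reference both series' means, $R^2$ defaults
to the squared Pearson correlation; the residual form
$1 - SS_{res}/SS_{tot}$ is available via `form = "residual"` — the two
coincide when the prediction-truth fit is near the identity line, which is
the regime of interest. Agreement is additionally summarized by an OLS fit
of prediction on truth (slope, intercept, SEs, p-values), with the
45-degree line as reference.

Group comparisons are normality-gated: Shapiro–Wilk per condition at
$\alpha = .05$; if all conditions pass, one-way repeated-measures ANOVA
with Tukey HSD (3+ conditions) or a paired t-test (2 conditions); otherwise
Friedman with a Tukey-style mean-rank (Nemenyi) post hoc, or the Wilcoxon
signed-rank test. All tests are two-sided; significance is flagged at
.05/.01/.001. Identical conditions are reported as "no difference
anywhere" rather than an undefined statistic.

## The synthetic generator

The generator emulates the study conditions so that every stage is
testable without recordings: five treadmill speeds (0.50–1.50 m/s), eight
stance cycles per speed, 1000 Hz analog channels trigger-synchronized with
1000 frames/s imaging, and a moment whose peak grows with speed. Where the
protocol fixes no value, the generator picks one physiologically sensible
number once:

* **Moment profile**: a sin²-type bump, zero at heel-strike and toe-off,
  peaking at 75% stance (push-off); peak = 60 + 50 · speed Nm (≈ 85–135 Nm
  over the speed range, typical adult magnitudes), perturbed by 3%
  cycle-to-cycle noise. Within-subject variability is not characterized in
  the source protocol, so it is a config parameter, not an asserted value.
* **Stance duration**: linearly 0.8 s at 0.50 m/s down to 0.55 s at
  1.50 m/s (frame counts per stance must fall with speed).
* **GRF**: a double-peaked bump (≈ 1.1 body weight maximum) that is zero
  outside stance and exceeds the 5% body-weight threshold within ~2 samples
  of the scheduled boundaries, so event detection is exactly recoverable.
* **sEMG**: band-limited noise amplitude-modulated by the moment envelope
  advanced by a 50 ms electromechanical lead (inside the physiological
  30–150 ms window), per-channel seeded gains.
* **Images**: a static per-cycle multiplicative speckle field
  (exponentiated smoothed Gaussian) times bright oblique fascicle-like
  bands whose inclination (10°–45°), spacing (14–8 px) and brightness are
  deterministic monotone functions of the instantaneous moment normalized
  by the dataset peak — the simplest texture realizing the premise that the moment is
  instantaneously encoded in the muscle image. In `rf_mode` the generator
  instead emits point-scatterer RF channel data for beamformer tests.

What the generator does **not** emulate: acoustic wave propagation, muscle
mechanics (no Hill-type model), swing-phase data, inter-subject anatomy,
probe motion, or out-of-plane decorrelation. Passing tests therefore show
that the pipeline recovers a moment that is monotonically encoded in image
texture under speckle — not that the method works on any particular human
recording.

## Scaled study conditions for the checks

The test suite and `scripts/acceptance.R` run the end-to-end recovery at a
reduced problem size chosen once as the package's reference desk-scale
experiment: 100 Hz frame/analog rate (so a five-speed, eight-cycle dataset
is ~2,700 frames of 100 × 100, with ~1,700 in a training fold), held-out
speed 1.00 m/s (an interior speed, so prediction interpolates the
speed–moment relation rather than extrapolating past the training range),
and a training schedule scaled to the smaller iteration count: mini-batch
64, 5 epochs, learning rate 0.003 dropping to 0.0003 after epoch 4. At
~50 iterations the paper-scale rate of 0.001 barely moves the loss, so the
scaled schedule triples it; all other training conventions are unchanged.
Under these conditions the held-out-speed prediction reaches N-RMSE in
the 0.08–0.13 range depending on the seed, with Pearson r above 0.99, and
the ultrasound route clearly outperforms the sEMG scalogram route on the
same architecture — consistent in regime with, but not numerically
comparable to, results on real walking data.

## Numerical notes and degenerate inputs

* Batch-norm uses $\epsilon = 10^{-5}$ and biased batch variance; running
  statistics update with rate 0.1 and are frozen at inference.
* The conv bias gradient is identically zero under batch normalization
  (the mean subtraction absorbs it); it is still carried for completeness.
* All-zero RF frames beamform to all-zero images; an all-zero envelope
  log-compresses to an all-zero image rather than $-\infty$.
* Pooling drops a trailing row/column on odd sizes (`floor((n - 2)/2) + 1`),
  which is exactly what the shape oracle encodes.
* An all-zero GRF trace yields an empty event list, not an error; a
  constant metric matrix yields "no significant differences", not a
  division by zero.
* Training aborts with a divergence error (reporting the iteration) on a
  non-finite loss rather than continuing silently.

## Known limitations

The CNN engine is single-threaded C++ via im2col/GEMM — adequate for the
desk-scale experiments here, not tuned for the 240k-image scale of a real
acquisition campaign. The generator's texture model is a caricature of
muscle echo structure; architectural realism (fascicle curvature,
aponeuroses, probe pressure artifacts) is out of scope. The CLI is a thin
front end for the pipeline stages; vendor RF formats and DICOM are not
ingested.
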