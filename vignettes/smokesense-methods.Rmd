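---
title: "Methods: thermal and NIR detection of smoke contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal and NIR detection of smoke contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesense)
```

## Model and assumptions

### Thermal stream

A radiometric image is a matrix of leaf-scale temperatures in degrees
Celsius. Two painted reference leaves are photographed in the same frame:
a water-sprayed *wet* reference approximating a fully transpiring leaf
(temperature $T_{wet}$) and a petroleum-jelly-coated *dry* reference
approximating a non-transpiring leaf ($T_{dry}$, with $T_{dry} > T_{wet}$
enforced). Canopy pixels are assumed to lie between the two physical
bounds, so the mask keeps exactly the closed interval
$[T_{wet}, T_{dry}]$; sky is colder than the wet bound and sun-lit posts
or soil hotter than the dry bound.

From a mean canopy temperature $T_c$ the package computes

$$\mathrm{CWSI} = \frac{T_c - T_{wet}}{T_{dry} - T_{wet}}, \qquad
  I_g = \frac{T_{dry} - T_c}{T_c - T_{wet}},$$

with the algebraic identity $\mathrm{CWSI}\cdot(1 + I_g) = 1$. $I_g$ is
proportional to stomatal conductance $g_s$ under the standard
energy-balance linearisation, which motivates the through-origin
calibration $I_g = b\, g_s$ implemented in `origin_fit()`. The fit
reports the slope $b = \sum xy / \sum x^2$ and a coefficient of
determination computed against the *centered* total sum of squares; with
this convention a through-origin line can score poorly (even negatively)
when the data do not pass near the origin trend, which is exactly the
diagnostic used to detect decoupling in smoked vines.

Smoke exposure is assumed to disturb stomatal behaviour *heterogeneously*:
individual leaves close stomata to different degrees, so the whole-canopy
mean $I_g$ no longer tracks porometer-style $g_s$ measurements, while
control canopies keep a tight proportional relationship. Classification
does not rely on that calibration; it uses the spatial pattern. Each
image is subdivided into an $m\times n$ grid and each cell contributes
its mean temperature, $I_g$ and CWSI, giving $3mn$ features
(27, 75, 147, 300 for the four supported grids).

### NIR stream

Berry reflectance $R(\lambda)$ is converted to apparent absorbance
$A = \log_{10}(1/R)$, restricted to 700–1100 nm (401 points on a 1 nm
grid), and differentiated twice with a Savitzky–Golay filter. The second
derivative suppresses additive baseline offsets and linear slopes —
including the deliberate between-cultivar absorbance offset in the
generator — and sharpens the overtone bands; the O–H/C–H band near
982 nm carries the contamination signal. One network with three linear
outputs regresses glycoconjugated guaiacol in berries (µg/kg), the same
compound in wine (µg/L) and free guaiacol in wine (µg/L) simultaneously;
targets are min–max scaled to $[-1, 1]$ per column for training and
back-transformed for reporting.

### Networks

Both streams use one hidden layer of tanh units. Classification uses a
softmax output with mean cross-entropy loss; regression uses linear
outputs with mean squared error. The model-selection loop
(`select_model()`) crosses a set of training algorithms with hidden
widths {3, 7, 10} ("neuron trimming") and ranks by test-set score. The
training algorithms are implemented directly in R:

* scaled conjugate gradient (`scg`) — Møller's Hessian-free CG with
  Levenberg–Marquardt-style scaling ($\sigma_0 = 5\cdot10^{-5}$,
  $\lambda_0 = 5\cdot10^{-7}$);
* resilient backpropagation (`rprop`, the iRprop$^-$ variant; step
  factors 1.2 / 0.5);
* Levenberg–Marquardt (`lm`) — per-sample Jacobians, damping ladder;
  for classification the Jacobian is propagated through the softmax;
* batch gradient descent with momentum (`gdm`; rate 0.1, momentum 0.9)
  and with adaptive rate (`gda`; rate 0.05, grown 1.05× on improvement,
  cut 0.7× when the loss rises by more than 4%);
* incremental (per-sample) weight-and-bias updates in sequential
  (`seq_wb`) or shuffled (`rand_wb`) presentation order (rate 0.05,
  momentum 0.6, rate decay 0.99 per epoch).

Batch, three-stage algorithms use a 60/20/20 train/validation/test
partition with early stopping (patience `max_fail = 6` epochs on the
validation loss); the incremental algorithms use a 70/30 partition
without a validation stage, matching their historical usage. Partition
sizes follow a round-half-up rule on the minor fractions with the
training set absorbing the remainder, which yields 28/10/10 and 34/14
for 48 samples and 78/33 for 111.

A model is flagged as overfitting when the relative train−test score gap
exceeds `overfit_margin = 0.10`; the selection returns the best
*unflagged* model and errors (with the full leaderboard attached) if all
candidates are flagged. 10% is deliberately loose: with test sets of
10–33 samples a single misclassification moves accuracy by 3–10
percentage points, so a tighter margin would mostly flag noise.

## Parameter defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| mask interval | closed $[T_{wet}, T_{dry}]$ | the references are physical bounds; a canopy pixel *at* a bound is valid |
| grid sizes | 3, 5, 7, 10 | the four protocol grids; near-equal integer partition, remainder pixels assigned to the last rows/columns |
| camera range | −20 to 1200 °C | radiometric validity range used for TIFF scaling and input validation |
| field of view | 140 × 110 cm | sets the cm²-per-cell geometry (a 10×10 cell of a 240×320 image covers 154 cm², roughly two average leaves) |
| SG filter | window 15, order 3, $m = 2$ | shortest window that leaves quadratic features exact while suppressing point noise on a 1 nm grid |
| NIR window | 700–1100 nm | instrument range containing the 982 nm band; avoids visible pigments |
| hidden widths | 3, 7, 10 | the trimming ladder; 10 is the full-size reference network |
| `max_epochs` | 300 | all batch trainers converge or early-stop well before this on the study-scale problems |
| `overfit_margin` | 0.10 | see above |
| standardisation | training split only | test data must not leak into scaling |

## The synthetic generator

Field campaigns of this kind (smoke-tent exposure of vineyard rows,
paired thermography and berry spectroscopy) are not redistributable, so
the package generates data with the statistical structure the analysis
assumes. Defaults are the study conditions; they were fixed before the
benchmark tests were run and are not tuned per seed.

**Scenes** (`make_scene()`, `make_dataset()`): 240 × 320 px, leaf cover
fraction 0.55 built from random elliptical patches of 50–80 cm²
equivalent area, sky pixels at 8 °C, occasional hot non-canopy material
at 40 °C, exact reference patches embedded at known ROIs with values
$T_{wet} = 20$, $T_{dry} = 32$. Leaf temperature follows a linear
surrogate $T = T_{dry} - c\, g_s$ (coupling $c = 0.0175$ °C per
mmol m⁻² s⁻¹, clipped to the reference interval) instead of a full
energy balance: it is sufficient to produce the monotone $g_s$–$I_g$
relationship and is analytically invertible, which the tests exploit.
Control scenes draw $g_s$ per vertical band (top 250, mid 300, bottom
150 mmol m⁻² s⁻¹, sd 40) to mimic canopy light gradients. Smoked scenes
multiply the within-scene sd by a patchiness factor (default 3) and mix
the per-leaf draws with an independent scene-level component with weight
$1 - 1/\mathrm{patchiness}$, which both roughens the spatial field and
decouples the whole-image mean from the nominal $g_s$. Per-scene mean
conductances are scaled by a clipped $N(1, 0.25)$ factor so the dataset
spans a realistic $g_s$ range. Pixel noise sd is 0.15 °C (typical
microbolometer NETD plus leaf-angle variation).

**Spectra** (`make_spectra()`): 7 cultivars × 16 berries, half control
and half smoked. A latent dose $u$ drawn per berry maps all three
targets into their printed control/smoked concentration ranges, so the
targets are mutually consistent. Spectra are smooth absorbance baselines
plus Gaussian bands at 982, 1190 and 1450 nm; the 982 nm band amplitude
and width grow with the normalised contamination load
(`link_strength = 0.15`). White cultivars sit 0.05 absorbance above red
ones — a deliberate confound that the second derivative must remove.
Reflectance noise sd is $5\cdot10^{-4}$, the scale expected after
instrument-internal scan averaging (single-scan noise near $10^{-2}$
averaged over a few hundred scans).

**What is *not* emulated:** radiative transfer, emissivity and
reflected-sky corrections, wind- or humidity-driven reference drift,
biochemical pathways from smoke volatiles to stomatal response, berry
ripening trends, and any smartphone/UAV deployment concerns. Absolute
concentrations are uniform draws within ranges; the generator makes no
claim about real concentration distributions.

## Numerical choices

* **Raster formats.** The primary text format is headerless CSV with
  2-decimal temperatures (0.01 °C granularity, below sensor noise).
  TIFF rasters store values scaled to $[0,1]$ over the camera range, so
  a round trip through single-precision TIFF is accurate to well under
  0.01 °C but not bit-exact; the tests assert a 10⁻³ °C bound.
* **Stable losses.** Softmax cross-entropy is computed via log-sum-exp;
  probabilities are never logged directly.
* **$I_g$ singularity.** $I_g \to \infty$ as $T_c \to T_{wet}$. Index
  computation returns `NA` with a warning at or below the wet bound. In
  grid feature extraction, a cell whose mean sits exactly at $T_{wet}$
  (possible when a cell contains only the wet reference patch) is nudged
  to $T_{wet} + 0.01$ so the feature matrix stays finite; empty cells
  are imputed with the image-wide canopy means and flagged in the
  `imputed` attribute. Out-of-interval $T_c$ passed directly to
  `cwsi()`/`ig()` yields a value plus a `beyond_reference` flag rather
  than silent clipping.
* **Determinism.** Every stochastic function takes a seed and restores
  the caller's RNG state (`with_seed()`), so library calls never disturb
  a user's random stream; derived per-scene seeds are drawn below
  $2^{31}$. Pipeline runs write a manifest (seed, configuration,
  package versions, MD5 of every artifact), and a rerun with the same
  seed reproduces the artifacts bit for bit.
* **ROC.** The ROC curve is a full threshold sweep anchored at (0,0) and
  (1,1); AUC is the trapezoid integral. The test suite cross-checks it
  against `pROC` and against the Mann–Whitney U statistic.

## Limitations

The classifiers and regressors here are validated on synthetic data
only; performance numbers quoted by the tests and the acceptance script
measure the pipeline's behaviour under the generator's assumptions, not
field performance. The linear conductance surrogate cannot represent
situations where air temperature, wind or radiation change between the
reference reading and the canopy image. The NIR model is a
single-instrument, single-grid model: spectra must share the exact
wavelength grid, and no calibration transfer between instruments is
attempted. Multi-target regression assumes the three compounds are
driven by a common latent exposure; strongly discordant targets would
need the per-target mode.
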