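---
title: "Multispectral tea-canopy phenotyping with teaspec: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral tea-canopy phenotyping with teaspec: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaspec)
```

## The problem

Oolong tea quality is tied to the cultivar of *Camellia sinensis* it is made
from, and cultivars also differ in their germination period — the
phenological earliness class (early, mesophytic or late) that governs when a
plantation is plucked.  Identifying cultivar and earliness in the field
normally takes an expert eye.  `teaspec` implements an image-analysis
alternative: five-band multispectral canopy photographs (blue 475 nm, green
560 nm, red 668 nm, red edge 717 nm, NIR 840 nm) are calibrated, segmented,
summarised into 86 colour/texture/spectral indicators, screened to an
informative subset, and classified with a kernel support vector machine
whose hyperparameters are tuned by population metaheuristics; the
germination period is then recovered from cultivar-mean indicators by Fisher
discriminant analysis.

Because no public canopy imagery accompanies this problem, the package
includes a first-class synthetic generator whose outputs carry full ground
truth.  Every stage is therefore testable end to end, and all numbers the
package reports are computed, not assumed.

## The synthetic study conditions

`synthetic_spec()` defines the conditions every test and the acceptance
script run under.  Its defaults emulate a field campaign over 18 oolong
cultivars — 5 early (Baxian, Yellow Rose, Huangyan, Dangui, Jinmudan), 5
mesophytic (Baijiguan, Beidou, Benshan, Maoxie, Foshou) and 8 late
(Shuixian, Rougui, Jiulongpao, Qilan, Ruixiang, Dahongpao, Tieluohan,
Tieguanyin):

* **Spectra.** Each cultivar has a five-band mean reflectance built from a
  healthy-vegetation spectrum (B 0.04, G 0.09, R 0.05, RE 0.30, NIR 0.50),
  multiplied by a germination-stage factor (earlier-flushing canopies are
  denser: higher NIR/red-edge, slightly greener; late cultivars the
  opposite, within ±7%) and by fixed per-cultivar offsets of up to ±10%
  drawn once and frozen.  The stage-level shifts are what the germination
  discriminant later recovers; the cultivar offsets are what the classifier
  separates.
* **Within-class variation.** Every image perturbs its cultivar's band
  means by a Gaussian deviation of sd 0.002 (reflectance units) — plant-to-
  plant biological variation that calibration cannot remove — plus per-pixel
  sensor noise of sd 0.004.  The offset amplitude and within-class sd were
  calibrated once so that cultivar classes overlap slightly: the tuned
  classifier then sits in the low-to-mid 90% test-accuracy regime rather
  than at a saturated 100%, and hyperparameter tuning has something to do.
* **Texture.** Canopy reflectance is modulated multiplicatively by a field
  of anisotropic Gaussian "leaf blobs"; per-cultivar blob scale,
  eccentricity, orientation and modulation amplitude drive differences in
  the second-order (GLCM/LBP) statistics.  The field is standardised to
  mean 0 / sd 1, so the modulation is unbiased and band means stay
  recoverable.
* **Background.** A smooth random field assigns a `background_fraction`
  (default 35%) of pixels to background; 30% of the background is shadow
  (canopy spectrum × 0.3) and the rest soil.  The soil spectrum (B 0.10,
  G 0.17, R 0.18, RE 0.24, NIR 0.30) keeps the excess-green-minus-excess-red
  index slightly negative, so soil and shadow fall on one side of the
  vegetation/background split — the property the segmentation stage relies
  on.
* **Panel and illumination.** A square barium-sulfate-style reference panel
  of known reflectance (0.5 in all bands) occupies one corner, noise- and
  texture-free.  A per-image multiplicative illumination factor
  (log-normal, sd 0.05) scales everything before quantisation to digital
  numbers (reflectance 1.0 ↦ DN 10000, 16-bit ceiling).

What the generator does **not** emulate: radiative transfer and BRDF
effects, sun-angle geometry, band misregistration, mixed border pixels,
seasonal drift.  Passing tests therefore demonstrate correctness of the
algorithms and the internal consistency of the pipeline under these
conditions, not field-level accuracy claims.

## Calibration and segmentation

Radiometric calibration uses the in-scene panel: per band,
\(R_i = DN_i \cdot R_s / \overline{DN_s}\), with \(\overline{DN_s}\) the
arithmetic panel-mean digital number.  The mapping is linear in DN, so a
uniform illumination change cancels exactly; panel pixels calibrate back to
their known reflectance to machine precision.

Vegetation is enhanced with \(ExGR = (2G-R-B) - (1.4R-G) = 3G - 2.4R - B\),
computed on calibrated reflectance so thresholds are illumination-free, and
thresholded with Otsu's method over a 256-bin histogram.  Two numerical
choices matter:

* **Plateau ties.** Between well-separated modes the between-class variance
  is constant across empty bins; the threshold is taken at the plateau
  midpoint, i.e. halfway between the modes.
* **Degenerate scenes.** Otsu presumes a canopy/background mixture.  If the
  class below its cut still has positive mean ExGR, the scene is
  background-free and Otsu would split the canopy; the rule then falls back
  to the physical zero threshold (ExGR > 0 ⇔ vegetation).  A fixed
  threshold is also available via `segment_canopy(img, threshold = 0)`;
  note that shadow retains the canopy's spectral shape, so zero-thresholding
  counts shadow as vegetation by design.

The reference-panel region is always excluded from the mask.  Geometric
band registration is a no-op hook (`register_bands()`): synthetic bands are
generated co-registered, and the hook marks where a feature-based
registration step would plug in for real imagery.

## The 86-indicator registry

`feature_registry()` fixes the order and naming of all indicators:

* 9 colour values — masked means of pseudo-RGB r, g, b (the R-, G-, B-band
  reflectances clipped to [0,1]); h, s, v from per-pixel HSV (each scaled
  to [0,1]); and CIELab L\*, a\*, b\* from per-pixel conversion treating
  pseudo-RGB as sRGB with D65 white (columns `L`, `a_star`, `b_star`).
  Per-pixel conversion before averaging is the default; the means of the
  converted values are reported.
* 7 colour indices computed from the *mean* L\*, a\*, b\*: LI, AI, AL, AB,
  NDLBI, NDALI, NDABI.
* 8 GLCM statistics (Asm, Ent, Con, Cor, Mea, Var, Hom, Dis) of the
  grey-level co-occurrence matrix at distance 1, accumulated symmetrically
  over the four angles 0/45/90/135° and normalised to sum 1.  The texture
  channel is the luminance of the pseudo-RGB composite
  (0.299r + 0.587g + 0.114b) quantised to 64 levels; only pixel pairs with
  both ends inside the canopy mask are counted.  Entropy uses the natural
  logarithm with 0·log 0 ≡ 0.
* 7 LBP statistics (mu, sigma, S, K, `G_lbp`, E, `Rs`) of the 256-bin
  histogram of classic 8-neighbour radius-1 local binary pattern codes on
  the unquantised luminance; a neighbour equal to the centre sets its bit
  (≥ rule), and codes are only formed where the full 3×3 neighbourhood lies
  in the mask, so mask-external pixels can never leak in.  `sigma` is the
  histogram standard deviation (its square enters the relative smoothness
  `Rs` = 1 − 1/(1+σ²)), S the third central moment, K the kurtosis
  σ⁻⁴·Σ(g−μ)⁴P, `G_lbp` the energy ΣP² and E the entropy in bits.  The LBP
  energy and smoothness are named `G_lbp` and `Rs` because the plain
  symbols G and R already name the green and red band means.
* 5 band reflectance means (B, G, R, RE, NIR) over the mask.
* 50 vegetation indices, evaluated from those masked mean band reflectances
  exactly as printed in the registry's formula table — including variants
  written on the blue/green bands (EVI, VOG, MTCI as registered here) —
  rather than silently normalised to other literature conventions.
  Duplicate formulas (RVI = SR, PGR = RGI, GRVI = NGRDI) are kept and serve
  as an internal consistency check.

**NaN policy.** Any ratio whose denominator has magnitude below 1e-12 is
set to 0 (with a warning available at the computing site), keeping feature
tables rectangular for the classifier.

## Feature screening: UVE, LASSO, VIP

**UVE.** Uninformative variable elimination appends one standard-Gaussian
noise column per real variable, fits a multi-response PLS2 (SIMPLS) against
the one-hot cultivar indicator on resampled subsets — leave-one-out for
n ≤ 200, otherwise 20 Monte-Carlo 80% subsets — and scores each variable by
the reliability of its regression coefficient, mean(b)/sd(b) over
resamples, taking the maximum magnitude over response columns.  A real
variable survives if its |reliability| exceeds the largest |reliability|
among the noise variables (the multiplier on that cutoff is configurable).
The PLS component count, when not given, is chosen by 5-fold CV on the
response error, capped at 10.

**LASSO.** The surviving variables enter an L1-penalised regression on the
class indicators (glmnet coordinate descent: a single 0/1 response for two
classes, the grouped multi-response gaussian family for more), over a
100-point log-spaced λ grid descending three decades from λ_max.  The
reported λ minimises the mean cross-validated squared error
(`rule = "min"`; the one-standard-error rule is a flag), and the retained
set is the union of nonzero supports across response columns.

**VIP.** Variable importance in projection from the same PLS2 machinery:
\(VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SS_a}\).
The squared scores average to exactly 1 over variables — an identity the
tests assert on every fit.

On image data at the package's desk scale, the 86 → after-UVE →
after-LASSO cascade is strictly decreasing; the exact counts are
data-dependent, and the tests assert the shape rather than any particular
pair of numbers.

## SVM classification and hyperparameter search

Samples are split 6:2:2 into training/test/validation per class with
largest-remainder rounding (remainder ties resolve train > test >
validation).  The classifier is a soft-margin SVM with RBF kernel
\(K(x,y) = e^{-g\lVert x-y\rVert^2}\) and one-vs-one voting (libsvm via
e1071), with z-score standardisation fit on the training rows and frozen
into the model.  The tuning fitness is 5-fold stratified cross-validation
accuracy on the training split only, with per-fold standardisation.

Three from-scratch metaheuristics search (c, g) over c, g ∈ [0.01, 100] on
log10 scale (bounds bracket the useful RBF regime with margin):

* **GA** — real-coded: tournament selection of size 2, arithmetic crossover
  with probability 0.8, Gaussian mutation with probability 0.1 and sd 10%
  of the range, elitism of one.
* **PSO** — inertia weight linear 0.9 → 0.4, c1 = c2 = 2, velocity clamped
  to 20% of the range, boundary clipping.
* **GWO** — canonical grey wolf: the three best wolves (α, β, δ) steer the
  pack; control scalar a decreases linearly 2 → 0; per wolf and leader,
  A = 2a·r₁ − a, C = 2r₂, D = |C·X_leader − X|, candidate = mean of the
  three leader-driven positions.

Default budgets are 20 agents × 50 iterations; the bundled tests and the
acceptance script use 12–15 × 15 so a full run stays within a couple of
minutes, and sphere/Rastrigin benchmarks plus an exhaustive 50×50 log-grid
oracle bound the search quality.  All traces are non-decreasing by
construction and every optimizer is bit-deterministic under its seed.

Two ablations mirror learning-curve studies: `dataset_scale_ablation()`
re-runs the tuned pipeline on nested per-class subsamples (1/5 … 5/5 at
3:1:1 ratios) and `per_class_reduction_ablation()` removes a fixed number
of samples per class per round until any class would fall below the split
minimum.  Both re-tune per subset by default.

## Germination-period discrimination

The 15 canonical indicators (h, s, r, b, L, Asm, Var, Hom, Dis, sigma, S,
G_lbp, RVI, DVI, VOG — `b` is the blue colour mean and `L` the CIELab
lightness) are averaged per cultivar; the 18 cultivar-mean vectors, with
their stage labels, enter a Fisher discriminant: standardise, form
within- and between-class scatter, solve
\(S_b w = \lambda (S_w + \gamma I) w\) and keep the two leading axes
(at most classes − 1).  With 18 observations and 15 variables \(S_w\) is
near-singular, so the default ridge is γ = 1e-3·tr(S_w)/p;
`regularization = 0` recovers the classical solution (and the two-class
closed form \(S_w^{-1}(\mu_1 - \mu_2)\) exactly) when \(S_w\) is
invertible.  Scores are centred so the grand mean projects to the origin,
and classification is by nearest class centre in score space, with exact
ties breaking to the first class in early < mesophytic < late order.  A
Mahalanobis-style rule was considered and rejected for the default: with
three classes and two axes the nearest-centre rule is the transparent
choice, and the class covariances are estimated from at most 8 points.

The package also ships the published two-function reference model
(`printed_germination_model()`, applied by `apply_printed_model()`): 15
coefficient pairs and three class centres kept verbatim as constants.  Its
coefficient magnitudes indicate standardised inputs, and the identity of
its `b` and `L` symbols is ambiguous in the source (colour b vs CIELab b\*;
L vs L\*); the package resolves them as the blue colour mean and L\*, and
documents that resolution rather than guessing silently.  The fitted-model
route is the primary analysis; the printed model is a fixed reference for
regression tests.

## Determinism

Every stochastic component draws from an isolated RNG stream seeded
explicitly; nested stages receive child seeds derived from their parent.
One master seed in `run_config()` therefore fixes the synthetic imagery,
the segmentation, the screening, the folds, the optimizer trajectory and
the discriminant — `run_pipeline()` hashes every stage output into its
manifest, and re-running a config reproduces the hashes byte for byte.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at 18
cultivars × 15 images of 48×48 pixels (270 images), selection fixtures of
150–240 samples, and optimizer budgets of 12–30 agents × 15–100
iterations.  These sizes were chosen as the smallest at which every
qualitative property of the analysis — class overlap, cascade shape,
tuning benefit, stage separation — is stably expressed.

## Known limitations

* Vegetation-index formulas follow the registry's printed table verbatim;
  several differ from common literature forms (e.g. EVI/VOG/MTCI written on
  blue/green), so absolute index values should not be compared against
  other sources.
* The colour pipeline treats linear reflectance composites as sRGB for HSV
  and CIELab; this is a convention, not colourimetry.
* The UVE cutoff (max noise reliability) is conservative on heavily
  collinear tables; `cutoff_multiplier` exposes the knob.
* Synthetic texture is a blob-modulation model: adequate to make GLCM/LBP
  statistics class-informative, not a model of real leaf arrangement.
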