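---
title: "Methods: colour-texture classification of tear film lipid layer patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-texture classification of tear film lipid layer patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The tear film's outermost lipid layer controls tear evaporation; its
thickness is graded in the clinic by the interference patterns it shows
under specular illumination. The Guillon grades, in increasing thickness,
are *open meshwork* (a faint, sparse grey mesh), *closed meshwork* (a
denser grey mesh), *wave* (oriented grey waves), and *colour fringe*
(brown/blue interference fringes on a whitish background). Grading by eye
is slow and subjective. This package implements an automatic pipeline:
locate the region of interest (ROI) in an eye photograph, describe it as a
colour texture, classify it into one of the four grades, and compare
candidate classifiers statistically.

## Pipeline stages

### ROI extraction

The acquisition protocol makes the gradeable area — the bottom part of the
iris — the most illuminated region of the frame. The image is converted to
CIE Lab and the luminance channel `L` is matched against a set of
illumination-profile templates by Pearson-type normalised
cross-correlation (NCC); the crop under the best template's subtemplate
mask is the ROI. Window statistics use integral images and the inner
product uses an FFT correlation; a direct double-loop Pearson oracle in
the test suite confirms both paths agree to 1e-10 on small instances.
Zero-variance windows receive score 0 and are flagged; a fully constant
image raises an explicit no-ROI error. Ties break by template order, then
row-major placement; coordinates are 0-based with half-open windows.

The clinical template set is not published, so `generate_templates()`
builds a deterministic stand-in: Gaussian bright-band and crescent
profiles at three scales. The contract it supports — and the only thing a
green test establishes — is recovery of a planted bright band, not
clinical fidelity.

### Texture descriptors

Five families map a single-channel image to a fixed-length vector:

* **Butterworth bands** (16 per band): the spectrum is multiplied by the
  radially symmetric bandpass gain `1/(1 + ((w - wc)/w0)^(2n))`, the band
  output is renormalised to `[0, 1]`, and summarised by a 16-bin
  histogram. The published bank gives only "9 second-order filters
  covering the spectrum", so the default centres tile `(0, 0.5]`
  cycles/pixel uniformly with `w0` equal to half the spacing; both are
  config-overridable and results should not be read as sensitive to this
  stand-in.
* **Haar wavelet statistics** (12): two orthonormal pyramid scales; mean
  and absolute average deviation of the input, `LL1` and `LL2`, plus the
  energy of the six detail subbands. Energy is the *mean* squared
  coefficient (not the sum) so values are comparable across scales; odd
  dimensions are trimmed by one row/column with a warning.
* **Co-occurrence / Haralick** (28): grey-level co-occurrence matrices at
  the `4d` orientations of the Chebyshev ring of radius `d` (d = 1: 0°,
  45°, 90°, 135°), with symmetric counting and 32-level uniform range
  quantisation (the source is silent on both; 32 levels keep the 14
  statistics stable on ~100 px ROIs). The descriptor is the mean and the
  range of the 14 Haralick statistics across matrices. Entropies use log
  base 2 with `0·log 0 := 0`; statistics needing marginal variance
  (correlation, IMC1/2, MCC) return 0 with a degeneracy flag on constant
  regions so descriptors stay finite.
* **Gaussian Markov random field** (4d): the standardised image is
  regressed on the symmetric neighbour-pair sums `Q_c` within Chebyshev
  distance `d` (least squares over interior pixels, margin `d`; toroidal
  wrapping was rejected as physically implausible). The descriptor is the
  directional residual variance `f_i = mean((X - beta_i Q_i)^2)`, with
  `beta_i` the i-th component of the jointly fitted coefficient vector —
  the directional-variance reading of the model; this interpretation is
  noted, not derived.
* **Gabor bank** (16 × n_bins, n_bins ∈ {3, 5, 7, 9}): 4 frequencies
  {1/16, 1/8, 1/4, 3/8} cycles/pixel × 4 orientations {0°, 45°, 90°,
  135°}, `a = b` set for a one-octave half-magnitude bandwidth, phase 0.
  Only the counts (4 × 4) are published; the frequencies are declared
  stand-ins. Magnitude responses are summarised by nonequidistant-bin
  histograms.

**Nonequidistant binning.** Filter responses pile up in the low values, so
equal-width histograms waste resolution. Bin edges are placed at empirical
quantiles of a calibration sample, making the calibration histogram
uniform and the low bins narrow. In the cross-validated pipeline the
calibration sample is the training fold only; a standalone descriptor
self-calibrates on its own response (documented on the function).

### Colour spaces

Descriptors are computed in grayscale (ITU-R BT.601 weights 0.299, 0.587,
0.114 — the convention is declared, not derived), channel-wise in CIE Lab
(sRGB primaries, D65 white; the source names only "natural illumination"),
and in the opponent space `RG = R − p∗G`, `GR = G − p∗R`,
`BY = B − p∗(R+G)` with `p` a unit-DC lowpass. The lowpass is unspecified
at the source; a Gaussian with σ = 2 px and reflective borders is the
standard opponent-smoothing choice here, and σ is a config key
(`colour.lowpass_sigma`) precisely because it is a guess — behaviour
should be (and in our tests is) robust for σ in [1, 4]. Lab and opponent
descriptors are the concatenation (L, a, b) / (RG, GR, BY) of the
per-channel descriptors, so they are three times the grayscale length.

### Classification

Five families, all implemented in-package because no classifier library
is assumed at run time: Gaussian naive Bayes; a *logistic model tree*
approximated as a depth-3 CART tree with ridge-regularised multinomial
logistic models at leaves holding at least 10 samples (full LogitBoost
LMT induction is out of scope; the approximation captures "trees with
logistic models at the leaves" at tractable complexity); a *random tree*
(single unpruned CART tree, random `sqrt(p)` feature subset per node); a
*random forest* (100 bagged random trees, majority vote); and an RBF
support vector machine trained by a compact SMO solver in C++ (one-vs-one
for four classes). SVM defaults are C = 10, γ = 1/p after z-scoring, with
an optional inner 5-fold grid search over C ∈ 10^{−1..3}, γ ∈ 10^{−4..1};
the original study does not state kernel or parameters, so all defaults
are declared and recorded in output metadata.

Evaluation is stratified 10-fold cross-validation with a fixed default
seed (20120405). Standardisation for NB/SVM is fitted per training fold;
so are descriptor binnings when the pipeline runs end-to-end. Accuracy is
the percentage of pooled correct predictions, equal to the fold-size
weighted mean of per-fold accuracies. If a class has fewer members than
folds, stratification degrades gracefully (the class misses some folds).

### Statistical comparison

Each classifier's accuracies across experimental conditions (frequency
bands, distances, neighbourhood radii, histogram sizes) form a sample.
The workflow is: (1) a Lilliefors normality test per classifier —
a Kolmogorov–Smirnov sup-distance against the normal CDF with estimated
mean/SD, with Monte-Carlo p-values (10^4 seeded replicates) rather than
lookup tables, for exact small-n behaviour; (2) one-way ANOVA across the
classifiers that pass; (3) Tukey HSD (studentized range, equal group
sizes) only if the ANOVA rejects at α = 0.05. The *best set* is the top
classifier plus every classifier not significantly below it.

Because the published exclusions depend on an unstated Lilliefors
variant, `compare_classifiers()` accepts a pinned `excluded` list that
overrides the gate; the reproduction suite uses the documented exclusions
(NB for the Markov Lab/opponent blocks, NB for Gabor Lab, SVM for Gabor
opponent). Treating the condition columns as independent observations
ignores the dependence induced by shared cross-validation folds; this is
reproduced as-is and is a known limitation of the original design, not of
this implementation.

## Reproduction of the published analysis

The per-condition accuracy tables of the reference study are transcribed
as CSV fixtures (2-dp percentages). `reproduce_paper_stats()` recomputes
all 12 ANOVA blocks and the Tukey verdicts: degrees of freedom match
exactly and F and SS within 0.5% relative — the slack covers exactly the
2-dp rounding of inputs that were originally computed on unrounded
multiples of 100/105. Three printed values required judgement calls:

* One between-group SS is internally inconsistent with its own MS × df
  and with total − within; it is flagged as a typo in the reference
  fixture and checked against the reconstructed value (the printed F
  reproduces).
* Four printed "Avg." cells disagree with the mean of their own printed
  row by far more than a rounding artifact (two look like digit
  transpositions). The Tukey verdicts reproduce only with the computed
  means, confirming the row values, not the Avg cells, are authoritative.
  Tests assert the discrepancy explicitly rather than hiding it.
* Remaining Avg. cells can differ from the recomputed mean by one unit in
  the second decimal because the originals averaged unrounded accuracies;
  the tests allow 0.02 for this and nothing more.

## The synthetic world

`generate_dataset()` emulates the reference dataset's shape: 105 images,
29/29/25/22 per class, seeded and deterministic. Meshwork classes are
ridges of thresholded band-limited noise at two densities; waves are
phase-jittered oriented sinusoids; fringes interpolate between brown
(Lab ≈ (55, 15, 30)) and blue (Lab ≈ (55, 5, −35)) endpoints over a
whitish background — endpoint colours chosen once to be unambiguous under
the Lab/opponent analyses. Contrast/scale/orientation jitter is applied
per image; additive Gaussian noise everywhere. Default image size is
128 × 128, on the order of the clinical ROIs.

These classes are texture-separable *by construction*. A green
end-to-end test (co-occurrence d = 5 in Lab + SVM ≥ 85% accuracy, with
permuted labels falling to chance) establishes that the pipeline wiring,
descriptors and classifiers function and discriminate; it does **not**
establish clinical accuracy, which requires the unavailable clinical
images. The published absolute accuracies are therefore reproduced only
through the statistical analysis of their printed tables, never through
image processing.

## Numerical choices and degenerate inputs

* FFT paths (NCC cross term, Butterworth, Gabor) are all checked against
  direct-summation oracles at ≤ 1e-6 on small instances.
* NCC zero-variance windows: score defined as 0, flagged; the detection
  threshold is relative (1e-9 of the window second moment) because
  integral images leave cancellation noise on constant regions.
* Constant images: GLCM collapses to one cell (mass 1); Haralick
  statistics needing marginal variance return 0 + flag; GMRF fitting
  raises an explicit degenerate-model error; ROI extraction raises a
  no-ROI error.
* Quantile bin edges on heavily tied calibration data are nudged by 1e-12
  of the range to stay strictly increasing.
* The Lilliefors type-I calibration test runs 1000 replicates with 1000
  Monte-Carlo draws each (instead of 10^4) purely to stay inside the test
  run-time budget; p-value validity does not depend on the replicate
  count, only its resolution.

## Known limitations

The template set, Butterworth centre frequencies, nonequidistant-bin
calibration, Gabor frequencies, GLCM depth/symmetry and all classifier
hyperparameters are declared stand-ins for unpublished choices; each is
config-overridable. The LMT is an approximation. No amorphous category,
no iris segmentation, no multi-frame video selection, no nonparametric
comparison alternatives.
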