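---
title: "Detecting ragged red fibers in trichrome-stained muscle tiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ragged red fibers in trichrome-stained muscle tiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfdetect)
```

## The problem

Ragged red fibers (RRFs) are muscle fibers with subsarcolemmal accumulations
of abnormal mitochondria. Under Gomori's trichrome stain they show as a red,
granular rim around an otherwise blue-green fiber cross-section, and they are
the histological hallmark of mitochondrial myopathy. `rrfdetect` implements a
tile-level recognition pipeline for 20x light-microscopy fields of such
sections: each acquisition (nominally 1653 x 1239 px) is cut into a regular
grid of 110 x 110 px tiles (15 x 11 = 165 tiles per field), each tile is
summarised by 134 hand-crafted features, and a two-stage cascade of binary
classifiers assigns it one of three labels:

* `waste` — artifacts (bubbles, folds, staining defects) or predominantly
  connective tissue; excluded from fiber-level interpretation,
* `not_ragged` — analyzable muscle tissue without an RRF,
* `ragged` — tissue containing (part of) an RRF.

Stage 1 separates `waste` from tissue on all tiles; stage 2 separates
`ragged` from `not_ragged` among tissue tiles only. The cascade mirrors how
a pathologist works: first discard uninterpretable regions, then look for
the lesion.

## The feature vector

Every tile yields exactly 134 named features, in a fixed order that is part
of the package's public contract (models refuse to predict on a mismatched
schema).

**Colour (39).** The tile is converted to HSV — hue separates the red rim
from the green fiber body far better than raw RGB — and each channel is
summarised by 13 first-order statistics: mean, median, min, max, range,
variance, mean absolute deviation, RMS, skewness, kurtosis, energy, entropy
and uniformity. Moments use the population convention and are computed on
the raw channel values; entropy (base 2) and uniformity come from a 32-bin
equal-width histogram over the observed range. The histogram-vs-raw choice
is deliberately split this way: binning stabilises the two distributional
features while leaving the moment estimates unbiased by bin centering.
Zero-variance inputs (blank waste regions are common) get skewness and
kurtosis 0 rather than NaN so feature vectors stay total.

**Texture (43).** The tile is reduced to BT.601 luminance and quantized to
`Ng = 32` equal-width gray levels over its own min-max range (per-tile
normalisation makes texture features robust to staining intensity). Three
matrix families are computed:

* *GLCM* (21 features): co-occurrences of level pairs at offset distance 1
  along 0, 45, 90 and 135 degrees, accumulated symmetrically and averaged
  over angles. The panel is the standard Haralick-lineage set (contrast,
  correlation, cluster statistics, entropy family, inverse-difference
  family, sum/difference statistics).
* *GLRLM* (11 features): maximal runs of equal level per angle, averaged
  over the same four angles (short/long-run emphasis, nonuniformities, run
  percentage and the gray-level-weighted variants).
* *GLSZM* (11 features): 8-connected zones of equal level (Chebyshev
  distance 1), one matrix for all directions, hence rotation invariant —
  a property the test suite checks explicitly.

The speckled red rim of an RRF is precisely a texture anomaly: it breaks up
large homogeneous zones and short-range co-occurrence, which is what these
panels measure. Matrix builders are verified exactly against brute-force
pixel-pair, run-walking and flood-fill oracles on hundreds of random images.

**Wavelet (52).** A one-level separable 2D DWT with the 8-tap
least-asymmetric Daubechies orthonormal pair (embedded as named constants
and unit-tested against their defining properties) splits the luminance
image into four 55 x 55 subbands; each subband's coefficients are summarised
by the same 13 first-order statistics. Boundary handling is periodic because
it keeps the periodized operator exactly orthogonal: reconstruction is exact
to ~1e-12 and subband energy equals input energy, both enforced in tests.
This choice requires even image dimensions (tiles are 110 px, so the
constraint never binds in practice; odd-sized inputs are rejected with an
informative error). Statistics are computed on the subband coefficients
directly, not on back-projected quarter images.

## Normalisation and leakage

Features are z-scored to zero mean and unit variance (population SD;
zero-variance columns map to 0). The normalisation record is always fitted
on training rows only — inside every cross-validation fold it is refitted on
that fold's training portion — and then applied to validation folds and the
held-out test split. Fitting on all data would leak test information into
training; the no-leakage variant is the package's fixed behaviour and the
test suite asserts that a train-fitted record leaves held-out rows
off-centre.

## The cascade and its tuning

The labelled table is split once, stratified by the three-class label, into
80% training and 20% test; both stages share this split so their test sets
are disjoint from all training activity. At each stage three learners are
benchmarked:

| learner | implementation | search space (random draws) |
|---|---|---|
| random forest | `ranger` | trees 100–1000, mtry 1–134, min node 1–10 |
| gradient boosting | `xgboost` | trees 50–500, learning rate 0.01–0.3 (log), depth 1–8 |
| RBF SVM | `e1071` | cost 2^-5–2^15 (log), gamma 2^-15–2^3 (log) |

Each learner is tuned by random search (50 draws by default) under
stratified 10-fold cross-validation; a draw is scored by its mean
validation F1 (ties broken by mean accuracy, then draw order), with the
positive class being `tissue` at stage 1 and `ragged` at stage 2 and a 0.5
probability threshold (ties map to the positive class). The winning draw is
refitted on the whole training split and all three tuned learners are
compared by test-set AUC; the highest-AUC learner joins the cascade. ROC
curves are computed by an exact threshold sweep whose trapezoidal area
equals the Mann–Whitney pairwise-ranking probability (ties at 1/2), a
property the tests verify against both a pair-enumeration oracle and an
independent ROC implementation.

One engineering note: the SVM's class probabilities come from a Platt-type
logistic calibration of its decision values fitted on the training rows.
libsvm's built-in probability machinery shuffles data with an unseeded
internal RNG, which would break the package's guarantee that a fixed seed
reproduces identical tuned hyperparameters and predictions; the explicit
calibration is deterministic and equally standard.

All randomness — split, folds, search draws, forest growth — derives from
the single `seed` argument, and training twice with the same seed yields
byte-identical predictions (tested).

## The synthetic tile generator

No public RRF tile dataset exists, so the package ships a generator that
emulates the three classes well enough to exercise every pipeline stage:

* a seeded Voronoi mosaic of ~11 fiber cross-sections in blue-green hues
  (hue ~0.42, saturation ~0.45) with darkened boundaries — the `not_ragged`
  appearance;
* the same mosaic plus a contiguous red annulus (hue ~0.98, saturation
  ~0.75) with salt-noise speckle covering 10–35% of the tile — the `ragged`
  appearance, imitating the granular subsarcolemmal rim;
* a pale, nearly unsaturated field (value ~0.93) with dark elliptical
  artifact blobs — the `waste` appearance.

Additive Gaussian pixel noise (SD 6 on the 0–255 scale) roughens all
classes. A separation scalar `s` linearly interpolates every class
parameter toward the across-class mean: at `s = 0` the three generators are
literally identical (the package tests that tiles of different labels are
byte-identical given the same seed), giving an honest permutation null; at
`s = 1` the classes are cleanly separable. Default class counts are 250
waste / 100 ragged / 138 not-ragged (488 tiles), a composition typical of a
curated tile study in this domain.

What the generator does *not* emulate: stain batch variability, optical
blur and vignetting, partial rims at tile borders, connective-tissue
false-positives that mimic rims, and inter-patient variation. Passing the
pipeline's performance checks on synthetic data therefore demonstrates that
the machinery (features, tuning, selection, gating) works and ranks
separable classes correctly — it does not certify clinical performance on
real slides.

## Problem sizes and numerical choices

The package's own validation uses the full default composition (488 tiles)
with a reduced random-search budget of 10 draws per learner per stage for
the end-to-end performance checks, and smaller sets (~100 tiles, 3 draws,
5 folds) for the reproducibility check; at these sizes a full
simulate–extract–train–evaluate cycle runs in minutes on a single core. At
full separation the selected models at both stages reach test AUC at or
above 0.95; with permuted labels both stages fall back to chance-level AUC
(the band 0.35–0.65 on a ~100-tile test split). Degenerate inputs are
handled with fixed conventions rather than errors wherever a blank tile
could otherwise kill a batch run: constant images quantize to level 1,
GLCM correlation with zero marginal variance is 0, zero-denominator
classification metrics report 0 with a `degenerate` flag, and sub-tile
images yield an empty tile list with a warning.

## Known limitations

* Feature panels follow the standard Haralick/Galloway/Thibault
  definitions; other radiomics dialects differ in a few formulas (e.g.
  homogeneity variants), so absolute feature values are comparable only
  within this package.
* The cascade's 0.5 decision thresholds are fixed, not tuned; threshold
  calibration on a validation split would be a natural extension.
* A tile-level classifier localises RRFs only to grid resolution; no
  segmentation is attempted.
* Probabilities are not calibrated beyond the SVM's logistic link;
  downstream use should rely on ranks (AUC) rather than absolute
  probability values.
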