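---
title: "Choroid texture analysis in OCT B-scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroid texture analysis in OCT B-scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octchoroid)
```

This vignette documents the analysis model implemented by `octchoroid`, the
parameters that matter, the synthetic phantom that stands in for clinical
scans, and the numerical and design choices made where the procedure left
room for interpretation.

## The analysis chain

The subject is a single-channel 8-bit OCT B-scan, nominally 256 x 1024
pixels (rows = depth, columns = lateral position); resolution is
configurable and does not change the analysis. The chain has three parts.

**Preprocessing.** The scan is median filtered with a 3 x 3 mask — sized to
the salt-and-pepper-like acquisition artefacts this layer exhibits — with
edge replication at the borders, so that no artificial dark rim can attract
the subsequent maximum search. The RPE is the brightest band in most
columns, so a per-column brightness argmax locates it; because an 8-bit
column often holds several equal maxima and residual impulse noise, the
robust detector instead collects every row reaching at least `p_r_rpe = 0.9`
of the column maximum and takes the lower median of their indices. A column
whose maximum is zero has no usable cluster and maps to the sentinel row
`M`; such columns are excluded downstream by the validity mask. This
single-cluster assumption is the method's main anatomical premise: when a
column's brightest cluster is not the RPE (rare, but possible in heavily
distorted scans) the contour is wrong there. Everything above the contour
is replaced by the sentinel value -1 — unambiguous against genuine grey
level 0 — and each column is shifted so the RPE sits at row 1, yielding the
flattened choroid image.

**Morphological analysis.** A 30 x 30 windowed mean is subtracted to remove
slowly varying illumination; the window is at least twice the 20 x 20 pixel
maximum object size, so vessel-scale structure survives as signed
residuals. The mean is computed over valid (non-sentinel) pixels only, and
the result is defined on the interior band (a 15-pixel margin on all four
sides) where the window fits. A five-scale filter bank follows: for disc
structuring elements of diameter 3, 5, 7, 9, 11 pixels (discrete discs
`dm^2 + dn^2 <= r^2`, matching the roughly circular vessel cross-sections),
the masked residual image is passed through the neighborhood maximum and
then the neighborhood minimum. On dark objects this max-then-min composite
erases structures smaller than the disc and restores the rest, so the five
outputs encode the object-size distribution. Each is min-max normalized
over the masked region and thresholded at `p_r_bin = 0.5`, keeping the dark
half — the vessels. Finally, three rounds of conditional dilation followed
by conditional erosion clean small artefacts and holes: the neighborhood
max (min) is applied only where the windowed mean of the normalized
filtered image violates a threshold condition scaled by the effectiveness
constants `p_wd` (`p_we`). At `p_we = p_wd = 0` the operators act at
maximal intensity; at `p_we = 1` erosion is provably the identity, which
the test suite asserts.

**Features and classification.** Each refined binary image is decomposed
into 8-connected components; per scale the feature vector records the
object count (`w1`-`w5`), the mean centre of gravity in x and y
(`w6`-`w15`, 1-based pixels, x = column), and the population standard
deviation of per-object mean brightness sampled from the corrected
residual image (`w16`-`w20`). A CART classification tree is grown on these
20 features with Gini impurity and no minimum node size, then pruned by
the one-standard-error rule: stratified 10-fold cross-validation on the
learning split estimates the misclassification cost of every
cost-complexity pruning level, and the smallest tree within one binomial
standard error of the minimum is kept. Evaluation is one-vs-rest per
imaging type (specificity, sensitivity, accuracy). Single-feature ROC
curves (both threshold orientations, better AUC reported) rank individual
features, and a feature-subset search trains a full and a pruned tree for
every subset of a feature pool. The complete 20-feature plan enumerates
`2 * 2^20 = 2,097,152` trees; because enumeration cost doubles per added
feature, desk-scale runs use a pool of about 8 features (512 trees), which
exercises every code path at a few seconds' cost.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `median_mask` | 3 | px | impulse-noise suppression before RPE search |
| `p_r_rpe` | 0.9 | — | bright-cluster membership threshold per column |
| `mean_mask` | 30 | px | illumination-correction window; >= 2 x max object size |
| `p_r_bin` | 0.5 | — | binarization threshold on the normalized residual |
| `scales` | 3,5,7,9,11 | px | disc SE diameters of the filter bank |
| `p_we`, `p_wd` | 0 | — | conditional-operator effectiveness, in [-1, 1] |
| `p_mn` | 0.5 | — | conditional-operator threshold map (constant) |
| `n_rounds` | 3 | — | dilation+erosion repetitions |
| `k_folds` | 10 | — | pruning cross-validation folds |

The two thresholds named alike in the field's notation (`p_r` for the RPE
cluster and for binarization) are deliberately distinct configuration
entries. `p_mn` is constant by default — the usual special case — but a
full per-pixel map is accepted. The effectiveness grid
`effectiveness_grid()` (-1.0 to 1.0 in steps of 0.1) supports parameter
sweeps; the default 0 is the maximal-intensity setting, and the suite
verifies that the erosion branch fires monotonically less often as `p_we`
grows.

## The synthetic phantom

No clinical images ship with the package, so `generate_bscan()` renders
the minimal phantom that exercises every downstream stage with known
ground truth: a moderately reflective retina; a smoothly curved RPE band
(low-order polynomial contour, top-heavy brightness profile so the cluster
detector has a well-defined top edge); a darker choroid carrying dark
elliptical vessel cross-sections (dark because the binarization selects
low intensities; bounding boxes within 20 x 20 px); Gaussian texture
noise; and salt-and-pepper noise applied last as independent per-pixel
replacement by 0 or 255, each at half the configured density — the noise
the median prefilter targets. The three imaging types are encoded exactly
as their qualitative signatures: `Z1` attenuates vertical sub-RPE bands
under simulated retinal lesions, `Z2` multiplies all sub-RPE intensities
by a global dimming factor (default 0.6), `Z3` uses a single vessel
brightness, a narrow placement depth and reduced texture noise. Class
effect sizes are free parameters of the generator; the defaults were
chosen once so that the three class markers (mean sub-RPE brightness for
`Z2`, cross-column brightness variance for `Z1`, vessel-brightness
dispersion for `Z3`) separate by at least three pooled standard
deviations at 50 images per class, which the suite asserts.

The phantom is *not* a physical OCT model: there is no speckle statistics,
no depth-dependent attenuation, no A-scan simulation, no enhanced-depth
mode. Passing tests therefore demonstrate that the implementation computes
the specified quantities correctly and that the chain recovers known
structure — not that the classifier's synthetic accuracies transfer to
clinical scans, where the published accuracies on ~1,000 clinical images
are substantially lower than on phantoms.

## Numerical choices and conventions

* Coordinates are R-native 1-based `(row, column)`; centroids are
  `(x = column, y = row)`. The degenerate-column sentinel is row `M`.
* Argmax ties break towards the smallest row (shallowest tissue); the
  cluster median uses the lower median, so the result is always an
  existing row index.
* All neighborhood operators use a shrinking window: offsets falling
  outside the image are ignored, avoiding padding artefacts next to the
  sentinel-masked region. The median prefilter alone uses edge
  replication, for the reason above.
* The validity-mask polarity marks the *valid choroid* as 1. The
  printed form of the mask definition in the source material marks the
  area above the RPE instead, which would zero out the choroid in the
  filter bank; it is treated as a typo and implemented as the complement.
  Likewise the bright-cluster rule is implemented as `>=` (membership at
  or above the threshold), the only direction that selects the bright RPE
  cluster and is consistent with the stated degenerate-column behaviour.
* The filter-bank composite is implemented exactly as printed — maximum
  first, then minimum — although the surrounding text calls the step an
  "opening"; a `morphology_order = "opening"` switch provides the
  min-then-max alternative. On residual images with dark vessels both
  orders suppress small dark structure similarly.
* The condition means `s_re`/`s_rd` average the filtered image after
  min-max normalization to [0, 1], making them commensurate with the
  left-hand sides `(1 - p_we) * p_mn` in [0, 2] and `p_mn` in [0, 1]; the
  analytic limit regimes (identity at `p_we = 1`, and at `p_wd = 1` with
  `p_mn = 1`) then hold exactly.
* Degenerate normalization (constant masked region) binarizes to all
  zeros with a warning. Scales with zero objects contribute zeros to the
  centroid and dispersion features, keeping the vector complete for the
  classifier; a single object has dispersion 0 (population SD).
* Refinement applies the validity mask after every conditional operation,
  so foreground can never grow into the excluded region.
* The CART engine is rpart (Gini impurity is its classification default),
  driven at `minsplit = 2`, `minbucket = 1`, complexity 0 for unrestricted
  growth; candidate thresholds are midpoints between consecutive distinct
  values. On exact ties in impurity decrease rpart's deterministic internal
  tie-break decides; the suite verifies against an exhaustive search that
  the chosen split always attains the maximal decrease and is identical
  whenever the maximum is unique.
* Pruning cross-validates on the learning split only (stratified, seeded
  fold assignment; folds reduced with a warning if a class is smaller than
  the fold count). The 20% validation split is reserved for model
  selection across subsets and never touches training, pruning or the
  final test evaluation. The standard error of a CV misclassification
  rate `e` over `n` rows is the binomial `sqrt(e(1-e)/n)`.
* The subset search counts `2^k` subsets including the empty one, which
  is realised as a majority-class stump so that the enumeration arithmetic
  (`2 * 2^k` trees with pruned counterparts) holds exactly; `train_cart`
  itself rejects an empty feature mask.
* ROC curves come from pROC with both orientations tried and the better
  AUC kept (the AUC equals the Mann-Whitney U statistic over the product
  of group sizes, which is the oracle the tests use); a constant feature
  yields the degenerate diagonal, AUC 0.5, with a warning.

## Problem sizes

The test suite and the acceptance script run the study conditions at
144 x 512 pixels with 100 images per class and a stratified 60/20/20
learning/validation/test split; unit tests use 96 x 192 phantoms and
8 x 8 random fields for the brute-force oracle comparisons. The generator's
own defaults remain the full 256 x 1024 acquisition geometry. These sizes
are the package's choice of a problem large enough to exercise every
stage densely while keeping a full run in the minutes range on one CPU.

## Known limitations

* Only the RPE contour is segmented; no other retinal layers, and no
  handling of scans where the RPE is not the brightest cluster.
* The morphology API is profiled to disc structuring elements of the five
  standard sizes (arbitrary odd sizes are accepted but not optimized).
* DICOM input is not supported (no DICOM reader among the package's
  dependencies); PNG, TIFF and headerless RAW are.
* Synthetic effect sizes are free parameters; nothing in the package
  calibrates them against clinical data.
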