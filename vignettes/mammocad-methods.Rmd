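---
title: "mammocad: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mammocad: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocad)
```

## The problem

Craniocaudal-view mammograms carry acquisition artefacts (white border
frames, burned-in text and markers, a bright near-vertical line attached to
the breast), poor contrast, and lesions — calcifications or masses, benign
or malignant — whose intensity sits only slightly above the surrounding
dense tissue. mammocad implements a classical computer-aided-diagnosis
pipeline for this setting: clean the image, enhance it, segment the lesion
with a per-image dynamic intensity threshold, describe it with sixteen
geometric/intensity/texture descriptors, and classify the four-class
problem (benign/malignant × calcification/mass, coded BC = 0, BM = 1,
MC = 2, MM = 3) with an accuracy-thresholded stacking ensemble.

Because the package must be testable without clinical images, a seeded
phantom generator renders synthetic mammogram-like scenes with ground-truth
masks. Everything downstream is exercised against those phantoms.

## Pipeline stages and their parameters

### Artefact removal

1. **Border mask** (`applyBorderMask`, width 5 px): zeroes a frame around
   the image, removing white border lines.
2. **Largest-component breast isolation** (`binarize` +
   `largestComponentMask`): the image is binarised (Otsu by default — the
   source method does not state its binarisation rule, and Otsu is robust on
   both real and synthetic images; a fixed threshold is available), the
   connected component of largest area is kept (8-connectivity, since
   contour-based extraction follows diagonal boundaries), and interior holes
   are filled, which reproduces the draw-the-outer-contour-and-fill
   behaviour of contour-based implementations. Area ties break towards the
   component whose top-left-most pixel comes first in row-major order.
3. **Vertical-line removal** (`removeVerticalLines`): Canny edge detection
   (L1 Sobel magnitude, hysteresis 50/150, aperture 3) followed by a
   straight-line voting (Hough) transform restricted to ±10° of vertical,
   vote threshold 50, angular step π/180. Detected segments are overdrawn
   with black at width 5. The coarser angular step π/50 that is sometimes
   quoted for this configuration is almost certainly a typo (it would
   quantise angles to 3.6°); both values are accepted via
   `enhanceParams(thetaStep = )`, with π/180 the default.

### Enhancement

4. **Gamma correction** (`gammaCorrect`): `Vout = gain * Vin^gamma` applied
   on [0, 1]-normalised intensities (the power law is scale-ambiguous on
   8-bit data; normalising first is the standard resolution), defaults
   gamma = 2.0, gain = 1. On the normalised scale gamma > 1 darkens —
   implemented literally even though prose descriptions sometimes claim the
   opposite.
5. **CLAHE** (`clahe`): tile-wise (8 × 8) histogram equalisation with the
   per-bin ceiling `clipLimit × tileArea / 256` (clip limit 1.0), uniform
   redistribution of the clipped excess, and bilinear interpolation between
   the four surrounding tile mappings. Constant images map to constant
   images. Because the clipped mapping lifts level 0 slightly,
   `preprocessImage` re-imposes the pre-CLAHE black support afterwards so
   background and overdrawn lines stay exactly zero.

### Quality verification

`imageMSE`, `imageRMSE`, `imagePSNR` and `imageSSIM` compare the
artefact-removed and the enhanced image. MSE is the plain mean of squared
pixel differences (the printed normaliser is ambiguous between 1/pq and the
m, n indexing; the mean over all pixels is the only reading consistent with
"combined squared error among pixels"). PSNR is `20·log10(MAX/RMSE)` with an
`Inf` sentinel for identical images; the conventional 8-bit acceptance band
is 30–50 dB (`qualityGate`). SSIM uses the standard Gaussian 11 × 11,
σ = 1.5 window with stabilisers `(0.01·MAX)²` and `(0.03·MAX)²`, averaged
over positions where the full window fits — the printed formula in the
source material contains a typographical repetition in the denominator, so
the standard form is implemented.

### Augmentation

`augmentImage` produces the seven fixed geometric variants — horizontal
flip, vertical flip, combined flip, ±30° rotations, each rotation also
horizontally flipped — and `augmentDataset` therefore grows any labelled set
exactly eightfold. Rotations keep the original canvas with black fill and
bilinear interpolation (downstream stages assume fixed geometry and black
background); flips are exact pixel permutations, and the combined flip
equals a 180° rotation bit-exactly (`cospi`/`sinpi` make the multiples of
90° exact). Augmentation runs after preprocessing and before segmentation;
a `pipelineConfig(augmentFirst = FALSE)` ablation segments first and then
augments the ROI images.

### Dynamic-threshold region growing

For each image, `computeDynamicThreshold` records the brightest level, the
near-brightest level (brightest − delta, delta = 10 of 255), and both pixel
counts. The decision rule the source material motivates but never prints is
operationalised as: if at least `minRegion` (default 10) pixels sit at the
exact maximum, grow at the maximum (`MAX_SUFFICIENT`); otherwise relax the
threshold to the near-maximum level (`NEAR_MAX_EXPANDED`) so that
near-brightest lesion pixels are not lost. "Near-brightest" is an intensity
band rather than the second distinct histogram level, which makes the rule
robust to isolated hot pixels. The diagnostics record which branch fired so
alternative rules can be compared.

The seed is the integer-rounded centroid (`floor(x + 0.5)` per coordinate)
of the brightest-pixel set; if a disconnected or concave brightest region
puts the centroid below the threshold, the seed snaps to the nearest
eligible pixel (Euclidean distance, row-major tie-break). `regionGrow` is a
compiled flood fill (default 8-connectivity — lesion boundaries are
irregular and touch diagonally) and only the seed's component is returned:
multi-lesion images are out of scope.

### Descriptors

`computeFeatures` returns, per ROI: area, perimeter/area ratio, convex
area, solidity, circularity `4πA/P²`, equivalent diameter, extent,
filled area, major/minor axis lengths (from second-order central moments),
mean and standard deviation of intensity, Shannon entropy (bits, 256-bin
histogram), GLCM entropy (distance 1, angle 0°, 64 levels, symmetric,
mask-interior pairs only), skewness and non-excess kurtosis (population
moments; a Gaussian sample gives ≈ 3, a constant or single-pixel region is
defined as 0). Two definitional ambiguities in the source table are
resolved towards the standard definitions: equivalent diameter is the
equal-*area* circle `sqrt(4A/π)` (the equal-perimeter variant `P/π` is
available via `equivalentDiameter = "perimeter"`), and extent is area over
the bounding box (the printed area/convex-hull definition would duplicate
solidity and leave only 15 distinct descriptors).

The perimeter is a marching-squares contour length computed on a lightly
Gaussian-smoothed (σ = 0.8) copy of the mask with linearly interpolated
level-0.5 crossings. On raw 0/1 data every crossing sits at an edge
midpoint, the contour hugs the pixel staircase, and a rasterised r = 32
disk comes out ~7% long (circularity 0.88); the smoothed field removes that
staircase bias (circularity 0.98) while the binary-midpoint contour remains
as a fallback for degenerate masks whose smoothed field never crosses the
level.

### Classifier bank, stacking, selection, K-fold

The bank holds the eleven named members (KNN, SVC, DT, RF, MLP, AB, XGB,
GNB, SVM, SGD, LR). This R environment provides no tree, boosting, SVM or
neural-network packages, so the package carries minimal, seeded
implementations: CART kernels in compiled code (Gini classification trees
for DT/RF/AdaBoost, second-order regularised gradient trees for the
XGBoost-style booster), and small vectorised R for KNN, Gaussian naive
Bayes, a one-hidden-layer perceptron (tanh, Adam), mini-batch softmax SGD,
a Pegasos linear SVM and an RBF kernel ridge classifier (least-squares SVM
flavour); multinomial logistic regression delegates to glmnet.
Hyperparameters are documented defaults, overridable via
`modelBankConfig(params = )` — the source reports "hyper-tuned" models
without printing values, so reproducibility is preferred over unpublishable
tuning. Margin-based members report softmax pseudo-probabilities; that is
sufficient for ranking (AUC) and for the meta-learner.

`splitDataset` is a stratified 80:20 split; features are min–max normalised
on the training set only, and held-out rows may leave [0, 1] (not clipped).
`selectByAccuracy` keeps members whose test accuracy *strictly* exceeds the
threshold ("accuracies above X%"), in bank order; the default ensemble
thresholds are 90/93/95 (the body values; an abstract variant 90/95/96
exists in the source and the threshold is a plain argument).
`trainStacked` feeds cross-validated out-of-fold class probabilities
(10-fold by default) into a multinomial logistic meta-learner.

Evaluation: accuracy, the multi-category (covariance-form) Matthews
correlation coefficient — which reduces to the familiar binary formula on
2 × 2 matrices — macro-averaged one-vs-rest F1, and rank-based macro
one-vs-rest AUC. The source prints single numbers for a 4-class problem
without naming the averaging; macro averaging is the conventional choice.

`selectFeatures` implements the five strategies: random-forest impurity
importance with a threshold (the abstract and the results table pair
thresholds 0.045/0.05 with 10/12 features inconsistently, so the threshold
is an input and the resulting count is reported rather than fixed);
univariate ANOVA-F top-k; absolute Pearson correlation of each feature with
the integer class label (the "correlation with what" question is resolved
to feature–label; a feature–feature redundancy filter would be a different
method); PCA components fitted on the training set; and greedy sequential
forward selection that stops when the cross-validated accuracy gain drops
below the threshold.

`kfoldSweep` runs stratified K-fold cross-validation for the twelve default
K values {3, 4, 5, 7, 10, 12, 15, 18, 20, 22, 25, 30} (the source names the
range 3–30 and the count twelve but not the individual values). K may reach
the number of rows (leave-one-out); the implemented validity condition is
that every fold's *training* rows retain all classes, which is what
actually breaks model fitting — a literal "K larger than the smallest class
count" rule would contradict the leave-one-out case.

## The phantom: what it emulates and what it does not

`generatePhantom` renders, deterministically per seed:

- a **breast** as the right half of an ellipse (vertical semi-axis 0.42 ×
  height, horizontal 0.36 × width), its flat chest-wall side 7 px from the
  left image edge. The 7 px inset is deliberate: the method's own border
  mask (width 5) would amputate a literally flush breast and put a ~8%
  ceiling on breast-mask recovery through no fault of the segmentation;
- **dense-tissue texture**: Gaussian-blurred (σ = 2) white noise rescaled
  to σ = 12 intensity units around a base level of 120, clamped strictly
  below the lesion rim — the simplest texture with a controllable dense
  tail;
- a **lesion disk** (default radius 12) whose centre is the breast maximum
  (250) with a quadratic radial drop of 3 levels at the rim. The rim drop
  matters: gamma 2.0 roughly doubles top-range contrast (the slope of the
  power law is `2v/255 ≈ 1.95` near v = 250), so a drop d becomes ≈ 2d
  after enhancement and must stay below the near-max band delta = 10 for
  the lesion to be segmented whole — hence a default safely under delta/2.
  The small exact-maximum set also exercises the `NEAR_MAX_EXPANDED`
  branch, which is the interesting one;
- an optional **dense patch** 14 levels below the lesion peak — "slightly
  below lesion intensity", and just outside the near-max band so
  segmentation must rely on the band edge and on connectivity;
- the three **artefacts**: a 255-level frame (thickness 3, inside the
  border-mask width), 2–4 bright text-like rectangles in the right portion
  of the image, and a 255-level near-vertical line (|slope| ≤ 0.04,
  length ≈ 0.55 × height) touching the breast's right edge.

`generatePhantomDataset` varies lesion radius (class means 7/14/10/18 px
± 2 jitter) and rim drop (2/3/4/5) by class so shape and intensity
descriptors carry class signal. `generateFeatureTable` is the abstract
counterpart: exactly uniform class priors, informative columns as unit
Gaussians whose class means are offset by `classSeparation` standard
deviations in a cyclic one-feature-per-class pattern, and class-independent
noise columns.

What the phantom does **not** emulate: radiologically realistic parenchymal
texture, pectoral muscle, multi-lesion images, spiculated or blurred lesion
margins, DICOM semantics, or the intra-/inter-class visual similarity
structure of real mammograms. A green phantom test therefore establishes
that the pipeline's mechanics are correct — artefacts removed, the stated
threshold rule followed, the grown region equal to the flood-fill ideal,
descriptors matching analytic geometry, the ensemble logic faithful to its
selection rule — not that real-data accuracies are reproduced. The
published real-data headline numbers depend on CBIS-DDSM and are out of
scope here.

## Numerical choices and degenerate inputs

- Otsu on a constant image falls back to the fixed threshold with a
  message; an all-black image fails at breast isolation (documented error).
- `computeDynamicThreshold` rejects all-zero images; a constant image takes
  the `MAX_SUFFICIENT` branch and the ROI is the whole support.
- PSNR of identical images is the `Inf` sentinel, not an error.
- Centroid rounding is `floor(x + 0.5)`, ties in the seed snap break in
  row-major order, and component-area ties keep the row-major-first
  component — all chosen to make results reproducible to the bit.
- Min–max normalisation maps constant columns to 0; correlations involving
  constant columns are 0 with a warning.
- Single-pixel regions define std/skewness/kurtosis as 0; GLCM entropy of a
  region with no interior horizontal pair is 0.
- All RNG flows through `set.seed` on R's generator, including the
  compiled per-node feature subsampling (which draws through R's RNG), so
  identical configs give bit-identical runs.

## Worked example

```{r example, eval = FALSE}
library(mammocad)

truth <- generatePhantom(phantomSpec(seed = 3))
pre <- preprocessImage(phantomImage(truth))
roi <- extractROI(pre)
diagnostics(roi)
sum(roiMask(roi) & lesionMask(truth)) / sum(roiMask(roi) | lesionMask(truth))

tab <- generateFeatureTable(nPerClass = 40, classSeparation = 6, seed = 1)
sp <- splitDataset(tab, seed = 1)
norm <- minmaxNormalize(sp$train)
bank <- trainBank(norm$table, applyNormalization(sp$test, norm$ranges),
                  modelBankConfig(seed = 1))
spec <- selectByAccuracy(bank, 90)
st <- trainStacked(norm$table, applyNormalization(sp$test, norm$ranges),
                   spec, modelBankConfig(seed = 1, cvFolds = 5))
st$metrics
```

## Known limitations

- The line-removal stage targets near-vertical straight segments only;
  curved or short marker lines survive.
- Margin-based learners (SVM, SVC, AdaBoost) emit calibrationless softmax
  pseudo-probabilities; their AUCs are rank-valid but their probability
  values should not be read as calibrated risks.
- The in-package learners are deliberately minimal; they are faithful in
  kind (same loss families and structures as the named algorithms) but are
  not drop-in numerical replicas of any specific library's defaults.
- The segment-then-augment ablation recomputes masks as the non-zero
  support of the augmented ROI image, which slightly thickens rotated masks
  at interpolated borders.
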