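---
title: "Click-guided joint segmentation and classification of hepatic lesions in ultrasound: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Click-guided joint segmentation and classification of hepatic lesions in ultrasound: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Focal hepatic lesions found on B-mode ultrasound — cysts, hemangiomas,
metastases and hepatocellular carcinomas (HCC) — are hard to delineate and
characterize automatically: speckle, low lesion-to-parenchyma contrast and
overlapping sonographic phenotypes defeat fully automatic methods, while
manual ROI drawing is too slow for routine use. `usjoint` implements an
*interactive* middle ground: the user marks the lesion with a few clicks
(or a two-corner bounding box) and a single convolutional network jointly
produces a per-pixel lesion segmentation and a lesion-type classification.
Doing both tasks from one shared encoder lets each task inform the other:
segmentation supplies the region of interest, classification supplies
shape/echogenicity priors.

## User-input encoding

Clicks are 0-based `(row, col)` pixel coordinates with a polarity:
*foreground* (inside the lesion) or *background* (surrounding tissue).
The network never sees raw coordinates; each polarity is rendered as a
**Euclidean distance map** — every pixel holds the minimum distance
between its center and any click of that polarity, truncated at 255 —
and the triplet

\[
(\text{image},\; D_{\text{fg}},\; D_{\text{bg}}) / 255
\]

forms the three-channel input. When no background click is given,
\(D_{\text{bg}}\) is the constant 255 fill, so "no information" is a
well-defined input rather than a missing channel. The truncation at 255
(before the division) mirrors that fill convention and bounds the channel;
distances between pixel centers keep the encoding exact under geometric
augmentation, because maps are recomputed from transformed coordinates
rather than warped as images.

Training inputs are *simulated* users: the foreground click count is
uniform on \(\{1,\dots,5\}\) with clicks uniform without replacement over
lesion pixels; the background count is uniform on \(\{0,\dots,10\}\) with
clicks uniform over the band of background pixels whose distance to the
lesion lies in \([d_{\min}, d_{\max}]\). The band default
\(d_{\min}=5,\ d_{\max}=40\) px is defined at the 256 px reference scale
and kept proportional on smaller canvases (2–10 px at 64 px in
`run_pipeline()`): near enough to inform the boundary, unambiguously
outside the lesion, and at the same relative distance as the corner
clicks of a test-time bounding box — the stated "certain distance range"
is otherwise unquantified, so this is a package choice. Each training image carries 15
pre-generated click sets; we pair one foreground draw with one background
draw per set (pairing, rather than crossing, the foreground and background
sequences — the natural reading of "15 sequences each" that keeps the
input count per image fixed).

Two test modes are supported:

* **one-click** — a single foreground click, background map = 255 fill;
* **two-click** — a simulated bounding box: the lesion's tight box with
  each corner coordinate jittered by \(\pm 10\%\) of the box side,
  enlarged by 10% per side (both amplitudes are package choices for the
  unquantified "positional error" and "enlarged a little"), clamped so it
  always contains the lesion; the box is fed to the network as one
  foreground click at its center and four background clicks at its
  corners.

## Network

Three variants share one construction (all convolutions 3×3, each followed
by batch normalization and ReLU; down-sampling by 2×2 max pooling;
up-sampling by fixed bilinear interpolation, never learned transposed
convolutions):

* `seg_only`: encoder + decoder producing a foreground logit map;
* `cls_only`: a VGG-style stack (two convolutions per stage) over a
  single-channel lesion patch — the patch is centered on the lesion's
  tight box with side twice its larger dimension, edge-replicated at
  borders and resampled to 64 px;
* `joint`: the shared encoder feeds both the decoder and a classification
  branch that pools the deepest shared feature map — concatenated global
  average and global max pooling — into fully connected layers.

The *desk* profile uses 4 stages of widths (16, 32, 64, 128), decoder
widths half the mirrored encoder widths with skip concatenations, and two
hidden FC layers (64, 32) — the classification branch's depth and widths
are unspecified in the source method ("several fully connected layers"),
so two hidden layers is our choice. The desk joint network has ~3×10⁵
parameters (the profile guarantees < 2×10⁶), small enough to train on one
CPU at 64² resolution. Pooling the deepest shared map is our
reading of "from the features of the shared convolutional layers"; the
average term summarizes context and the max term preserves
lesion-localized evidence that a plain mean dilutes on a small deep grid
(a lesion occupies few cells of the 4×4 deepest map). The binary mask is the
probability map thresholded at 0.5 (unstated; the natural choice for a
logistic output). Weights are He-initialized from a seed; the original
system warm-started its early convolutional layers from a network trained
on breast-ultrasound images, which is not reproducible without those
weights — `build_network(..., warm_start = )` accepts a previously trained
phantom network instead.

## Losses and training

Segmentation uses the pixelwise focal loss
\(-\,(1-p_t)^\gamma \log p_t\) averaged over pixels
(\(p_t = p\) on lesion pixels, \(1-p\) off), classification the
α-balanced focal loss \(-\,\alpha_y (1-p_y)^\gamma \log p_y\), and the
joint network their **unweighted sum**. We take \(\gamma = 2\) and
\(\alpha\) = normalized inverse class frequency (the canonical focal-loss
settings; the source cites the focal-loss paper without giving values —
with balanced phantom classes \(\alpha\) is uniform). Probabilities are
clamped at \(\varepsilon = 10^{-7}\) so losses stay finite; gradients are
taken analytically through the clamp and verified against finite
differences in the test suite.

Optimization is SGD with 0.9 momentum and 5×10⁻⁴ weight decay (applied to
convolution/FC weights, not biases or batch-norm parameters). The learning
rate is constant for the first half of the iterations and ten times
smaller for the second half, stepping after iteration
\(\lceil\text{iterations}/2\rceil\). The clinical-scale (*paper* profile)
schedule is 150,000 iterations at 5×10⁻⁴ / 5×10⁻⁵ (40,000 at 10⁻³ / 10⁻⁴
for `cls_only`). The *desk* profile runs 2,000 iterations, batch 8, on 64²
images at rates 10⁻² / 10⁻³: training a batch-normalized network from
scratch in 2,000 iterations needs a larger step than a 150,000-iteration
schedule, and 10⁻² is the standard SGD+BN starting rate at this scale.
Augmentation: horizontal flip (p = 0.5) applied identically to image, mask
and click coordinates; isotropic scaling drawn from (0.8, 1.2) with the
canvas size preserved by center crop/pad (scaling-as-crop/pad keeps the
pixel grid and click semantics; the alternative — resizing the canvas —
would change the meaning of the distance maps); brightness ±20/255 and
contrast gain (0.8, 1.25) on the image channel only. Masks are resampled
nearest-neighbor so they stay binary. All augmentation ranges are package
choices (the source lists the transform types only).

## The phantom generator

No clinical accession exists for the source dataset, so the `phantom`
module synthesizes B-mode-like studies that carry the same statistical
handles: four classes with distinct phenotypes, class-specific size
distributions, speckled background.

* **Size**: longest lesion dimension drawn from a log-normal truncated to
  [4 mm, 80% of the field of view], with (μ, σ) solved numerically so the
  *truncated* mean and SD equal the clinical values — cyst 16.8 ± 14.9,
  hemangioma 17.4 ± 14.5, metastasis 26.2 ± 15.7, HCC 23.3 ± 14.7 mm.
  The clinical SDs describe cohort variation, not a generative law; the
  log-normal is a stand-in with the right support and skew. The 4 mm floor
  avoids sub-resolution lesions.
* **Shape**: an ellipse (axis ratio 0.65–0.95, random orientation) with
  low-frequency radial harmonics; the perturbation amplitude is a class
  parameter, largest for HCC and metastasis (irregular margins), smallest
  for cysts. The analytic boundary is rescaled so its caliper diameter
  equals the drawn size exactly before rasterization.
* **Echogenicity**: cyst — strongly hypoechoic (offset −65), sharp margin
  (blur σ 0.5 px); hemangioma — hyperechoic (+45), well defined (0.7);
  metastasis — hypoechoic (−35), blurred margin (2.5) with a peripheral
  hypoechoic halo; HCC — mildly hypoechoic (−15), blurred (2.0), strong
  internal texture (amplitude 28). Offsets ride on a background parenchyma
  of mean 90 with slow spatial drift.
* **Speckle**: multiplicative noise with Rayleigh-distributed amplitude
  smoothed by a small Gaussian kernel (σ 0.8 px), normalized to unit mean
  and scaled to a 25% coefficient of variation — the canonical
  approximation of fully developed B-mode speckle.

At the desk scale we use 64² images at 1 mm/px so the clinical millimeter
means land at trainable pixel sizes; the package default is 256² at
0.5 mm/px. What the phantoms do **not** model: acoustic physics (no ray
tracing, attenuation, TGC or probe geometry), scan-plane variability,
multiple lesions, or the long tail of atypical clinical presentations.
Passing tests on phantoms therefore demonstrate that the implementation
learns and evaluates correctly — not that clinical performance figures
transfer.

Train/test splitting mirrors the clinical protocol: within each class,
records are ranked by lesion area, cut into up-to-ten groups, and the test
quota is sampled evenly across the groups, so the test set spans the size
range.

## Evaluation protocol

Five simulated user inputs per test image (seeds 0–4 offset by the image
index), each scored separately: the per-image Jaccard index
\(|A\cap B| / |A\cup B|\) against the reference mask, and the predicted
class by probability argmax. Classification is summarized by the confusion
matrix over all (image, input) pairs, per-class accuracy
(diagonal / row sum) and overall accuracy (trace / total); the
benign/malignant ROC scores each prediction by
\(P(\text{metastasis}) + P(\text{HCC})\) when the model is four-class
(separately trained binary models are also supported); AUROC is the
trapezoid area, which equals the tie-corrected rank statistic
\(U/(n_+ n_-)\); the operating point maximizes Youden's
\(J = \text{sens} + \text{spec} - 1\), ties broken toward sensitivity
(the tie rule is unspecified in the source; sensitivity is the
screening-relevant direction). One-vs-rest curves and their unweighted
mean give the four-class macro AUROC. AUROC confidence intervals are
percentile bootstrap over 2,000 case resamples (the source's CI method is
unnamed). System comparisons use a two-sided paired sign-flip permutation
test on the mean difference — exact by enumeration up to 14 pairs, Monte
Carlo beyond (the source reports p-values without naming a test).

## Numerical and degenerate-input conventions

* Coordinates 0-based `(row, col)`; distances between pixel centers;
  boxes inclusive of both corners. Stated once, used everywhere.
* Jaccard of two empty masks is 1 (unreachable when a reference lesion
  exists, but defined).
* An empty click list encodes to the 255 fill; an empty background band
  (lesion fills the image) yields zero background clicks with a warning.
* Requested click counts are capped at the number of available pixels.
* A lesion whose drawn size cannot fit the canvas is an error, not a
  silent clamp.
* Augmented samples whose lesion leaves the canvas fall back to the
  untransformed record.
* Training aborts with a diagnostic on non-finite loss.
* Batch-norm inference uses running statistics (momentum 0.9), making
  `predict()` deterministic; training-mode determinism is exact for a
  fixed seed because every stochastic step is seeded and the kernels are
  single-threaded C++ over doubles.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run the desk study: 50 phantoms
per class (160 training / 40 test after the stratified 20% split), 64²
pixels, 2,000 iterations at batch 8, five user inputs per test image.
These sizes were chosen so a complete study runs in minutes on one CPU
core while leaving every pipeline stage — simulation, click encoding,
joint training, two evaluation modes — exercised at full fidelity.
Sanity checks at reduced size (8-record overfit runs, 2-stage networks
for finite-difference gradient verification) are likewise generated in
code.

## Known limitations

* The phantom's speckle is an image-domain approximation; real B-mode
  texture is depth- and TGC-dependent and correlated with anatomy.
* Desk-scale training from random initialization on phantoms says nothing
  quantitative about clinical JI/accuracy/AUROC values, which depend on a
  private clinical dataset and 150,000-iteration training; headline
  clinical figures are deliberately out of scope here.
* The hand-written network supports the shapes this package needs
  (square inputs divisible by \(2^{\text{depth}}\)); it is not a general
  deep-learning framework.
* `cls_only` evaluation uses ideal lesion-centered patches (as in the
  source protocol); a deployed cascade would crop patches from a
  segmentation result instead.
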