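---
title: "Methods: bag-of-words behavior recognition for deformable animals"
author: "hydrabow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bag-of-words behavior recognition for deformable animals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

*Hydra* is a freshwater polyp with an extremely deformable body: it
contracts into a ball, elongates into a thin column, bends, and sways, and
different individuals carry different numbers of tentacles. Template- or
eigenpose-based behavior trackers, which work well for worms, flies and
mice, fail on such a body plan. `hydrabow` instead treats each short video
window as a *bag of visual words*: local motion and shape statistics are
collected without committing to any explicit body model, and behaviors are
recognized from the distribution of those statistics. Supervised
classifiers recognize pre-defined behaviors; an unsupervised embedding of
the same representation discovers behavioral motifs that were never
annotated, such as egestion.

# Pipeline

## Behavior elements

The unit of analysis is a 5 s window ("behavior element") at 5 Hz — 25
frames. Most *Hydra* behaviors last under 10 s and 5 s windows rarely mix
behavior types, which motivates this choice; the length is a configuration
parameter (`window_s`), not a constant. Per-frame manual labels are
aggregated to a window label by a prominence-weighted rule: with the two
most frequent labels L1 and L2, the window takes L2 when L2 is the more
prominent behavior and L1's count is at most three times L2's. A brief
whole-body contraction inside a mostly quiet window therefore labels the
window as contraction — large-amplitude behaviors are short, and a plain
majority vote would erase them.

## Registration

Each frame is segmented by background subtraction (the background is a
grayscale opening with a disc larger than the animal, computed at reduced
scale and clipped under the frame so anti-extensivity holds exactly),
contrast stretching, and 3-way 1-D k-means on intensity — bright body,
weak tentacles, dark background; the largest cluster is background.
Components below 0.25% of the image area are discarded and the mask is
dilated by 3 px. The bright body column is isolated with two Otsu passes
(the second threshold computed within the first's above-threshold region)
and fitted with an ellipse by second-order moments. The moments are
weighted by the smoothed intensity over the slightly dilated body-column
region rather than computed on the bare binary mask: the second Otsu
threshold sits between tentacle and body intensity and cuts the smoothed
boundary ramp inside the true edge, biasing binary-mask axes 1-2 px
short, whereas the symmetric intensity ramp centers the weighted fit on
the true boundary (residual error under 0.5 px on noise-free fixtures); head polarity is the
major-axis end with the larger area of animal-minus-body-column under a
square probe. The probe side is 3x the minor axis (a free parameter of
the method: one minor axis proved too small to cover fanned tentacles,
and the value is exposed as `probeScale`). The
animal is split into tentacle / upper / lower body parts at the probe and
the ellipse minor axis.

Every window is then mapped by a single similarity transform — built from
the window-average centroid, head direction and major-axis length — to a
300 x 300 canvas with the body vertical, head up, and body length 100 px
(bilinear interpolation; pixels outside the animal mask zeroed). Averaging
the transform over the window keeps within-window motion intact;
registering per frame would cancel the very motion being measured. The
"body length" used for scaling is the ellipse major axis; the alternative
(head-to-foot extent including tentacles) varies with tentacle posture and
was rejected.

## Dense-trajectory features

Interest points are seeded every 5 px inside the animal at the start of
each 15-frame tracking batch, gated by a corner-response quality threshold
(0.01 of the frame maximum), and advected along a dense Lucas-Kanade
optical flow (box integration window, two warp-refinement iterations, 3x3
median filtering of the field). Tracks whose positional standard deviation
falls below 0.1 px (static) or above 50 px (erratic), or with any
frame-to-frame displacement above 50 px, are pruned. Around each tracked
point a 32 px neighborhood contributes to four single-cell histograms
accumulated over the whole spatio-temporal patch and l2-normalized:

* **HOG** — unsigned image-gradient orientations, 8 bins, magnitude
  weighted (shape);
* **HOF** — signed flow orientations, 8 bins plus a zero bin counting
  pixels with flow below 0.4 px/frame (motion);
* **MBHx / MBHy** — signed orientations of the spatial gradient of each
  flow component, 8 bins each; gradient magnitudes below 0.05 are
  discarded, so uniform translation yields an all-zero histogram
  (motion boundaries).

Single-cell histograms (9/8/8/8 dimensions), rather than the 2x2x3 cell
grids of the original dense-trajectory method, keep the descriptor
dimensionality deliberately small. The HOF zero-bin threshold and MBH
floor are configurable; their defaults are common practice, not derived
quantities. Trajectories are grouped by the body part containing their
mean position (nearest part for points on zeroed background), which is how
spatial structure enters an otherwise orderless representation.

## Fisher-vector encoding

Per descriptor type, training descriptors are centered per body part,
reduced by a shared PCA to half their dimension (ceiling: 9-bin HOF keeps
5), and whitened by the eigenvalue square roots. A diagonal-covariance
Gaussian mixture (K = 128 by default; 256 supported) is fitted by EM on a
seeded subset of at most 256,000 points, initialized by k-means, with
responsibilities computed in log space and variances floored at 1e-4. Each
window and body part is then encoded by the Fisher vector — the
mean- and variance-gradients of the GMM log-likelihood with the
closed-form diagonal Fisher-information normalization; weight gradients
are omitted, as in the improved-Fisher-vector practice this encoding
follows. Components receiving negligible responsibility contribute zero
blocks. Each (part, type) block is power-normalized (sign(z)|z|^0.5) and
l2-normalized, blocks are concatenated in the fixed order (tentacle,
upper, lower) x (HOF, HOG, MBHx, MBHy), and the concatenation is
l2-normalized once more so every window has unit norm (or is exactly zero,
for a window with no surviving trajectories).

## Classification

Fisher vectors are PCA-reduced keeping 90% of training variance, and an
RBF-kernel SVM (libSVM via e1071) is trained with class weights
w_i = N/N_i and a 5-fold cross-validated grid search over
log2(cost), log2(gamma) in {-5, -3, ..., 15}; ties take the first grid
point, and the final model is refitted on all data with pairwise-coupled
probability estimates. When an animal id is supplied per window, the
cross-validation folds keep whole animals together. This matters:
consecutive windows of one clip are near-duplicates, and random folds
that split them make every grid point look perfect, so the search
degenerates to its first entry and the selected model fails on unseen
animals. Grouped folds measure exactly the generalization the held-out
evaluation asks for. The cross-validated accuracy is also scored the way
the model is deployed — by the argmax of the calibrated class
probabilities, not by raw decision values: a weakly-regularized grid
point can separate the folds by decision sign while its probability
calibration collapses, and a selection blind to probabilities would pick
it. Hard prediction is the probability argmax (ties
broken toward the more prominent behavior); soft prediction admits a
second label when its probability exceeds half the first's and a third
exceeding half the second's (strict inequalities), capturing overlapping
behaviors. Evaluation is one-vs-rest: accuracy (TP+TN)/total, precision
TP/(TP+FP), recall TP/(TP+FN), and a trapezoid AUC over the ROC; a soft
prediction is credited when the truth appears anywhere in its label set.
Ethograms are summarized as the fraction of windows per behavior and the
standard deviation of that fraction across 30 min blocks.

## Motif discovery

The same reduced vectors are embedded in 2-D by exact t-SNE (Euclidean
distances, perplexity 16, early exaggeration, deterministic PCA
initialization plus a seeded sub-pixel jitter, and the auto learning
rate max(n/(4 x exaggeration), 50) — a fixed large step is unstable for
the small n this package embeds and can collapse the map). t-SNE is implemented in
the package: the out-of-sample machinery below needs the same
perplexity-calibration and Q-kernel internals, and the exact O(n^2)
gradient is inexpensive at the problem sizes this package targets. A
Gaussian kernel density (sigma = 1/40 of the maximum absolute embedding
coordinate; 1/60 suits long recordings) is computed on a 501 x 501 grid
with 10% padding — "maximum value in the embedding space" is read as the
maximum absolute coordinate, and both the fraction and the reading are
configurable. Local density maxima above 1% of the peak are dilated by
3 px (merging near-duplicates) and seed a watershed on the inverted
distance transform; every grid cell drains to its nearest peak group, and
cells below the support threshold stay unassigned (points there take the
nearest labeled cell). Regions are annotated with the majority manual
label (ties toward prominence; empty regions are "none"). New windows are
embedded against the frozen map by minimizing their KL mismatch to the
training embedding per point (Nelder-Mead from the probability-weighted
mean of the training coordinates), then looked up in the segmentation.

## Egestion detection

Egestion — a sub-second radial contraction expelling cavity fluid — is
detected from the body-width (minor axis) trace: the filter value at t is
the mean width over 15 min before t minus the mean over 15 min after t,
so a sharp drop gives a positive peak exactly at the drop. Peaks with
topographic prominence at least 50x the MAD of the filtered trace are
events; the default multiplier is deliberately far above 3 because the
filtered trace is smooth at the half-window scale, making chance
peak-to-trough excursions an order of magnitude larger than the
per-sample MAD, while genuine events sit another order above (their peak
height is of the order of the width drop itself). At the trace ends the
truncated windows average fewer samples; the local threshold is inflated
by sqrt(h/windowLength) so edge noise does not fire, while genuine early
or late events — flagged `edge_flag` — remain detectable. Events closer
than one half-window keep only the higher peak.

# The synthetic data generator

Real *Hydra* videos are large and not shipped; the package generates its
own study material with known ground truth. A clip renders a bright solid
ellipse (intensity 0.85) with 3-px curved tentacle strokes at 0.45 on a
0.03 background plus Gaussian pixel noise (SD 0.02) — three intensity
populations, so the 3-way clustering in segmentation is genuinely
exercised. Kinematics per behavior: silent (static), elongation (major
axis grows 35% over the clip, minor shrinking to conserve area),
contraction (45% major-axis drop within 1.5 s, then oscillation in the
contracted state, tentacles shortened), tentacle sway (only tentacle
angles oscillate, 0.25-0.5 Hz, 12-25 degrees), body sway (rigid 8-degree
rotation about the foot at 0.3 Hz), bending (a quadratic midline offset
growing to 0.9 of the half-width), and egestion (a 35% minor-axis drop
within 0.8 s recovering over seconds). Ground truth per frame is the
moment ellipse of the true body mask plus head polarity. Morphology
(length, tentacle count/length/curvature, pose, phases) is drawn from the
seed, so animals differ; identical specs are bit-identical.

The generator emulates the statistical structure the pipeline assumes —
intensity contrast, part-specific motion, deformability — but not
photometric realism: no shading, no depth, no prey, no occlusion, no
camera drift. Passing tests therefore demonstrate the pipeline's
correctness and its sensitivity to the motion structure that defines these
behaviors, not field performance on real microscopy video.

The width-trace generator drops the baseline width by `drop_frac` at each
event and recovers linearly over 30 min by default — the cavity refills
slowly, which is exactly what makes the before-minus-after filter peak
sharply at the drop. (An early draft recovered in a minute; the filter
response then spread over the whole half-window and the detector could
not localize events. The slow-recovery sawtooth is also what the real
width traces look like.)

# Desk-scale study conditions

The self-contained experiment (`runSyntheticPipeline()`, the acceptance
script, and the heavier tests) uses: 7 animals (5 train, 2 held out) x 6
basic behaviors x 20 s clips (4 windows each; 120 train and 48 test
windows) rendered at 224 x 224 px, noise SD 0.02, 5 tentacles; codebooks
with K = 32 on at most 20,000 descriptors per type with up to 60 EM
iterations; the full SVM grid; perplexity 16 and sigma 1/40 for the motif
map. K = 32 (not the production default of 128) matches the few-10^4
descriptor volume of this dataset; all other analysis constants are the
defaults above. The egestion benchmark uses a 24 h width trace with five
events and noise at 5% of baseline.

# Numerical choices and degenerate inputs

* Segmentation k-means runs on a 256-bin intensity histogram with
  quantile-initialized centers — deterministic, and empty clusters keep
  their previous center.
* A frame whose segmentation or fit fails inherits the previous frame's
  geometry and is flagged; windows therefore stay contiguous.
* EM variances are floored at 1e-4; components with responsibility below
  1e-10 contribute zero Fisher blocks; responsibilities are computed in
  log space throughout.
* PCA eigenvalues are floored at 1e-12 before whitening.
* All-zero patches give all-zero histograms; all-zero Fisher vectors stay
  all-zero through every normalization.
* Argmax and majority ties break toward the more prominent behavior;
  grid-search ties take the first grid point. Both rules are documented
  determinism guarantees, not statistical claims.
* Every stochastic step (generator, EM subset and init, CV folds, t-SNE
  jitter) takes an explicit integer seed; identical seeds give identical
  results, including across sessions.

# Known limitations

* The representation discards temporal order beyond the window length: no
  transition probabilities, no temporal smoothing of ethograms. This is a
  property of the bag-of-words design, not an implementation gap.
* Single-animal scenes only; no bud detection, no 3-D pose, no
  multi-animal tracking.
* AVI input is not supported (no codec stack is assumed); multi-page TIFF
  is the lossless interchange format.
* The Lucas-Kanade flow assumes smooth, moderate motion (a few px/frame
  at the canonical scale). The trajectory filters prune the failures, but
  very fast whole-body motions are represented mainly by their
  large-displacement statistics rather than accurate flow fields.
* Fine behaviors of single tentacles, or behaviors distinguished only by
  features smaller than the 32 px patch at canonical scale, are below the
  representation's resolution.
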