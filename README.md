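# hydrabow

Automatic recognition and unsupervised discovery of behaviors in videos
of *Hydra*, a freshwater polyp whose body contracts, bends and elongates
so freely that template- and eigenpose-based trackers do not apply.
`hydrabow` is aimed at quantitative ethologists and neuroscientists who
need per-window behavior labels (ethograms), behavior time budgets, and
discovery of unannotated behaviors from widefield microscopy video of a
single bright animal on a dark background.

## The method

Each 5 s window of video (25 frames at 5 Hz) is treated as a *bag of
visual words*:

1. **Registration.** The animal is segmented (background opening,
   3-cluster intensity k-means, area filtering), its bright body column
   is isolated by a two-pass Otsu threshold and fitted with an ellipse
   by image moments, head polarity is resolved from the tentacle area at
   the major-axis ends, and the animal is split into tentacle / upper /
   lower body parts. One similarity transform per window maps the body
   to a canonical 300 x 300 frame (vertical axis, head up, body length
   100 px).
2. **Dense trajectories.** Interest points seeded every 5 px are tracked
   for 15 frames along a median-filtered dense optical flow; static and
   erratic tracks are pruned. Each track carries four single-cell
   histograms over its 32 px neighborhood: HOG (8 orientation bins), HOF
   (8 + a zero-motion bin), and MBHx/MBHy (8 bins each).
3. **Fisher vectors.** Per descriptor type, part-centered descriptors
   are PCA-halved and whitened, and a K-component diagonal Gaussian
   mixture (K = 128 by default) is the codebook. A window is encoded by
   the normalized mean- and variance-gradients of the GMM
   log-likelihood,

   G_mu(i,d)    = 1/(T sqrt(w_i))   sum_t gamma_t(i) (x_td - mu_id) / sigma_id
   G_sigma(i,d) = 1/(T sqrt(2 w_i)) sum_t gamma_t(i) [((x_td - mu_id)/sigma_id)^2 - 1],

   power-normalized (sign(z) |z|^0.5), l2-normalized, and concatenated
   over 3 body parts x 4 descriptor types.
4. **Recognition.** A class-weighted RBF SVM (w_i = N/N_i, 5-fold
   cross-validated grid over log2 c, log2 g in -5..15) predicts one hard
   label per window, or up to three "soft" labels when runner-up
   probabilities exceed half the previous one.
5. **Discovery.** The same vectors are embedded by exact t-SNE
   (perplexity 16), a Gaussian kernel density (sigma = 1/40 of the
   maximum embedding coordinate) is segmented by watershed into motif
   regions, regions take their majority manual label, and new windows
   are placed into the frozen map by per-point KL minimization.
6. **Egestion.** Rapid radial contractions are detected from the
   body-width trace with a before-minus-after 15 min mean filter and
   prominence-based peak detection.

A synthetic-video module (`makeBehaviorClip`, `makeWidthTrace`) renders
a deformable ellipse-plus-tentacles animal executing parameterized
behaviors with exact ground truth, so the whole pipeline is testable
without the (large) original recordings.

## A worked example

```r
library(hydrabow)

spec <- syntheticSpec("contraction", duration_s = 5, image_size = 224,
                      seed = 7)
sim <- makeBehaviorClip(spec)
sim$clip
#> VideoClip: 25 frames of 224 x 224 px at 5 Hz (5.0 s)

an <- analyzeClip(sim$clip)
round(head(an$geometry[, 1:6], 3), 1)
#>   frame    cx    cy major minor angle_deg
#> 1     1 120.6 110.0 120.4  33.8      41.6
#> 2     2 120.7 110.1 113.0  34.9      41.6
#> 3     3 120.6 110.0 106.0  36.0      41.7

rw <- registerWindow(sim$clip, an, 1)
rw
#> RegisteredWindow 1: 25 canonical frames (300 x 300 px)
#>   scale 1.323, rotation 228.4 deg

extractWindowFeatures(rw)
#> TrajectorySet: 365 trajectories of 15 frames
#> tentacle    upper    lower
#>      287       32       46
```

The geometry table shows the fitted body ellipse per frame — here the
major axis shrinks from 120 px toward ~106 px within three frames, the
contraction the clip was asked to perform. After registration the body
is vertical at 100 px, and the window yields 365 surviving dense
trajectories, most of them on the strongly moving tentacles.

The full supervised analysis is one call per stage:

```r
cfg <- pipelineConfig()
res <- runSyntheticPipeline(cfg, K = 32)      # simulate..encode (minutes)
model <- trainBehaviorClassifier(res$train, seed = cfg$seed,
          groups = res$info$animal[res$info$set == "train"])
eth <- predictHard(model, res$test)
evaluateClassification(eth, windowInfo(res$test)$label)$overallAccuracy
```

A staged, artifact-on-disk variant of the same pipeline is available
through `runStage()` (stages `simulate`, `preprocess`, `features`,
`fit-codebook`, `encode`, `train`, `predict`, `evaluate`, `embed`,
`egestion`) and the thin CLI wrapper `inst/scripts/hydrabow`.

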