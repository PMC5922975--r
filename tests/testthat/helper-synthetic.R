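# Shared fixtures, built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# A small noise-free clip with masks, plus its analysis.
smallClip <- function() cached("smallClip", {
  res <- makeBehaviorClip(syntheticSpec("silent", duration_s = 5,
                                        image_size = 224, noise_sd = 0,
                                        seed = 11), masks = TRUE)
  res$analysis <- analyzeClip(res$clip)
  res
})

# A moving (body-sway) clip with noise, analysis and one registered window.
swayWindow <- function() cached("swayWindow", {
  res <- makeBehaviorClip(syntheticSpec("body_sway", duration_s = 5,
                                        image_size = 224, seed = 5))
  an <- analyzeClip(res$clip)
  rw <- registerWindow(res$clip, an, 1L)
  list(res = res, analysis = an, rw = rw,
       ts = extractWindowFeatures(rw))
})

# The full synthetic experiment at desk scale: encoded train/test windows,
# trained classifier and predictions. Built once; used by the acceptance
# suite.
syntheticExperiment <- function() cached("syntheticExperiment", {
  cfg <- pipelineConfig()
  res <- runSyntheticPipeline(cfg, K = 32L, verbose = FALSE)
  model <- trainBehaviorClassifier(res$train, seed = cfg$seed,
                                   groups = res$info$animal[
                                     res$info$set == "train"])
  list(cfg = cfg, res = res, model = model,
       ethHard = predictHard(model, res$test),
       ethSoft = predictSoft(model, res$test),
       truth = windowInfo(res$test)$label)
})

ellipseFromGeometry <- function(g, i) {
  el <- as.list(g[i, ])
  names(el)[names(el) == "angle_deg"] <- "angle"
  el
}
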