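# End-to-end orchestration: configuration, staged artifacts and manifest.

#' Default pipeline configuration
#'
#' All analysis defaults in one list: 5 s behavior elements at 5 Hz,
#' codebook size K = 128 with PCA halving of descriptor dimensions, power
#' normalization alpha = 0.5, t-SNE perplexity 16 with density kernel
#' 1/40, and the SVM grid log2(c), log2(g) in -5, -3, ..., 15. The
#' \code{data} block parameterizes the synthetic dataset used by the
#' \code{simulate} stage.
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    window_s = 5, frame_rate_hz = 5,
    out_size = 300L, body_length_canon = 100,
    K = 128L, pca_half = TRUE, n_subset = 256000L,
    alpha = 0.5, perplexity = 16, sigma_frac = 1 / 40,
    grid_n = 501L, peak_thresh_frac = 0.01,
    cv_folds = 5L, log2c = seq(-5, 15, 2), log2g = seq(-5, 15, 2),
    pca_var = 0.9,
    track_len = 15L, spacing = 5L, quality_frac = 0.01,
    min_var = 0.1, max_var = 50, max_disp = 50,
    hof_zero_thresh = 0.4,
    bg_radius = 60,
    egestion_half_window_min = 15,
    classes = c("silent", "elongation", "tentacle_sway", "body_sway",
                "bending", "contraction"),
    seed = 1L,
    data = list(n_train_animals = 5L, n_test_animals = 2L,
                clip_seconds = 20, image_size = 224L, noise_sd = 0.02,
                n_tentacles = 5L)
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#' @param path file path
#' @param cfg a \code{PipelineConfig}
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

.md5string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

.configHash <- function(cfg)
  .md5string(yaml::as.yaml(unclass(cfg)))

.updateManifest <- function(dir, stage, cfg, outputs) {
  mf <- file.path(dir, "manifest.json")
  man <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  files <- unlist(lapply(outputs, function(o)
    if (dir.exists(o)) list.files(o, full.names = TRUE) else o))
  files <- files[file.exists(files) & !dir.exists(files)]
  man[[stage]] <- list(config_hash = .configHash(cfg),
                       package_version =
                         as.character(utils::packageVersion("hydrabow")),
                       outputs = as.list(unname(tools::md5sum(files))))
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

.needs <- function(dir, path, stage) {
  p <- file.path(dir, path)
  if (!file.exists(p))
    stop("missing artifact '", path, "': run stage '", stage, "' first",
         call. = FALSE)
  p
}

.clipSeed <- function(cfg, animal, code) cfg$seed * 1000L + animal * 20L + code

#' Run the full pipeline on an in-memory synthetic dataset
#'
#' Generates the synthetic behavior dataset described by
#' \code{cfg$data} (train and held-out test animals, one clip per basic
#' behavior each), preprocesses and registers every window, extracts
#' dense-trajectory features, fits the Gaussian-mixture codebooks on the
#' training animals only, and encodes all windows as Fisher vectors.
#' This is the front half of the analysis; pass the result to
#' \code{\link{trainBehaviorClassifier}} / \code{\link{predictHard}} or
#' \code{\link{buildMotifMap}} / \code{\link{embedNew}}.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param K codebook size for this run (defaults to \code{cfg$K}).
#' @param verbose log per-stage progress and counts.
#' @return list with \code{train}, \code{test}
#'   (\code{\link{FisherWindows-class}}; labels are the aggregated
#'   ground-truth window labels), \code{info} (per-window clip/animal/
#'   behavior table), \code{codebooks}, and \code{geometry} (per-clip
#'   geometry tables with recovery errors against ground truth).
#' @export
runSyntheticPipeline <- function(cfg = pipelineConfig(), K = cfg$K,
                                 verbose = TRUE) {
  wf <- as.integer(round(cfg$window_s * cfg$frame_rate_hz))
  nTr <- cfg$data$n_train_animals; nTe <- cfg$data$n_test_animals
  say <- function(...) if (verbose) message(sprintf(...))
  feats <- list(train = list(), test = list())
  labs <- list(train = integer(0), test = integer(0))
  info <- NULL
  geometry <- list()
  for (a in seq_len(nTr + nTe)) {
    set <- if (a <= nTr) "train" else "test"
    for (b in cfg$classes) {
      code <- behaviorCode(b)
      sp <- syntheticSpec(b, duration_s = cfg$data$clip_seconds,
                          frame_rate_hz = cfg$frame_rate_hz,
                          image_size = cfg$data$image_size,
                          n_tentacles = cfg$data$n_tentacles,
                          noise_sd = cfg$data$noise_sd,
                          seed = .clipSeed(cfg, a, code))
      res <- makeBehaviorClip(sp)
      an <- analyzeClip(res$clip, bgRadius = cfg$bg_radius)
      nm <- sprintf("a%02d_%s", a, b)
      g <- an$geometry
      tr <- res$truth$ellipse_track
      g$err_major <- abs(g$major - tr$major)
      g$err_minor <- abs(g$minor - tr$minor)
      g$err_angle <- abs(wrapOrientation(g$angle_deg - tr$angle_deg))
      geometry[[nm]] <- g
      nW <- countWindows(res$clip, wf)
      for (w in seq_len(nW)) {
        rw <- registerWindow(res$clip, an, w, windowFrames = wf,
                             outSize = cfg$out_size,
                             bodyLength = cfg$body_length_canon)
        ts <- extractWindowFeatures(rw, trackLen = cfg$track_len,
                                    spacing = cfg$spacing,
                                    qualityFrac = cfg$quality_frac,
                                    minVar = cfg$min_var,
                                    maxVar = cfg$max_var,
                                    maxDisp = cfg$max_disp,
                                    hofZeroThresh = cfg$hof_zero_thresh)
        feats[[set]] <- c(feats[[set]], ts)
        labs[[set]] <- c(labs[[set]], code)
        info <- rbind(info, data.frame(set = set, animal = a, behavior = b,
                                       code = code, clip = nm, window = w,
                                       nTraj = length(ts)))
      }
      say("[%s] animal %d %s: %d windows, %d trajectories", set, a, b, nW,
          sum(info$nTraj[info$clip == nm]))
    }
  }
  say("fitting codebooks (K = %d) on %d training windows", K,
      length(feats$train))
  cb <- fitCodebooks(feats$train, K = K, nSubset = cfg$n_subset,
                     seed = cfg$seed)
  say("encoding %d + %d windows", length(feats$train), length(feats$test))
  out <- list(
    train = encodeWindows(feats$train, cb, labels = labs$train,
                          frameRate = cfg$frame_rate_hz, windowFrames = wf,
                          alpha = cfg$alpha),
    test = encodeWindows(feats$test, cb, labels = labs$test,
                         frameRate = cfg$frame_rate_hz, windowFrames = wf,
                         alpha = cfg$alpha),
    info = info, codebooks = cb, geometry = geometry)
  out
}

#' Run one pipeline stage
#'
#' Stages read the previous stage's artifacts from \code{dir} and write
#' their own, recording config and output hashes in
#' \code{manifest.json}. Stages: \code{simulate} (synthetic dataset),
#' \code{preprocess} (geometry + registered windows), \code{features}
#' (dense-trajectory descriptors + window labels), \code{fit-codebook},
#' \code{encode}, \code{train}, \code{predict}, \code{evaluate},
#' \code{embed} and \code{egestion}.
#'
#' @param stage stage name.
#' @param dir working directory for artifacts.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return invisibly, the paths of the stage outputs.
#' @export
runStage <- function(stage, dir, cfg = pipelineConfig()) {
  stage <- match.arg(stage, c("simulate", "preprocess", "features",
                              "fit-codebook", "encode", "train", "predict",
                              "evaluate", "embed", "egestion"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wf <- as.integer(round(cfg$window_s * cfg$frame_rate_hz))
  out <- switch(stage,
    "simulate" = {
      vdir <- file.path(dir, "videos")
      dir.create(vdir, showWarnings = FALSE)
      nTr <- cfg$data$n_train_animals; nTe <- cfg$data$n_test_animals
      idx <- NULL
      for (a in seq_len(nTr + nTe)) {
        for (b in cfg$classes) {
          code <- behaviorCode(b)
          sp <- syntheticSpec(b, duration_s = cfg$data$clip_seconds,
                              frame_rate_hz = cfg$frame_rate_hz,
                              image_size = cfg$data$image_size,
                              n_tentacles = cfg$data$n_tentacles,
                              noise_sd = cfg$data$noise_sd,
                              seed = .clipSeed(cfg, a, code))
          res <- makeBehaviorClip(sp)
          base <- sprintf("a%02d_%s", a, b)
          writeVideo(res$clip, file.path(vdir, paste0(base, ".tif")))
          writeLabels(rep(code, nFrames(res$clip)),
                      file.path(vdir, paste0(base, "_labels.csv")))
          writeGroundTruth(res$truth,
                           file.path(vdir, paste0(base, "_truth.json")))
          idx <- rbind(idx, data.frame(clip = base,
            set = if (a <= nTr) "train" else "test", animal = a,
            behavior = b, code = code))
        }
      }
      write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
      file.path(dir, "index.csv")
    },
    "preprocess" = {
      idxFile <- .needs(dir, "index.csv", "simulate")
      idx <- read.csv(idxFile)
      gdir <- file.path(dir, "geometry"); rdir <- file.path(dir, "registered")
      dir.create(gdir, showWarnings = FALSE)
      dir.create(rdir, showWarnings = FALSE)
      for (i in seq_len(nrow(idx))) {
        clip <- readVideo(file.path(dir, "videos",
                                    paste0(idx$clip[i], ".tif")),
                          frameRate = cfg$frame_rate_hz)
        an <- analyzeClip(clip, bgRadius = cfg$bg_radius)
        write.csv(an$geometry,
                  file.path(gdir, paste0(idx$clip[i], ".csv")),
                  row.names = FALSE)
        wins <- lapply(seq_len(countWindows(clip, wf)), function(w)
          registerWindow(clip, an, w, windowFrames = wf,
                         outSize = cfg$out_size,
                         bodyLength = cfg$body_length_canon))
        saveRDS(wins, file.path(rdir, paste0(idx$clip[i], ".rds")))
      }
      c(gdir, rdir)
    },
    "features" = {
      idx <- read.csv(.needs(dir, "index.csv", "simulate"))
      fdir <- file.path(dir, "features")
      dir.create(fdir, showWarnings = FALSE)
      for (i in seq_len(nrow(idx))) {
        wins <- readRDS(.needs(dir, file.path("registered",
          paste0(idx$clip[i], ".rds")), "preprocess"))
        labels <- readLabels(file.path(dir, "videos",
          paste0(idx$clip[i], "_labels.csv")))
        ts <- lapply(wins, extractWindowFeatures,
                     trackLen = cfg$track_len, spacing = cfg$spacing,
                     qualityFrac = cfg$quality_frac, minVar = cfg$min_var,
                     maxVar = cfg$max_var, maxDisp = cfg$max_disp,
                     hofZeroThresh = cfg$hof_zero_thresh)
        wl <- vapply(seq_along(wins), function(w)
          aggregateWindowLabel(labels[seq((w - 1L) * wf + 1L, w * wf)]), 1L)
        saveRDS(list(features = ts, windowLabels = wl),
                file.path(fdir, paste0(idx$clip[i], ".rds")))
      }
      fdir
    },
    "fit-codebook" = {
      idx <- read.csv(.needs(dir, "index.csv", "simulate"))
      tr <- idx$clip[idx$set == "train"]
      feats <- unlist(lapply(tr, function(cl)
        readRDS(.needs(dir, file.path("features", paste0(cl, ".rds")),
                       "features"))$features), recursive = FALSE)
      cb <- fitCodebooks(feats, K = cfg$K, nSubset = cfg$n_subset,
                         seed = cfg$seed)
      saveRDS(cb, file.path(dir, "codebooks.rds"))
      file.path(dir, "codebooks.rds")
    },
    "encode" = {
      idx <- read.csv(.needs(dir, "index.csv", "simulate"))
      cb <- readRDS(.needs(dir, "codebooks.rds", "fit-codebook"))
      enc <- list(groups = list())
      for (s in unique(idx$set)) {
        cls <- idx$clip[idx$set == s]
        feats <- list(); labs <- integer(0); anims <- integer(0)
        for (cl in cls) {
          fr <- readRDS(.needs(dir, file.path("features",
                                              paste0(cl, ".rds")),
                               "features"))
          feats <- c(feats, fr$features)
          labs <- c(labs, fr$windowLabels)
          anims <- c(anims, rep(idx$animal[idx$clip == cl],
                                length(fr$features)))
        }
        enc[[s]] <- encodeWindows(feats, cb, labels = labs,
                                  frameRate = cfg$frame_rate_hz,
                                  windowFrames = wf, alpha = cfg$alpha)
        enc$groups[[s]] <- anims
      }
      saveRDS(enc, file.path(dir, "encoded.rds"))
      file.path(dir, "encoded.rds")
    },
    "train" = {
      enc <- readRDS(.needs(dir, "encoded.rds", "encode"))
      model <- trainBehaviorClassifier(enc$train, cvFolds = cfg$cv_folds,
                                       cGrid = 2^cfg$log2c,
                                       gGrid = 2^cfg$log2g,
                                       pcaVar = cfg$pca_var,
                                       seed = cfg$seed,
                                       groups = enc$groups$train)
      saveRDS(model, file.path(dir, "model.rds"))
      file.path(dir, "model.rds")
    },
    "predict" = {
      enc <- readRDS(.needs(dir, "encoded.rds", "encode"))
      model <- readRDS(.needs(dir, "model.rds", "train"))
      eth <- predictSoft(model, enc$test)
      write.csv(ethogramTable(eth), file.path(dir, "ethogram.csv"),
                row.names = FALSE)
      saveRDS(eth, file.path(dir, "ethogram.rds"))
      file.path(dir, "ethogram.csv")
    },
    "evaluate" = {
      enc <- readRDS(.needs(dir, "encoded.rds", "encode"))
      model <- readRDS(.needs(dir, "model.rds", "train"))
      eth <- readRDS(.needs(dir, "ethogram.rds", "predict"))
      probs <- .classProbs(model, enc$test)
      colnames(probs) <- as.character(model@classes)
      ev <- evaluateClassification(eth, windowInfo(enc$test)$label,
                                   probs = probs)
      jsonlite::write_json(list(overall_accuracy = ev$overallAccuracy,
                                per_class = ev$perClass),
                           file.path(dir, "metrics.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write.csv(as.data.frame.matrix(ev$confusion),
                file.path(dir, "confusion.csv"))
      file.path(dir, "metrics.json")
    },
    "embed" = {
      enc <- readRDS(.needs(dir, "encoded.rds", "encode"))
      map <- buildMotifMap(enc$train, perplexity = cfg$perplexity,
                           sigmaFrac = cfg$sigma_frac, gridN = cfg$grid_n,
                           peakThreshFrac = cfg$peak_thresh_frac,
                           pcaVar = cfg$pca_var, seed = cfg$seed)
      saveRDS(map, file.path(dir, "motifmap.rds"))
      write.csv(regionTable(map), file.path(dir, "regions.csv"),
                row.names = FALSE)
      file.path(dir, "regions.csv")
    },
    "egestion" = {
      idx <- read.csv(.needs(dir, "index.csv", "simulate"))
      ev <- NULL
      for (i in seq_len(nrow(idx))) {
        g <- read.csv(.needs(dir, file.path("geometry",
          paste0(idx$clip[i], ".csv")), "preprocess"))
        wt <- widthTrace(g, frameRate = cfg$frame_rate_hz)
        hw <- cfg$egestion_half_window_min
        if (length(wt$width) <= hw * 60 * cfg$frame_rate_hz) next
        f <- filterWidth(wt$width, cfg$frame_rate_hz, hw)
        d <- detectEgestion(f, cfg$frame_rate_hz, hw)
        if (nrow(d)) ev <- rbind(ev, cbind(clip = idx$clip[i], d))
      }
      if (is.null(ev))
        ev <- data.frame(clip = character(0), frame = integer(0),
                         time_s = numeric(0), height_px = numeric(0),
                         edge_flag = logical(0))
      write.csv(ev, file.path(dir, "egestion_events.csv"),
                row.names = FALSE)
      file.path(dir, "egestion_events.csv")
    })
  .updateManifest(dir, stage, cfg, out[file.exists(out)])
  invisible(out)
}
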