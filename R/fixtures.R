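# Synthetic behaving-animal fixtures.
#
# The generator renders a bright deformable body (a solid, possibly bent
# ellipse) with curved 3-px tentacle strokes at intermediate intensity on a
# dark background, so the 3-way intensity clustering used by segmentation
# (body / weak tentacles / background) is exercised. Ground truth per frame
# is the moment ellipse of the true body mask plus the head polarity.

.synthBehaviors <- c("silent", "elongation", "tentacle_sway", "body_sway",
                     "bending", "contraction", "egestion")

#' Specification of one synthetic behavior clip
#'
#' @param behavior one of silent, elongation, tentacle_sway, body_sway,
#'   bending, contraction, egestion.
#' @param duration_s clip length in seconds.
#' @param frame_rate_hz acquisition rate (default 5 Hz, the imaging rate the
#'   pipeline is designed around).
#' @param image_size square frame side in pixels.
#' @param body_length_px full body length (major axis) in pixels.
#' @param n_tentacles tentacle count.
#' @param noise_sd Gaussian pixel noise, gray-level units on a [0, 1] scale.
#' @param seed integer seed; identical specs give bit-identical clips.
#' @return a \code{SyntheticSpec} list.
#' @export
syntheticSpec <- function(behavior, duration_s = 5, frame_rate_hz = 5,
                          image_size = 300, body_length_px = 120,
                          n_tentacles = 5, noise_sd = 0.02, seed = 1) {
  if (!is.character(behavior) || length(behavior) != 1L ||
      !(behavior %in% .synthBehaviors))
    stop("unknown behavior tag: ", behavior, " (hydrabow_unknown_behavior)",
         call. = FALSE)
  stopifnot(duration_s > 0, frame_rate_hz > 0, n_tentacles >= 0,
            image_size >= 64, body_length_px > 10, noise_sd >= 0)
  structure(list(behavior = behavior, duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz, image_size = image_size,
                 body_length_px = body_length_px, n_tentacles = n_tentacles,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Evaluate with a private RNG stream and restore the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

unitVec <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

# Render one frame. Body rasterization and moments are computed on the body
# bounding box only; tentacles are stamped as pixel index sets.
.renderFrame <- function(S, cx, cy, a, b, theta, bend, tentacles, tlen,
                         sway, masks = FALSE) {
  u <- unitVec(theta); v <- c(-u[2L], u[1L])
  r <- ceiling(a + abs(bend) + b + 2)
  x0 <- max(1L, floor(cx - r)); x1 <- min(S, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(S, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  dx <- xs - cx; dy <- ys - cy
  s <- outer(dx * u[1L], dy * u[2L], "+")
  d <- outer(dx * v[1L], dy * v[2L], "+")
  d2 <- d - bend * (s / a)^2
  bodyLoc <- (s / a)^2 + (d2 / b)^2 <= 1
  # head point and local head direction on the bent midline
  H <- c(cx, cy) + a * u + bend * v
  headAng <- theta + atan2(2 * bend, a) * 180 / pi
  tentIdx <- integer(0)
  if (length(tentacles)) {
    for (k in seq_along(tentacles)) {
      tk <- tentacles[[k]]
      len <- max(tk$length * tlen, 2)
      uu <- seq(0, len, by = 1)
      ang <- (headAng + tk$spread + sway[k] + tk$curv * uu / len) * pi / 180
      pxs <- round(H[1L] + cumsum(cos(ang)))
      pys <- round(H[2L] + cumsum(sin(ang)))
      for (di in -1:1) for (dj in -1:1) {
        ix <- pxs + di; iy <- pys + dj
        ok <- ix >= 1 & ix <= S & iy >= 1 & iy <= S
        tentIdx <- c(tentIdx, ix[ok] + (iy[ok] - 1L) * S)
      }
    }
    tentIdx <- unique(tentIdx)
  }
  img <- matrix(0.03, S, S)
  img[tentIdx] <- 0.45
  sub <- img[xs, ys, drop = FALSE]
  sub[bodyLoc] <- 0.85
  img[xs, ys] <- sub
  el <- momentEllipse(bodyLoc)
  el$cx <- el$cx + x0 - 1; el$cy <- el$cy + y0 - 1
  out <- list(img = img, ellipse = el)
  if (masks) {
    body <- matrix(FALSE, S, S); body[xs, ys] <- bodyLoc
    tent <- matrix(FALSE, S, S); tent[tentIdx] <- TRUE
    out$body <- body; out$tent <- tent & !body
  }
  out
}

#' Generate a synthetic behavior clip with ground truth
#'
#' Renders the behavior named in \code{spec} as parameterized kinematics of
#' the body ellipse and tentacles: silent is static apart from noise;
#' elongation grows the major axis monotonically (shrinking the minor axis
#' to conserve area); contraction shortens body and tentacles rapidly and
#' then oscillates in the contracted state; tentacle_sway oscillates only
#' the tentacle strokes; body_sway rotates the animal rigidly about its
#' foot; bending increases midline curvature; egestion drops the minor axis
#' by 35\% in under a second and recovers.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param masks if TRUE, also return per-frame logical body and tentacle
#'   masks (memory heavy; used by cross-module tests).
#' @return list with elements \code{clip} (a \code{VideoClip}) and
#'   \code{truth}: \code{per_frame_label} (character), \code{ellipse_track}
#'   (data.frame \code{frame, cx, cy, major, minor, angle_deg, head_x,
#'   head_y}), \code{egestion_times} (frame indices).
#' @export
makeBehaviorClip <- function(spec, masks = FALSE) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    S <- spec$image_size
    n <- max(1L, round(spec$duration_s * spec$frame_rate_hz))
    t <- (seq_len(n) - 1) / spec$frame_rate_hz
    Tdur <- spec$duration_s
    a0 <- spec$body_length_px / 2
    b0 <- 0.14 * spec$body_length_px
    cx0 <- S / 2 + runif(1, -0.04, 0.04) * S
    cy0 <- S / 2 + runif(1, -0.04, 0.04) * S
    theta0 <- runif(1, -180, 180)
    nT <- spec$n_tentacles
    tentacles <- lapply(seq_len(nT), function(k) {
      list(spread = seq(-40, 40, length.out = max(nT, 2))[k] + runif(1, -5, 5),
           length = spec$body_length_px * runif(1, 0.30, 0.42),
           curv = runif(1, -30, 30))
    })
    swayA <- runif(max(nT, 1), 10, 18)
    swayF <- runif(max(nT, 1), 0.25, 0.5)
    swayP <- runif(max(nT, 1), 0, 2 * pi)

    a <- rep(a0, n); b <- rep(b0, n); th <- rep(theta0, n)
    cx <- rep(cx0, n); cy <- rep(cy0, n)
    bend <- numeric(n); tlen <- rep(1, n)
    sway <- matrix(0, n, max(nT, 1L))
    egestion_times <- integer(0)

    switch(spec$behavior,
      silent = NULL,
      elongation = {
        g <- 1 + 0.35 * t / Tdur
        a <- a0 * g; b <- b0 / sqrt(g)
      },
      contraction = {
        tau <- min(1.5, Tdur / 2)
        f <- 1 - 0.45 * pmin(t / tau, 1)
        osc <- ifelse(t > tau, 0.06 * sin(2 * pi * 0.3 * (t - tau)), 0)
        f <- f + osc
        a <- a0 * f; b <- b0 / sqrt(f)
        tlen <- 0.45 + 0.55 * f
      },
      tentacle_sway = {
        for (k in seq_len(nT))
          sway[, k] <- swayA[k] * sin(2 * pi * swayF[k] * t + swayP[k])
      },
      body_sway = {
        th <- theta0 + 8 * sin(2 * pi * 0.3 * t)
        foot <- c(cx0, cy0) - a0 * unitVec(theta0)
        cx <- foot[1L] + a0 * cos(th * pi / 180)
        cy <- foot[2L] + a0 * sin(th * pi / 180)
      },
      bending = {
        bend <- 0.9 * b0 * t / Tdur
      },
      egestion = {
        ev <- max(2L, as.integer(round(n / 2)))
        egestion_times <- ev
        rate <- spec$frame_rate_hz
        pulse <- numeric(n)
        for (i in seq_len(n)) {
          dt <- (i - ev) / rate
          pulse[i] <- if (dt < 0) 0 else if (dt < 0.4) dt / 0.4 else
            max(0, 1 - (dt - 0.4) / 2.5)
        }
        b <- b0 * (1 - 0.35 * pulse)
      })

    frames <- array(0, c(S, S, n))
    track <- data.frame(frame = seq_len(n), cx = NA_real_, cy = NA_real_,
                        major = NA_real_, minor = NA_real_,
                        angle_deg = NA_real_, head_x = NA_real_,
                        head_y = NA_real_)
    bodyMasks <- if (masks) vector("list", n) else NULL
    tentMasks <- if (masks) vector("list", n) else NULL
    for (i in seq_len(n)) {
      fr <- .renderFrame(S, cx[i], cy[i], a[i], b[i], th[i], bend[i],
                         tentacles, tlen[i], sway[i, ], masks = masks)
      img <- fr$img
      if (spec$noise_sd > 0) {
        img <- img + rnorm(S * S, 0, spec$noise_sd)
        img[img < 0] <- 0; img[img > 1] <- 1
      }
      frames[, , i] <- img
      el <- fr$ellipse
      hd <- c(cx[i], cy[i]) + a[i] * unitVec(th[i]) +
        bend[i] * c(-unitVec(th[i])[2L], unitVec(th[i])[1L])
      hv <- hd - c(el$cx, el$cy); hv <- hv / sqrt(sum(hv^2))
      track[i, 2:8] <- c(el$cx, el$cy, el$major, el$minor, el$angle,
                         hv[1L], hv[2L])
      if (masks) { bodyMasks[[i]] <- fr$body; tentMasks[[i]] <- fr$tent }
    }
    clip <- new("VideoClip", frames = frames,
                frameRate = spec$frame_rate_hz,
                meta = list(spec = unclass(spec)))
    out <- list(clip = clip,
                truth = list(per_frame_label = rep(spec$behavior, n),
                             ellipse_track = track,
                             egestion_times = egestion_times))
    if (masks) out$truth$masks <- list(body = bodyMasks, tentacle = tentMasks)
    out
  })
}

#' Synthetic body-width trace with injected egestion events
#'
#' Baseline width plus Gaussian noise, with step drops of
#' \code{baseline_px * drop_frac} at the stated frames, recovering linearly
#' over \code{recover_s} seconds — the width signature of the rapid radial
#' contraction that empties the body cavity. The default recovery spans 30
#' minutes: the cavity refills slowly, which is what gives the width trace
#' its sawtooth shape and makes the drop sharply localized in time.
#'
#' @param n_frames trace length.
#' @param egestion_times event frame indices (1-based).
#' @param baseline_px baseline width in pixels.
#' @param drop_frac fractional width drop, in (0, 1).
#' @param noise_sd Gaussian noise SD in pixels.
#' @param seed integer seed.
#' @param frame_rate_hz frames per second.
#' @param recover_s recovery span in seconds.
#' @return numeric width series of length \code{n_frames}.
#' @export
makeWidthTrace <- function(n_frames, egestion_times = integer(0),
                           baseline_px = 30, drop_frac = 0.4, noise_sd = 0,
                           seed = 1, frame_rate_hz = 5, recover_s = 1800) {
  stopifnot(n_frames >= 1, drop_frac > 0, drop_frac < 1, baseline_px > 0)
  egestion_times <- as.integer(egestion_times)
  if (any(egestion_times < 1L | egestion_times > n_frames))
    stop("egestion time outside [1, n_frames]", call. = FALSE)
  withSeed(seed, {
    w <- rep(baseline_px, n_frames)
    rec <- max(1L, round(recover_s * frame_rate_hz))
    for (ev in egestion_times) {
      idx <- ev:min(n_frames, ev + rec)
      depth <- baseline_px * drop_frac * (1 - (idx - ev) / rec)
      w[idx] <- w[idx] - depth
    }
    if (noise_sd > 0) w <- w + rnorm(n_frames, 0, noise_sd)
    w
  })
}

#' Read and write grayscale video clips
#'
#' Multi-page TIFF is the primary, lossless container (32-bit float pages,
#' so write-then-read round-trips pixel values exactly). AVI input is not
#' supported in this build; convert to TIFF first.
#'
#' @param path file path ending in .tif/.tiff.
#' @param clip a \code{VideoClip}.
#' @param frameRate frame rate to attach on read (TIFF carries none).
#' @return \code{readVideo} returns a \code{VideoClip}.
#' @export
readVideo <- function(path, frameRate = 5) {
  if (!file.exists(path) || file.info(path)$size == 0)
    stop("unreadable or empty video file: ", path, call. = FALSE)
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("AVI input is not supported; convert to multi-page TIFF",
         call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable video file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
  if (!length(pages)) stop("empty TIFF stack: ", path, call. = FALSE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  frames <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  new("VideoClip", frames = frames, frameRate = frameRate,
      meta = list(source = path))
}

#' @rdname readVideo
#' @export
writeVideo <- function(clip, path) {
  stopifnot(is(clip, "VideoClip"))
  pages <- lapply(seq_len(nFrames(clip)), function(i) clip@frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and write per-frame behavior labels
#'
#' CSV with columns \code{frame_index,label_code}; codes are validated
#' against \code{\link{behaviorClasses}} (the none class is 0).
#'
#' @param path CSV path.
#' @param labels integer label codes, one per frame.
#' @return \code{readLabels} returns an integer vector.
#' @export
readLabels <- function(path) {
  df <- read.csv(path)
  if (!all(c("frame_index", "label_code") %in% names(df)))
    stop("label CSV must have columns frame_index,label_code", call. = FALSE)
  ok <- df$label_code %in% behaviorClasses()$code
  if (!all(ok))
    stop("unknown label codes at rows: ",
         paste(utils::head(which(!ok), 10L), collapse = ", "), call. = FALSE)
  df <- df[order(df$frame_index), ]
  as.integer(df$label_code)
}

#' @rdname readLabels
#' @export
writeLabels <- function(labels, path) {
  labels <- as.integer(labels)
  if (!all(labels %in% behaviorClasses()$code))
    stop("unknown label codes: ",
         paste(unique(labels[!labels %in% behaviorClasses()$code]),
               collapse = ", "), call. = FALSE)
  write.csv(data.frame(frame_index = seq_along(labels), label_code = labels),
            path, row.names = FALSE)
  invisible(path)
}
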