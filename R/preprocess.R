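# Segmentation, body-column ellipse fitting and canonical registration.

#' Estimate the static image background
#'
#' Morphological grayscale opening with a disc larger than the animal
#' removes it from the frame, leaving the background. The opening is
#' computed at a reduced scale for speed and clipped under the frame so the
#' anti-extensivity of the operation is preserved exactly.
#'
#' @param frame numeric matrix.
#' @param radius opening disc radius in pixels; must exceed half the animal
#'   width (default twice a typical body width).
#' @param downscale integer working-scale divisor.
#' @return background image, pixelwise \code{<= frame}.
#' @export
estimateBackground <- function(frame, radius = 60, downscale = 4L) {
  if (2 * radius + 1 > min(dim(frame)))
    stop("structuring element larger than image", call. = FALSE)
  if (downscale > 1L) {
    sm <- as.matrix(EBImage::resize(frame, nrow(frame) %/% downscale))
    r <- max(1L, round(radius / downscale))
    op <- EBImage::opening(sm, EBImage::makeBrush(2L * r + 1L, "disc"))
    bg <- as.matrix(EBImage::resize(op, w = nrow(frame), h = ncol(frame)))
  } else {
    bg <- as.matrix(EBImage::opening(frame,
            EBImage::makeBrush(2L * round(radius) + 1L, "disc")))
  }
  pmin(bg, frame)
}

# Deterministic 1-D k-means on a 256-bin intensity histogram. Returns a
# cluster id per input value. Empty clusters keep their previous center.
.kmeans1d <- function(x, k = 3L, nbins = 256L, iter = 100L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  bin <- pmin(as.integer((x - rng[1L]) / diff(rng) * nbins) + 1L, nbins)
  h <- tabulate(bin, nbins)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  cw <- cumsum(h) / sum(h)
  centers <- mids[vapply(c(0.05, 0.6, 0.98)[seq_len(k)],
                         function(q) which.max(cw >= q), 1L)]
  centers <- sort(centers + seq_len(k) * 1e-9)
  assign <- integer(nbins)
  for (it in seq_len(iter)) {
    d <- abs(outer(mids, centers, "-"))
    newAssign <- max.col(-d, ties.method = "first")
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (j in seq_len(k)) {
      w <- h[assign == j]
      if (sum(w) > 0) centers[j] <- sum(mids[assign == j] * w) / sum(w)
    }
  }
  assign[bin]
}

# Otsu threshold on a numeric sample (maximizes between-class variance).
.otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(as.integer((x - rng[1L]) / diff(rng) * nbins) + 1L,
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  k <- which.max(sigma2)
  rng[1L] + k / nbins * diff(rng)
}

#' Segment the animal from a frame
#'
#' Background subtraction, linear contrast stretch (saturating the extreme
#' 1\% of intensities), 3-cluster 1-D k-means on pixel intensity (body /
#' weak tentacles / background; the largest cluster is background), removal
#' of connected components smaller than 0.25\% of the image area, and a
#' 3-px dilation of the remaining mask.
#'
#' @param frame,background numeric matrices of equal size.
#' @param minAreaFrac connected-component area threshold as a fraction of
#'   the image area.
#' @param dilatePx dilation radius in pixels.
#' @return logical animal mask.
#' @export
segmentAnimal <- function(frame, background, minAreaFrac = 0.0025,
                          dilatePx = 3L) {
  stopifnot(all(dim(frame) == dim(background)))
  sub <- pmax(frame - background, 0)
  q <- quantile(sub, c(0.01, 0.99), names = FALSE)
  if (q[2L] <= q[1L]) q <- range(sub)   # sparse animal: stretch by range
  if (q[2L] <= q[1L]) stop("no-animal: flat frame", call. = FALSE)
  str <- clamp01((sub - q[1L]) / (q[2L] - q[1L]))
  cl <- .kmeans1d(as.vector(str), k = 3L)
  bgCluster <- which.max(tabulate(cl, 3L))
  fg <- matrix(cl != bgCluster, nrow(frame), ncol(frame))
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0) stop("no-animal: empty foreground", call. = FALSE)
  areas <- tabulate(lab[lab > 0], max(lab))
  keep <- which(areas >= minAreaFrac * length(frame))
  if (!length(keep)) stop("no-animal: all components below area threshold",
                          call. = FALSE)
  mask <- matrix(lab %in% keep, nrow(frame), ncol(frame))
  as.matrix(EBImage::dilate(mask,
    EBImage::makeBrush(2L * dilatePx + 1L, "disc"))) > 0
}

#' Fit the body column with a two-pass Otsu and image moments
#'
#' The background-removed frame is smoothed with a 3x3 Gaussian (sigma = 1
#' px) and thresholded with Otsu's method; a second Otsu threshold computed
#' within the first above-threshold region isolates the bright body column,
#' which is fitted with an ellipse by second-order moments. The moments are
#' weighted by the smoothed intensity over the slightly dilated body-column
#' region: the second threshold falls between tentacle and body intensity
#' and cuts the boundary ramp inside the true edge, so moments of the bare
#' binary mask underestimate the axes by 1-2 px, while the symmetric
#' intensity ramp centers the weighted fit on the true boundary.
#'
#' @param frame,background numeric matrices.
#' @param mask optional animal mask restricting the fit.
#' @return list with \code{cx, cy, major, minor, angle} (degrees in
#'   (-90, 90]), \code{bodyMask} (logical body-column mask), and
#'   unresolved polarity (\code{head = NULL}).
#' @export
fitBodyColumn <- function(frame, background, mask = NULL) {
  sub <- pmax(frame - background, 0)
  sm <- convSep(sub, gaussianKernel1d(1, 1L))
  if (!is.null(mask)) sm[!mask] <- 0
  th1 <- .otsu(as.vector(sm))
  r1 <- sm > th1
  if (!any(r1)) stop("body-column region empty (first pass)", call. = FALSE)
  th2 <- .otsu(sm[r1])
  r2 <- r1 & sm > th2
  if (!any(r2)) stop("body-column region empty (second pass)", call. = FALSE)
  lab <- EBImage::bwlabel(r2)
  areas <- tabulate(lab[lab > 0], max(lab))
  body <- lab == which.max(areas)
  bodyD <- as.matrix(EBImage::dilate(body * 1,
                                     EBImage::makeBrush(5L, "disc"))) > 0
  el <- momentEllipse(sm * bodyD)
  c(el, list(bodyMask = body))
}

# Square probe mask bounds at an ellipse endpoint; side scales with the
# minor axis (default 3x, so fanned tentacles fall under the head probe).
.probeBounds <- function(el, sign, S, probeScale = 3) {
  u <- unitVec(el$angle)
  p <- c(el$cx, el$cy) + sign * (el$major / 2) * u
  half <- probeScale * el$minor / 2
  list(x0 = max(1L, round(p[1L] - half)), x1 = min(S[1L], round(p[1L] + half)),
       y0 = max(1L, round(p[2L] - half)), y1 = min(S[2L], round(p[2L] + half)),
       center = p)
}

.probeArea <- function(region, pb) {
  if (pb$x0 > pb$x1 || pb$y0 > pb$y1) return(0)
  sum(region[pb$x0:pb$x1, pb$y0:pb$y1])
}

#' Resolve head/foot polarity of a fitted body ellipse
#'
#' Square probe masks (side = minor axis) are placed at both major-axis
#' endpoints; the end covering the larger area of animal-minus-body-column
#' (i.e. tentacles) is the head/mouth end.
#'
#' @param mask logical animal mask.
#' @param bodyMask logical body-column mask.
#' @param el ellipse as returned by \code{\link{fitBodyColumn}}.
#' @param prevHead optional unit head vector from the previous frame, used
#'   when both probes are empty.
#' @param probeScale probe side as a multiple of the minor axis.
#' @return \code{el} with elements \code{head_x, head_y} (unit vector from
#'   the centroid toward the head) added.
#' @export
resolvePolarity <- function(mask, bodyMask, el, prevHead = NULL,
                            probeScale = 3) {
  region <- mask & !bodyMask
  S <- dim(mask)
  pPlus <- .probeBounds(el, +1, S, probeScale)
  pMinus <- .probeBounds(el, -1, S, probeScale)
  aPlus <- .probeArea(region, pPlus)
  aMinus <- .probeArea(region, pMinus)
  u <- unitVec(el$angle)
  if (aPlus == 0 && aMinus == 0) {
    if (is.null(prevHead))
      stop("polarity unresolved: both probe areas empty", call. = FALSE)
    sgn <- if (sum(prevHead * u) >= 0) 1 else -1
  } else {
    sgn <- if (aPlus >= aMinus) 1 else -1
  }
  el$head_x <- sgn * u[1L]
  el$head_y <- sgn * u[2L]
  el
}

#' Split the animal mask into tentacle, upper and lower body parts
#'
#' The tentacle region is the animal-minus-body-column area under the
#' head-end probe; the remaining mask is split at the ellipse minor axis,
#' the head side being the upper body.
#'
#' @param mask,bodyMask logical masks.
#' @param el polarity-resolved ellipse.
#' @param probeScale probe side as a multiple of the minor axis.
#' @return list of pairwise-disjoint logical masks \code{tentacle},
#'   \code{upper}, \code{lower}, each a subset of \code{mask}.
#' @export
splitBodyParts <- function(mask, bodyMask, el, probeScale = 3) {
  if (is.null(el$head_x)) stop("polarity must be resolved first")
  S <- dim(mask)
  h <- c(el$head_x, el$head_y)
  sgn <- if (sum(h * unitVec(el$angle)) >= 0) 1 else -1
  pb <- .probeBounds(el, sgn, S, probeScale)
  tent <- matrix(FALSE, S[1L], S[2L])
  if (pb$x0 <= pb$x1 && pb$y0 <= pb$y1) {
    sel <- mask[pb$x0:pb$x1, pb$y0:pb$y1] & !bodyMask[pb$x0:pb$x1, pb$y0:pb$y1]
    tent[pb$x0:pb$x1, pb$y0:pb$y1] <- sel
  }
  rest <- mask & !tent
  sProj <- outer((seq_len(S[1L]) - el$cx) * h[1L],
                 (seq_len(S[2L]) - el$cy) * h[2L], "+")
  upper <- rest & sProj > 0
  lower <- rest & sProj <= 0
  list(tentacle = tent, upper = upper, lower = lower)
}

#' Per-frame geometry and masks for a whole clip
#'
#' Runs background estimation (first frame), segmentation, body-column
#' fitting and polarity resolution on every frame. A frame whose
#' segmentation or fit fails inherits the previous frame's geometry and is
#' flagged.
#'
#' @param clip a \code{VideoClip}.
#' @param bgRadius opening radius passed to \code{\link{estimateBackground}}.
#' @param keepMasks if TRUE, per-frame animal and body-column masks are
#'   returned (needed for registration).
#' @return list with \code{geometry} (data.frame \code{frame, cx, cy, major,
#'   minor, angle_deg, head_x, head_y, flagged}), \code{background}, and
#'   optionally \code{masks}, \code{bodyMasks}.
#' @export
analyzeClip <- function(clip, bgRadius = 60, keepMasks = TRUE) {
  stopifnot(is(clip, "VideoClip"))
  n <- nFrames(clip)
  bg <- estimateBackground(clip@frames[, , 1L], radius = bgRadius)
  geom <- data.frame(frame = seq_len(n), cx = NA_real_, cy = NA_real_,
                     major = NA_real_, minor = NA_real_,
                     angle_deg = NA_real_, head_x = NA_real_,
                     head_y = NA_real_, flagged = FALSE)
  masks <- if (keepMasks) vector("list", n) else NULL
  bodyMasks <- if (keepMasks) vector("list", n) else NULL
  prev <- NULL
  prevMask <- NULL
  prevBody <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch({
      fr <- clip@frames[, , i]
      m <- segmentAnimal(fr, bg)
      el <- fitBodyColumn(fr, bg, m)
      el <- resolvePolarity(m, el$bodyMask, el,
                            prevHead = if (!is.null(prev))
                              c(prev$head_x, prev$head_y) else NULL)
      list(el = el, mask = m)
    }, error = function(e) NULL)
    if (is.null(res)) {
      if (is.null(prev))
        stop("clip analysis failed on frame ", i,
             " with no previous geometry", call. = FALSE)
      geom[i, 2:8] <- c(prev$cx, prev$cy, prev$major, prev$minor,
                        prev$angle, prev$head_x, prev$head_y)
      geom$flagged[i] <- TRUE
      if (keepMasks) { masks[[i]] <- prevMask; bodyMasks[[i]] <- prevBody }
    } else {
      el <- res$el
      geom[i, 2:8] <- c(el$cx, el$cy, el$major, el$minor, el$angle,
                        el$head_x, el$head_y)
      prev <- el
      prevMask <- res$mask
      prevBody <- el$bodyMask
      if (keepMasks) { masks[[i]] <- res$mask; bodyMasks[[i]] <- el$bodyMask }
    }
  }
  out <- list(geometry = geom, background = bg)
  if (keepMasks) { out$masks <- masks; out$bodyMasks <- bodyMasks }
  out
}

#' Register one behavior-element window to the canonical pose
#'
#' A single similarity transform per window — built from the window-average
#' centroid, head direction and major-axis length — maps every frame to a
#' 300 x 300 canvas with the body axis vertical, the head pointing to +y
#' and a body length of 100 px. Pixels outside the (transformed) animal
#' mask are zeroed. Warping is by inverse mapping with bilinear
#' interpolation.
#'
#' @param clip a \code{VideoClip}.
#' @param analysis result of \code{\link{analyzeClip}} with masks kept.
#' @param windowId 1-based window index.
#' @param windowFrames frames per window (default 25 = 5 s at 5 Hz).
#' @param outSize canonical canvas side.
#' @param bodyLength canonical body length in px.
#' @return a \code{\link{RegisteredWindow-class}} object.
#' @export
registerWindow <- function(clip, analysis, windowId, windowFrames = 25L,
                           outSize = 300L, bodyLength = 100) {
  n <- nFrames(clip)
  i0 <- (windowId - 1L) * windowFrames + 1L
  i1 <- i0 + windowFrames - 1L
  if (i1 > n) stop("window ", windowId, " is shorter than ", windowFrames,
                   " frames", call. = FALSE)
  g <- analysis$geometry[i0:i1, ]
  ctr <- c(mean(g$cx), mean(g$cy))
  hbar <- c(mean(g$head_x), mean(g$head_y))
  hbar <- hbar / sqrt(sum(hbar^2))
  scale <- bodyLength / mean(g$major)
  # rotation taking hbar to (0, 1)
  ang <- atan2(1, 0) - atan2(hbar[2L], hbar[1L])
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  cOut <- (outSize + 1) / 2
  # inverse map: source = ctr + (1/s) R^-1 (dest - cOut)
  Ri <- t(R) / scale
  dx <- seq_len(outSize) - cOut
  sx <- as.vector(outer(dx * Ri[1L, 1L], dx * Ri[1L, 2L], "+")) + ctr[1L]
  sy <- as.vector(outer(dx * Ri[2L, 1L], dx * Ri[2L, 2L], "+")) + ctr[2L]
  # precompute bilinear corner indices and weights once per window
  sn <- dim(clip@frames)[1L]; sm <- dim(clip@frames)[2L]
  sx <- pmin(pmax(sx, 1), sn); sy <- pmin(pmax(sy, 1), sm)
  x0 <- pmin(floor(sx), sn - 1L); y0 <- pmin(floor(sy), sm - 1L)
  fx <- sx - x0; fy <- sy - y0
  i00 <- x0 + (y0 - 1L) * sn
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy
  warp <- function(img) matrix(img[i00] * w00 + img[i00 + 1L] * w10 +
                               img[i00 + sn] * w01 + img[i00 + sn + 1L] * w11,
                               outSize, outSize)
  regFrames <- array(0, c(outSize, outSize, windowFrames))
  for (k in seq_len(windowFrames)) {
    i <- i0 + k - 1L
    fr <- warp(clip@frames[, , i])
    mk <- warp(analysis$masks[[i]] * 1) > 0.5
    fr[!mk] <- 0
    regFrames[, , k] <- fr
  }
  mid <- i0 + windowFrames %/% 2L
  el <- as.list(analysis$geometry[mid, ])
  names(el)[names(el) == "angle_deg"] <- "angle"
  parts <- splitBodyParts(analysis$masks[[mid]], analysis$bodyMasks[[mid]],
                          el)
  partsC <- lapply(parts, function(p) warp(p * 1) > 0.5)
  new("RegisteredWindow", frames = regFrames,
      transform = list(scale = scale, angle = ang * 180 / pi, center = ctr,
                       head = hbar),
      parts = partsC, windowId = as.integer(windowId))
}

#' Write body-part masks as a color-coded PNG
#'
#' Tentacle, upper and lower body parts are written as the red, green and
#' blue channels of one image.
#'
#' @param parts list from \code{\link{splitBodyParts}}.
#' @param path output PNG path.
#' @export
writePartMasks <- function(parts, path) {
  img <- array(0, c(dim(parts$tentacle), 3L))
  img[, , 1L] <- parts$tentacle
  img[, , 2L] <- parts$upper
  img[, , 3L] <- parts$lower
  png::writePNG(aperm(img, c(2L, 1L, 3L)), path)
  invisible(path)
}

#' Number of complete windows in a clip
#' @param clip a \code{VideoClip}
#' @param windowFrames frames per window
#' @export
countWindows <- function(clip, windowFrames = 25L)
  nFrames(clip) %/% windowFrames
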