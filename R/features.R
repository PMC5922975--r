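# Dense-trajectory features: optical flow, interest-point tracking and
# HOF/HOG/MBH descriptors over 32 x 32 spatio-temporal patches.

#' Descriptor dimensionalities
#'
#' HOF has 8 orientation bins plus one zero-motion bin; HOG and the two
#' motion-boundary histograms have 8 orientation bins each.
#' @return named list of integer dimensions.
#' @export
descriptorDims <- function() list(hof = 9L, hog = 8L, mbhx = 8L, mbhy = 8L)

gradX <- function(img) (shiftMatrix(img, -1L, 0L) - shiftMatrix(img, 1L, 0L)) / 2
gradY <- function(img) (shiftMatrix(img, 0L, -1L) - shiftMatrix(img, 0L, 1L)) / 2

#' Dense optical flow between two frames
#'
#' Iterative dense Lucas-Kanade flow: intensities are pre-smoothed, the
#' second frame is warped by the current flow estimate, the flow update is
#' solved from Gaussian-windowed structure-tensor sums, and the field is
#' median-filtered (3 x 3) after each iteration to suppress outliers before
#' points are advected along it.
#'
#' @param I1,I2 numeric matrices (consecutive frames).
#' @param sigmaS presmoothing Gaussian sigma (px).
#' @param winRadius integration-window radius (box window, px).
#' @param iters warp-refine iterations.
#' @return list with numeric matrices \code{u} (x component) and \code{v}.
#' @export
denseOpticalFlow <- function(I1, I2, sigmaS = 1.2, winRadius = 7L,
                             iters = 2L) {
  stopifnot(all(dim(I1) == dim(I2)))
  kS <- gaussianKernel1d(sigmaS)
  A <- convSep(I1, kS); B <- convSep(I2, kS)
  n <- nrow(A); m <- ncol(A)
  gx <- matrix(seq_len(n), n, m); gy <- matrix(rep(seq_len(m), each = n), n, m)
  u <- matrix(0, n, m); v <- matrix(0, n, m)
  Ix <- gradX(A); Iy <- gradY(A)
  A11 <- boxFilter(Ix * Ix, winRadius); A12 <- boxFilter(Ix * Iy, winRadius)
  A22 <- boxFilter(Iy * Iy, winRadius)
  det <- A11 * A22 - A12^2
  ok <- det > 1e-9
  det[!ok] <- 1
  for (it in seq_len(iters)) {
    Bw <- if (it == 1L) B else
      matrix(bilinearSample(B, as.vector(gx + u), as.vector(gy + v)), n, m)
    It <- Bw - A
    b1 <- -boxFilter(Ix * It, winRadius)
    b2 <- -boxFilter(Iy * It, winRadius)
    du <- (A22 * b1 - A12 * b2) / det
    dv <- (A11 * b2 - A12 * b1) / det
    du[!ok] <- 0; dv[!ok] <- 0
    u <- u + du
    v <- v + dv
  }
  list(u = medianFilter3(u), v = medianFilter3(v))
}

# Minimum eigenvalue of the Gaussian-windowed structure tensor (the corner
# response used to gate interest-point seeding).
cornerResponse <- function(img, winRadius = 3L) {
  Ix <- gradX(img); Iy <- gradY(img)
  A11 <- boxFilter(Ix * Ix, winRadius); A12 <- boxFilter(Ix * Iy, winRadius)
  A22 <- boxFilter(Iy * Iy, winRadius)
  (A11 + A22 - sqrt((A11 - A22)^2 + 4 * A12^2)) / 2
}

#' Densely sample interest points on a grid inside a mask
#'
#' @param mask logical matrix.
#' @param spacing grid spacing in px (default 5).
#' @return two-column matrix of (x, y) points.
#' @export
samplePoints <- function(mask, spacing = 5L) {
  off <- ceiling(spacing / 2)
  xs <- seq(off, nrow(mask), by = spacing)
  ys <- seq(off, ncol(mask), by = spacing)
  pts <- cbind(x = rep(xs, times = length(ys)),
               y = rep(ys, each = length(xs)))
  pts[mask[pts], , drop = FALSE]
}

#' Track interest points through a window with optical flow
#'
#' Points are seeded on the 5-px grid inside the animal mask at the start
#' of each tracking batch, gated by a corner-response quality threshold
#' (points below \code{qualityFrac} of the frame's maximum response are not
#' seeded), and advected along the median-filtered dense flow for
#' \code{trackLen} frames. Tracks are kept iff the standard deviation of
#' their point positions lies in \code{[minVar, maxVar]} (static and
#' erratic tracks are pruned) and no frame-to-frame displacement exceeds
#' \code{maxDisp} px.
#'
#' @param frames numeric array (nx, ny, nFrames), zero outside the animal.
#' @param flows optional precomputed list of flows (from
#'   \code{\link{denseOpticalFlow}}) for frame pairs; computed if NULL.
#' @param trackLen trajectory span in frames.
#' @param spacing seeding grid spacing.
#' @param qualityFrac corner-quality threshold as a fraction of the
#'   per-frame maximum response.
#' @param minVar,maxVar bounds on the positional standard deviation.
#' @param maxDisp maximum per-step displacement.
#' @return list with matrices \code{x}, \code{y} (nTraj x trackLen) and
#'   integer vector \code{startFrame}.
#' @export
trackTrajectories <- function(frames, flows = NULL, trackLen = 15L,
                              spacing = 5L, qualityFrac = 0.01,
                              minVar = 0.1, maxVar = 50, maxDisp = 50) {
  nFr <- dim(frames)[3L]
  if (nFr < trackLen) stop("window shorter than tracking length")
  if (is.null(flows)) {
    flows <- lapply(seq_len(nFr - 1L), function(i)
      denseOpticalFlow(frames[, , i], frames[, , i + 1L]))
  }
  starts <- seq(1L, nFr - trackLen + 1L, by = max(trackLen - 5L, 1L))
  X <- NULL; Y <- NULL; S <- integer(0)
  for (s in starts) {
    fr <- frames[, , s]
    mask <- fr > 0
    if (!any(mask)) next
    pts <- samplePoints(mask, spacing)
    if (!nrow(pts)) next
    resp <- cornerResponse(fr)
    q <- resp[pts] >= qualityFrac * max(resp)
    pts <- pts[q, , drop = FALSE]
    if (!nrow(pts)) next
    px <- matrix(NA_real_, nrow(pts), trackLen)
    py <- matrix(NA_real_, nrow(pts), trackLen)
    px[, 1L] <- pts[, 1L]; py[, 1L] <- pts[, 2L]
    for (k in seq_len(trackLen - 1L)) {
      fl <- flows[[s + k - 1L]]
      px[, k + 1L] <- px[, k] + bilinearSample(fl$u, px[, k], py[, k])
      py[, k + 1L] <- py[, k] + bilinearSample(fl$v, px[, k], py[, k])
    }
    X <- rbind(X, px); Y <- rbind(Y, py); S <- c(S, rep(s, nrow(px)))
  }
  if (is.null(X))
    return(list(x = matrix(0, 0, trackLen), y = matrix(0, 0, trackLen),
                startFrame = integer(0)))
  dx <- X[, -1L, drop = FALSE] - X[, -trackLen, drop = FALSE]
  dy <- Y[, -1L, drop = FALSE] - Y[, -trackLen, drop = FALSE]
  stepMax <- sqrt(do.call(pmax, as.data.frame(dx^2 + dy^2)))
  bessel <- trackLen / (trackLen - 1)
  posSd <- sqrt(pmax((rowMeans(X^2) - rowMeans(X)^2 +
                      rowMeans(Y^2) - rowMeans(Y)^2) * bessel, 0))
  keep <- posSd >= minVar & posSd <= maxVar & stepMax <= maxDisp
  list(x = X[keep, , drop = FALSE], y = Y[keep, , drop = FALSE],
       startFrame = S[keep])
}

# Orientation-binned integral images for one frame/flow field, as one
# (n+1) x (m+1) x nbins array of summed-area tables (compiled scatter).
.binIntegrals <- function(fx, fy, nbins, fullCircle, zeroBin,
                          zeroThresh = 0.4) {
  mag <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx)
  if (!fullCircle) ang <- ang %% pi
  span <- if (fullCircle) 2 * pi else pi
  bin <- pmin(floor(((ang + if (fullCircle) pi else 0) / span) * nbins) + 1L,
              nbins)
  if (zeroThresh > 0) {
    low <- mag < zeroThresh
    if (zeroBin) {
      bin[low] <- nbins + 1L          # zero-motion bin, counted not weighted
      mag[low] <- 1
    } else {
      bin[low] <- 0L                  # dropped
    }
  }
  tot <- nbins + as.integer(zeroBin)
  storage.mode(bin) <- "integer"
  arr <- bin_integrals_c(mag, bin, tot)
  list(arr = arr, n1 = nrow(fx) + 1L, m1 = ncol(fx) + 1L, nbins = tot)
}

# Accumulate patch sums of bin integrals into acc rows.
.accumPatch <- function(acc, bi, rows, x, y, half, n, m) {
  x0 <- pmin(pmax(round(x) - half, 1L), n)
  x1 <- pmin(pmax(round(x) + half - 1L, 1L), n)
  y0 <- pmin(pmax(round(y) - half, 1L), m)
  y1 <- pmin(pmax(round(y) + half - 1L, 1L), m)
  n1 <- bi$n1
  sz <- bi$n1 * bi$m1
  a <- bi$arr
  for (b in seq_len(bi$nbins)) {
    off <- (b - 1L) * sz
    at <- function(i, j) a[off + i + (j - 1L) * n1]
    acc[rows, b] <- acc[rows, b] +
      at(x1 + 1L, y1 + 1L) - at(x0, y1 + 1L) - at(x1 + 1L, y0) + at(x0, y0)
  }
  acc
}

#' Compute HOF/HOG/MBH descriptors for tracked trajectories
#'
#' For each trajectory the 32-px neighborhood of every tracked point is
#' accumulated into single-cell orientation histograms: HOG from unsigned
#' image-gradient orientations (8 bins, magnitude weighted); HOF from
#' signed flow orientations (8 bins plus a zero bin counting pixels with
#' flow magnitude below \code{hofZeroThresh}); MBHx/MBHy from the spatial
#' gradients of the horizontal/vertical flow component (8 signed bins,
#' gradient magnitudes below \code{mbhThresh} discarded). Histograms are
#' l2-normalized; an all-zero accumulation stays all-zero.
#'
#' @param frames window frame array.
#' @param flows list of per-pair flows (as in
#'   \code{\link{trackTrajectories}}).
#' @param traj list with \code{x}, \code{y}, \code{startFrame}.
#' @param patch patch side in px.
#' @param hofZeroThresh flow magnitude (px/frame) under which a pixel
#'   counts as non-moving.
#' @param mbhThresh flow-gradient magnitude under which a pixel does not
#'   contribute to MBH.
#' @return named list of descriptor matrices \code{hof, hog, mbhx, mbhy}.
#' @export
computeDescriptors <- function(frames, flows, traj, patch = 32L,
                               hofZeroThresh = 0.4, mbhThresh = 0.05) {
  nT <- nrow(traj$x)
  span <- ncol(traj$x)
  dd <- descriptorDims()
  acc <- lapply(dd, function(d) matrix(0, nT, d))
  if (nT == 0L) return(acc)
  n <- dim(frames)[1L]; m <- dim(frames)[2L]
  half <- patch %/% 2L
  nFr <- dim(frames)[3L]
  for (f in seq_len(nFr)) {
    # trajectories whose track visits frame f (slot k = f - start + 1)
    k <- f - traj$startFrame + 1L
    rows <- which(k >= 1L & k <= span)
    if (!length(rows)) next
    idx <- cbind(rows, k[rows])
    x <- traj$x[idx]; y <- traj$y[idx]
    fr <- frames[, , f]
    hogII <- .binIntegrals(gradX(fr), gradY(fr), 8L, FALSE, FALSE,
                           zeroThresh = 0)
    acc$hog <- .accumPatch(acc$hog, hogII, rows, x, y, half, n, m)
    if (f <= length(flows)) {
      rowsF <- rows[k[rows] < span]  # flow step f belongs to tracks not ended
      if (length(rowsF)) {
        kF <- f - traj$startFrame[rowsF] + 1L
        idxF <- cbind(rowsF, kF)
        xf <- traj$x[idxF]; yf <- traj$y[idxF]
        fl <- flows[[f]]
        hofII <- .binIntegrals(fl$u, fl$v, 8L, TRUE, TRUE, hofZeroThresh)
        acc$hof <- .accumPatch(acc$hof, hofII, rowsF, xf, yf, half, n, m)
        mxII <- .binIntegrals(gradX(fl$u), gradY(fl$u), 8L, TRUE, FALSE,
                              zeroThresh = mbhThresh)
        acc$mbhx <- .accumPatch(acc$mbhx, mxII, rowsF, xf, yf, half, n, m)
        myII <- .binIntegrals(gradX(fl$v), gradY(fl$v), 8L, TRUE, FALSE,
                              zeroThresh = mbhThresh)
        acc$mbhy <- .accumPatch(acc$mbhy, myII, rowsF, xf, yf, half, n, m)
      }
    }
  }
  lapply(acc, function(a) {
    rn <- sqrt(rowSums(a^2))
    a[rn > 0, ] <- a[rn > 0, , drop = FALSE] / rn[rn > 0]
    a
  })
}

#' Assign trajectories to body parts
#'
#' A trajectory belongs to the part containing its mean position; a mean
#' position outside all parts (e.g. on zeroed background after
#' registration) is assigned to the nearest part by Euclidean distance.
#'
#' @param traj list with \code{x}, \code{y}.
#' @param parts list of tentacle/upper/lower logical masks.
#' @return factor of part assignments.
#' @export
assignBodyPart <- function(traj, parts) {
  lev <- c("tentacle", "upper", "lower")
  nT <- nrow(traj$x)
  if (nT == 0L) return(factor(character(0), levels = lev))
  mx <- pmin(pmax(round(rowMeans(traj$x)), 1L), nrow(parts$tentacle))
  my <- pmin(pmax(round(rowMeans(traj$y)), 1L), ncol(parts$tentacle))
  idx <- cbind(mx, my)
  out <- rep(NA_character_, nT)
  for (p in lev) out[is.na(out) & parts[[p]][idx]] <- p
  miss <- which(is.na(out))
  if (length(miss)) {
    dmaps <- lapply(lev, function(p)
      as.matrix(EBImage::distmap(1 - parts[[p]])))
    d <- vapply(dmaps, function(dm) dm[idx[miss, , drop = FALSE]],
                numeric(length(miss)))
    d <- matrix(d, nrow = length(miss))
    out[miss] <- lev[max.col(-d, ties.method = "first")]
  }
  factor(out, levels = lev)
}

#' Extract the full dense-trajectory feature set for one registered window
#'
#' Composes flow computation, tracking, descriptor extraction and
#' body-part assignment. Computation is restricted to the bounding box of
#' the animal across the window (plus a margin) for speed.
#'
#' @param rw a \code{\link{RegisteredWindow-class}}.
#' @param trackLen,spacing,qualityFrac,minVar,maxVar,maxDisp see
#'   \code{\link{trackTrajectories}}.
#' @param hofZeroThresh,mbhThresh see \code{\link{computeDescriptors}}.
#' @return a \code{\link{TrajectorySet-class}}.
#' @export
extractWindowFeatures <- function(rw, trackLen = 15L, spacing = 5L,
                                  qualityFrac = 0.01, minVar = 0.1,
                                  maxVar = 50, maxDisp = 50,
                                  hofZeroThresh = 0.4, mbhThresh = 0.05) {
  stopifnot(is(rw, "RegisteredWindow"))
  fr <- rw@frames
  d <- dim(fr)
  occ <- matrix(rowSums(matrix(fr, d[1L] * d[2L], d[3L])) > 0, d[1L], d[2L])
  if (!any(occ)) {
    dd <- descriptorDims()
    return(new("TrajectorySet", x = matrix(0, 0, trackLen),
               y = matrix(0, 0, trackLen), startFrame = integer(0),
               part = factor(character(0),
                             levels = c("tentacle", "upper", "lower")),
               descriptors = lapply(dd, function(d) matrix(0, 0, d))))
  }
  pad <- 20L
  xr <- range(which(rowSums(occ) > 0))
  yr <- range(which(colSums(occ) > 0))
  x0 <- max(1L, xr[1L] - pad); x1 <- min(dim(fr)[1L], xr[2L] + pad)
  y0 <- max(1L, yr[1L] - pad); y1 <- min(dim(fr)[2L], yr[2L] + pad)
  sub <- fr[x0:x1, y0:y1, , drop = FALSE]
  flows <- lapply(seq_len(dim(sub)[3L] - 1L), function(i)
    denseOpticalFlow(sub[, , i], sub[, , i + 1L]))
  traj <- trackTrajectories(sub, flows, trackLen = trackLen,
                            spacing = spacing, qualityFrac = qualityFrac,
                            minVar = minVar, maxVar = maxVar,
                            maxDisp = maxDisp)
  desc <- computeDescriptors(sub, flows, traj, hofZeroThresh = hofZeroThresh,
                             mbhThresh = mbhThresh)
  # back to canonical coordinates
  trajC <- list(x = traj$x + x0 - 1L, y = traj$y + y0 - 1L,
                startFrame = traj$startFrame)
  part <- assignBodyPart(trajC, rw@parts)
  new("TrajectorySet", x = trajC$x, y = trajC$y,
      startFrame = traj$startFrame, part = part, descriptors = desc)
}
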