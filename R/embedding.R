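# Unsupervised motif discovery: exact t-SNE embedding of encoded windows,
# Gaussian kernel density over a square grid, watershed segmentation of the
# density into motif regions, majority-label annotation, and out-of-sample
# placement of new windows against the frozen map.

# Perplexity-calibrated conditional probabilities from one point to a set
# of reference points (binary search on the Gaussian precision).
.condP <- function(d2, perplexity, tol = 1e-5, maxIter = 60L) {
  target <- log(perplexity)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (it in seq_len(maxIter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw <= 0) { H <- 0 } else {
      p <- w / sw
      nz <- p > 0
      H <- -sum(p[nz] * log(p[nz]))
    }
    diff <- H - target
    if (abs(diff) < tol) break
    if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                    else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
           else beta / 2 }
  }
  w <- exp(-d2 * beta)
  w / sum(w)
}

.pairwiseD2 <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  sx <- rowSums(X^2); sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, "+") - 2 * X %*% t(Y)
  pmax(d2, 0)
}

#' Exact t-SNE embedding
#'
#' Standard t-SNE with Euclidean distances, perplexity-calibrated Gaussian
#' conditionals, early exaggeration, momentum and adaptive gains, and a
#' deterministic PCA initialization (plus a seeded sub-pixel jitter). The
#' KL divergence against the unexaggerated P is logged every 25 iterations
#' after the exaggeration phase.
#'
#' @param X numeric matrix (n x d), already dimension-reduced.
#' @param perplexity effective neighborhood size (default 16).
#' @param seed integer seed (initial jitter).
#' @param maxIter gradient-descent iterations.
#' @param eta learning rate; the default follows the common auto rule
#'   max(n / (4 exaggeration), 50), which keeps the exaggerated gradient
#'   step stable for small n.
#' @param exaggeration early-exaggeration factor, applied for the first
#'   \code{exagIter} iterations.
#' @param exagIter length of the exaggeration phase.
#' @return list with \code{Y} (n x 2) and \code{klTrace}.
#' @export
embedTsne <- function(X, perplexity = 16, seed = 1L, maxIter = 1000L,
                      eta = NULL, exaggeration = 12, exagIter = 250L) {
  if (is.null(eta)) eta <- max(nrow(X) / (4 * exaggeration), 50)
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    stop("too few points for perplexity ", perplexity, call. = FALSE)
  d2 <- .pairwiseD2(X)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pi <- .condP(d2[i, -i], perplexity)
    P[i, -i] <- pi
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # deterministic init from the top-2 principal coordinates
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  Y <- pc$x[, 1:2, drop = FALSE]
  Y <- Y / max(sd(Y[, 1L]), 1e-12) * 1e-4
  Y <- Y + withSeed(seed, matrix(rnorm(2 * n, 0, 1e-6), n, 2L))
  dY <- matrix(0, n, 2L); gains <- matrix(1, n, 2L)
  klTrace <- numeric(0)
  for (it in seq_len(maxIter)) {
    Pe <- if (it <= exagIter) P * exaggeration else P
    num <- 1 / (1 + .pairwiseD2(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= exagIter) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8),
                  0.01)
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it > exagIter && it %% 25L == 0L)
      klTrace <- c(klTrace, sum(P * log(P / Q)))
  }
  list(Y = Y, klTrace = klTrace)
}

#' Kernel density map of embedded points
#'
#' Gaussian kernel density on a square grid covering the points with
#' padding; the kernel width is \code{sigmaFrac} times the maximum
#' absolute embedding coordinate. The grid density integrates to ~1.
#'
#' @param points n x 2 matrix.
#' @param sigmaFrac kernel sigma as a fraction of the maximum absolute
#'   coordinate (1/40 by default; 1/60 reveals finer structure on long
#'   recordings).
#' @param gridN grid resolution per side.
#' @param pad padding as a fraction of the coordinate span.
#' @return list with \code{density} (gridN x gridN), \code{gx}, \code{gy}
#'   (axes), \code{sigma}.
#' @export
densityMap <- function(points, sigmaFrac = 1 / 40, gridN = 501L,
                       pad = 0.1) {
  stopifnot(nrow(points) >= 1L)
  sigma <- sigmaFrac * max(abs(points))
  if (sigma <= 0) sigma <- 1e-3
  lo <- min(points); hi <- max(points)
  span <- max(hi - lo, 1e-6)
  gx <- seq(lo - pad * span, hi + pad * span, length.out = gridN)
  gy <- gx
  n <- nrow(points)
  Gx <- exp(-outer(gx, points[, 1L], "-")^2 / (2 * sigma^2))
  Gy <- exp(-outer(gy, points[, 2L], "-")^2 / (2 * sigma^2))
  dens <- (Gx %*% t(Gy)) / (2 * pi * sigma^2 * n)
  list(density = dens, gx = gx, gy = gy, sigma = sigma)
}

#' Watershed segmentation of a density map into motif regions
#'
#' Local density maxima (8-connected, above a fraction of the peak
#' density) are dilated by 3 px — merging near-duplicate peaks — and used
#' as seeds for a watershed on the inverted distance transform, so every
#' grid cell drains to its nearest peak group. Cells below the support
#' threshold get region id 0.
#'
#' @param dens density matrix.
#' @param peakThreshFrac peak/support threshold as a fraction of the
#'   maximum density.
#' @param dilatePx peak dilation radius in px.
#' @return integer matrix of region ids (0 = outside support).
#' @export
segmentDensity <- function(dens, peakThreshFrac = 0.01, dilatePx = 3L) {
  if (diff(range(dens)) == 0)
    return(matrix(1L, nrow(dens), ncol(dens)))
  mx <- shiftMatrix(dens, 1L, 0L)
  isMax <- dens >= mx
  for (d in list(c(-1L, 0L), c(0L, 1L), c(0L, -1L), c(1L, 1L), c(1L, -1L),
                 c(-1L, 1L), c(-1L, -1L)))
    isMax <- isMax & dens >= shiftMatrix(dens, d[1L], d[2L])
  isMax <- isMax & dens > peakThreshFrac * max(dens)
  if (!any(isMax)) return(matrix(1L, nrow(dens), ncol(dens)))
  peaks <- as.matrix(EBImage::dilate(isMax * 1,
    EBImage::makeBrush(2L * dilatePx + 1L, "disc"))) > 0
  dt <- as.matrix(EBImage::distmap(1 - peaks))
  ws <- EBImage::watershed(max(dt) - dt)
  region <- matrix(as.integer(ws), nrow(dens), ncol(dens))
  region[dens <= peakThreshFrac * max(dens)] <- 0L
  region
}

# Grid cell of each point (row/col indices into the density grid).
.gridIndex <- function(points, gx, gy) {
  ix <- pmin(pmax(findInterval(points[, 1L], gx), 1L), length(gx))
  iy <- pmin(pmax(findInterval(points[, 2L], gy), 1L), length(gy))
  cbind(ix, iy)
}

# Region of each point; points on region-0 cells take the nearest labeled
# cell.
.pointRegions <- function(points, regionGrid, gx, gy) {
  idx <- .gridIndex(points, gx, gy)
  reg <- regionGrid[idx]
  miss <- which(reg == 0L)
  if (length(miss)) {
    lab <- which(regionGrid > 0L, arr.ind = TRUE)
    for (i in miss) {
      d2 <- (lab[, 1L] - idx[i, 1L])^2 + (lab[, 2L] - idx[i, 2L])^2
      reg[i] <- regionGrid[lab[which.min(d2), , drop = FALSE]]
    }
  }
  reg
}

#' Annotate motif regions with majority manual labels
#'
#' @param region integer region id per point.
#' @param labels integer behavior codes per point.
#' @param nRegions total number of regions.
#' @return data.frame \code{region_id, n_points, majority_label,
#'   majority_name, fraction}; empty regions are labeled none (0), ties go
#'   to the more prominent behavior.
#' @export
labelRegions <- function(region, labels, nRegions = max(region)) {
  out <- data.frame(region_id = seq_len(nRegions), n_points = 0L,
                    majority_label = 0L, majority_name = "none",
                    fraction = NA_real_)
  for (r in seq_len(nRegions)) {
    lb <- labels[region == r & !is.na(labels)]
    out$n_points[r] <- length(lb)
    if (!length(lb)) next
    cnt <- table(lb)
    codes <- as.integer(names(cnt))
    ord <- order(-as.integer(cnt), -prominenceOf(codes))
    out$majority_label[r] <- codes[ord[1L]]
    out$majority_name[r] <- behaviorName(codes[ord[1L]])
    out$fraction[r] <- as.integer(cnt[ord[1L]]) / length(lb)
  }
  out
}

#' Build the behavioral motif map from encoded windows
#'
#' PCA-reduces the Fisher vectors (keeping \code{pcaVar} of the variance),
#' embeds them with exact t-SNE, computes the kernel density map, segments
#' it into motif regions by watershed, and annotates each region with the
#' majority manual label.
#'
#' @param fw a \code{\link{FisherWindows-class}} object (labels used when
#'   present).
#' @param perplexity,seed,maxIter see \code{\link{embedTsne}}.
#' @param sigmaFrac,gridN,pad see \code{\link{densityMap}}.
#' @param peakThreshFrac,dilatePx see \code{\link{segmentDensity}}.
#' @param pcaVar variance fraction kept by the PCA.
#' @return a \code{\link{MotifMap-class}} object.
#' @export
buildMotifMap <- function(fw, perplexity = 16, sigmaFrac = 1 / 40,
                          gridN = 501L, pad = 0.1, peakThreshFrac = 0.01,
                          dilatePx = 3L, pcaVar = 0.9, seed = 1L,
                          maxIter = 1000L) {
  stopifnot(is(fw, "FisherWindows"))
  X <- fisherMatrix(fw)
  ctr <- colMeans(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  cums <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  qd <- max(which(cums >= pcaVar)[1L], 2L)
  basis <- pc$rotation[, seq_len(qd), drop = FALSE]
  Z <- sweep(X, 2L, ctr) %*% basis
  em <- embedTsne(Z, perplexity = perplexity, seed = seed,
                  maxIter = maxIter)
  dm <- densityMap(em$Y, sigmaFrac = sigmaFrac, gridN = gridN, pad = pad)
  region <- segmentDensity(dm$density, peakThreshFrac = peakThreshFrac,
                           dilatePx = dilatePx)
  labels <- windowInfo(fw)$label
  ptReg <- .pointRegions(em$Y, region, dm$gx, dm$gy)
  tab <- labelRegions(ptReg, labels, nRegions = max(region))
  new("MotifMap", points = em$Y, labels = as.integer(labels), trainX = Z,
      pcaCenter = ctr, pcaBasis = basis, perplexity = perplexity,
      klTrace = em$klTrace, density = dm$density, gridX = dm$gx,
      gridY = dm$gy, sigma = dm$sigma, sigmaFrac = sigmaFrac,
      regionGrid = region, regionTable = tab)
}

# KL mismatch of one new point against the frozen embedding.
.oosObjective <- function(y, trainY, pcond) {
  w <- 1 / (1 + rowSums(sweep(trainY, 2L, y)^2))
  q <- pmax(w / sum(w), 1e-12)
  sum(pcond * log(pcond / q))
}

#' Embed new windows into a frozen motif map
#'
#' Each new window is PCA-reduced with the training projection, its
#' perplexity-calibrated conditional probabilities to the training points
#' are computed, and its 2-D position is found by minimizing the KL
#' mismatch to the fixed training embedding (training points frozen).
#' The optimization is restarted from several deterministic initial
#' positions — the coordinates of the highest-probability training
#' neighbors and the probability-weighted mean — and the lowest-KL
#' solution is kept, since the weighted mean alone can fall between
#' clusters and strand the optimizer in the wrong basin. Region ids are
#' looked up from the watershed segmentation.
#'
#' @param map a \code{\link{MotifMap-class}}.
#' @param fw new windows as a \code{\link{FisherWindows-class}}.
#' @return data.frame with \code{x}, \code{y}, \code{region},
#'   \code{region_label} (the region's majority behavior code).
#' @export
embedNew <- function(map, fw) {
  X <- fisherMatrix(fw)
  Z <- sweep(X, 2L, map@pcaCenter) %*% map@pcaBasis
  n <- nrow(Z)
  Y <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    d2 <- as.vector(.pairwiseD2(Z[i, , drop = FALSE], map@trainX))
    p <- pmax(.condP(d2, map@perplexity), 1e-12)
    p <- p / sum(p)
    inits <- rbind(map@points[order(-p)[1:3], , drop = FALSE],
                   colSums(map@points * p))
    best <- NULL
    for (k in seq_len(nrow(inits))) {
      opt <- optim(par = inits[k, ], fn = .oosObjective,
                   trainY = map@points, pcond = p,
                   method = "Nelder-Mead",
                   control = list(maxit = 300L, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    Y[i, ] <- best$par
  }
  reg <- .pointRegions(Y, map@regionGrid, map@gridX, map@gridY)
  data.frame(x = Y[, 1L], y = Y[, 2L], region = reg,
             region_label = map@regionTable$majority_label[reg])
}
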