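# Internal image primitives. Frames are plain numeric matrices; index 1 is
# the x coordinate, index 2 the y coordinate.

gaussianKernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicated borders.
blurGaussian <- function(img, sigma, radius = ceiling(3 * sigma)) {
  k <- gaussianKernel1d(sigma, radius)
  kern <- outer(k, k)
  as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
}

# Shift a matrix by (di, dj), replicating border values.
shiftMatrix <- function(img, di, dj) {
  n <- nrow(img); m <- ncol(img)
  ri <- pmin(pmax(seq_len(n) - di, 1L), n)
  rj <- pmin(pmax(seq_len(m) - dj, 1L), m)
  img[ri, rj, drop = FALSE]
}

# Small separable convolution by direct shifts (replicated borders);
# cheaper than FFT filtering for 3-tap kernels.
convSep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  out <- img * 0
  for (i in seq_along(k)) out <- out + k[i] * shiftMatrix(img, i - r - 1L, 0L)
  img2 <- out; out <- img * 0
  for (i in seq_along(k)) out <- out + k[i] * shiftMatrix(img2, 0L, i - r - 1L)
  out
}

med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

# 3x3 median filter (compiled).
medianFilter3 <- function(img) median3_c(img)

# Summed-area table with a leading zero row/column (compiled).
integralImage <- function(img) integral_c(img)

# Box filter: sum over a (2r+1)^2 neighborhood, truncated at borders
# (compiled).
boxFilter <- function(img, r) box_filter_c(img, as.integer(r))

# Sum of img over rectangles [x0, x1] x [y0, y1] (1-based, inclusive),
# vectorized over rectangles. Coordinates must be pre-clipped to the image.
patchSums <- function(ii, x0, x1, y0, y1) {
  n <- nrow(ii)
  at <- function(i, j) ii[i + (j - 1L) * n]
  at(x1 + 1L, y1 + 1L) - at(x0, y1 + 1L) - at(x1 + 1L, y0) + at(x0, y0)
}

# Bilinear interpolation of img at (x, y), clamped to the image domain.
bilinearSample <- function(img, x, y) {
  n <- nrow(img); m <- ncol(img)
  x <- pmin(pmax(x, 1), n); y <- pmin(pmax(y, 1), m)
  x0 <- pmin(floor(x), n - 1L); y0 <- pmin(floor(y), m - 1L)
  fx <- x - x0; fy <- y - y0
  at <- function(i, j) img[i + (j - 1L) * n]
  at(x0, y0) * (1 - fx) * (1 - fy) + at(x0 + 1L, y0) * fx * (1 - fy) +
    at(x0, y0 + 1L) * (1 - fx) * fy + at(x0 + 1L, y0 + 1L) * fx * fy
}

# Ellipse from second-order moments of a (possibly weighted) mask.
# Axes are full lengths (4 * sqrt(eigenvalue)); for a solid ellipse this
# recovers the true axis lengths. Orientation is the angle of the major
# axis to the +x axis, in degrees, mapped to (-90, 90].
momentEllipse <- function(w) {
  tot <- sum(w)
  if (tot <= 0) stop("momentEllipse: empty region")
  nx <- nrow(w); ny <- ncol(w)
  xs <- seq_len(nx); ys <- seq_len(ny)
  rx <- rowSums(w); cy <- colSums(w)
  cx0 <- sum(xs * rx) / tot
  cy0 <- sum(ys * cy) / tot
  dx <- xs - cx0; dy <- ys - cy0
  mxx <- sum(dx^2 * rx) / tot
  myy <- sum(dy^2 * cy) / tot
  mxy <- sum((dx * w) %*% dy) / tot
  tr <- mxx + myy
  dt <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr / 2 + dt
  l2 <- max(tr / 2 - dt, 0)
  ang <- if (abs(mxy) < 1e-12 && mxx >= myy) 0 else
    atan2(l1 - mxx, mxy) * 180 / pi
  # atan2 form: eigenvector of l1 is (mxy, l1 - mxx) unless degenerate
  if (abs(mxy) < 1e-12 && myy > mxx) ang <- 90
  ang <- ((ang + 90) %% 180) - 90
  if (ang <= -90) ang <- ang + 180
  list(cx = cx0, cy = cy0, major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       angle = ang)
}

l2normalize <- function(z) {
  nz <- sqrt(sum(z^2))
  if (nz == 0) z else z / nz
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Wrap angle (degrees) into (-90, 90].
wrapOrientation <- function(a) {
  a <- ((a + 90) %% 180) - 90
  a[a <= -90] <- a[a <= -90] + 180
  a
}
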