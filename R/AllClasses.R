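#' @import methods
#' @importFrom stats approx dnorm kmeans mad median optim prcomp quantile
#'   rnorm runif sd var predict
#' @importFrom utils head read.csv write.csv tail
NULL

#' VideoClip: an ordered stack of grayscale frames
#'
#' The unit of all per-window computation. Frames are stored as a numeric
#' array of dimension \code{c(nx, ny, nFrames)} with intensities in
#' \code{[0, 1]}; the first array index is the x coordinate, the second the
#' y coordinate (the convention used throughout the package).
#'
#' @slot frames numeric array \code{nx x ny x nFrames}.
#' @slot frameRate frames per second.
#' @slot meta list of provenance information (free form).
#' @export
setClass("VideoClip",
  representation(frames = "array", frameRate = "numeric", meta = "list"),
  prototype(frameRate = 5, meta = list()))

setValidity("VideoClip", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a 3-D array (nx, ny, nFrames)")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' RegisteredWindow: one behavior element in canonical coordinates
#'
#' A fixed-length window of frames after centering, rotation and scaling to
#' the canonical pose (body axis along +y with the head at larger y, body
#' length 100 px, 300 x 300 output), together with the similarity transform
#' that produced it and the three body-part masks in canonical coordinates.
#'
#' @slot frames numeric array, canonical frames.
#' @slot transform list with elements \code{scale}, \code{angle} (degrees),
#'   \code{center} (source centroid) and \code{flip}.
#' @slot parts list of three logical matrices named \code{tentacle},
#'   \code{upper}, \code{lower}.
#' @slot windowId integer window index within the source clip.
#' @export
setClass("RegisteredWindow",
  representation(frames = "array", transform = "list", parts = "list",
                 windowId = "integer"))

setValidity("RegisteredWindow", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a 3-D array")
  if (!all(c("tentacle", "upper", "lower") %in% names(object@parts)))
    msg <- c(msg, "'parts' must contain tentacle, upper and lower masks")
  if (is.null(msg)) TRUE else msg
})

#' TrajectorySet: tracked interest points with descriptors
#'
#' Dense-trajectory output for one registered window: per-trajectory point
#' tracks, body-part assignment, and the four descriptor histograms.
#'
#' @slot x,y numeric matrices (nTraj x span) of point coordinates per frame.
#' @slot startFrame integer vector, first frame of each track.
#' @slot part factor with levels tentacle/upper/lower.
#' @slot descriptors named list of matrices \code{hof} (nTraj x 9),
#'   \code{hog}, \code{mbhx}, \code{mbhy} (nTraj x 8).
#' @export
setClass("TrajectorySet",
  representation(x = "matrix", y = "matrix", startFrame = "integer",
                 part = "factor", descriptors = "list"))

setValidity("TrajectorySet", function(object) {
  n <- nrow(object@x)
  msg <- NULL
  if (nrow(object@y) != n || length(object@part) != n)
    msg <- c(msg, "trajectory slots disagree in length")
  dd <- descriptorDims()
  for (ty in names(dd)) {
    m <- object@descriptors[[ty]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != dd[[ty]])
      msg <- c(msg, sprintf("descriptor '%s' must be %d x %d", ty, n, dd[[ty]]))
  }
  if (is.null(msg)) TRUE else msg
})

#' GmmCodebook: PCA/whitening transform plus diagonal Gaussian mixture
#'
#' One codebook per descriptor type. Descriptors are centered per body part,
#' projected by a shared PCA keeping ceiling(D/2) components, whitened by
#' 1/sqrt(eigenvalue), and modeled by a K-component diagonal-covariance
#' Gaussian mixture.
#'
#' @slot descType one of "hof", "hog", "mbhx", "mbhy".
#' @slot partMeans named list of per-part centering vectors.
#' @slot pcaBasis D x q projection matrix (columns = components).
#' @slot eigenvalues variances of the q retained components.
#' @slot weights,means,variances mixture parameters; \code{means} and
#'   \code{variances} are K x q matrices.
#' @export
setClass("GmmCodebook",
  representation(descType = "character", partMeans = "list",
                 pcaBasis = "matrix", eigenvalues = "numeric",
                 weights = "numeric", means = "matrix", variances = "matrix"))

setValidity("GmmCodebook", function(object) {
  msg <- NULL
  if (abs(sum(object@weights) - 1) > 1e-6 || any(object@weights <= 0))
    msg <- c(msg, "mixture weights must be positive and sum to 1")
  if (any(object@variances <= 0))
    msg <- c(msg, "mixture variances must be positive")
  if (nrow(object@means) != length(object@weights) ||
      !all(dim(object@means) == dim(object@variances)))
    msg <- c(msg, "means/variances/weights dimensions disagree")
  if (ncol(object@pcaBasis) != ncol(object@means))
    msg <- c(msg, "PCA output dimension must match mixture dimension")
  if (is.null(msg)) TRUE else msg
})

#' FisherWindows: encoded behavior elements
#'
#' One row per window: the concatenated power- and l2-normalized Fisher
#' vector over 3 body parts x 4 descriptor types, plus window metadata and
#' the block index map locating each (part, type) slice of the vector.
#'
#' @slot vectors numeric matrix (nWindows x D).
#' @slot info data.frame with columns \code{window_id}, \code{t_start_s} and
#'   \code{label} (integer behavior code, NA when unlabeled).
#' @slot blockMap data.frame with columns \code{part}, \code{type},
#'   \code{start}, \code{end} (1-based, inclusive).
#' @slot frameRate,windowFrames acquisition metadata.
#' @export
setClass("FisherWindows",
  representation(vectors = "matrix", info = "data.frame",
                 blockMap = "data.frame", frameRate = "numeric",
                 windowFrames = "integer"))

setValidity("FisherWindows", function(object) {
  msg <- NULL
  if (nrow(object@vectors) != nrow(object@info))
    msg <- c(msg, "'vectors' and 'info' must have one row per window")
  if (nrow(object@blockMap) &&
      max(object@blockMap$end) != ncol(object@vectors))
    msg <- c(msg, "block map does not span the vector length")
  if (is.null(msg)) TRUE else msg
})

#' BehaviorModel: trained multi-class behavior classifier
#'
#' PCA projection (retaining 90\% of training variance) followed by a
#' class-weighted RBF-kernel SVM with probability estimates; the cost and
#' kernel-width pair is selected by cross-validated grid search.
#'
#' @slot pcaCenter,pcaBasis training PCA (applied to new data unchanged).
#' @slot svm fitted e1071 svm object.
#' @slot classes integer behavior codes in training order.
#' @slot classWeights numeric, w_i = sum(N) / N_i.
#' @slot bestCost,bestGamma selected grid point.
#' @slot cvAccuracy cross-validated accuracy at the selected grid point.
#' @slot cvTable full grid-search table.
#' @export
setClass("BehaviorModel",
  representation(pcaCenter = "numeric", pcaBasis = "matrix", svm = "ANY",
                 classes = "integer", classWeights = "numeric",
                 bestCost = "numeric", bestGamma = "numeric",
                 cvAccuracy = "numeric", cvTable = "data.frame"))

#' Ethogram: per-window behavior labels over time
#'
#' Hard predictions fill only \code{label1}; the soft rule can add up to two
#' more labels with non-increasing probabilities.
#'
#' @slot table data.frame with columns \code{window_id}, \code{t_start_s},
#'   \code{label1..3}, \code{prob1..3}.
#' @slot frameRate,windowFrames acquisition metadata.
#' @export
setClass("Ethogram",
  representation(table = "data.frame", frameRate = "numeric",
                 windowFrames = "integer"))

setValidity("Ethogram", function(object) {
  tb <- object@table
  need <- c("window_id", "t_start_s", "label1", "prob1", "label2", "prob2",
            "label3", "prob3")
  if (!all(need %in% names(tb))) return("ethogram table misses columns")
  p <- as.matrix(tb[, c("prob1", "prob2", "prob3")])
  bad <- apply(p, 1L, function(z) {
    z <- z[!is.na(z)]
    length(z) > 1L && any(diff(z) > 1e-9)
  })
  if (any(bad)) return("probabilities must be non-increasing")
  TRUE
})

#' MotifMap: unsupervised behavioral space
#'
#' t-SNE embedding of encoded windows, the Gaussian-kernel density over a
#' square grid, the watershed region labels, and the per-region majority
#' behavior annotation. Training inputs are retained so new windows can be
#' embedded against the frozen map.
#'
#' @slot points n x 2 embedded coordinates of the training windows.
#' @slot labels integer behavior codes of the training windows (NA allowed).
#' @slot trainX the (reduced) feature matrix the embedding was fit on.
#' @slot pcaCenter,pcaBasis the dimension reduction applied to Fisher
#'   vectors before embedding (reused for new windows).
#' @slot perplexity,sigmaFrac,sigma embedding / density parameters.
#' @slot klTrace logged KL divergence over the optimization.
#' @slot density,gridX,gridY density grid and its axes.
#' @slot regionGrid integer matrix of watershed region ids (0 = outside the
#'   density support).
#' @slot regionTable per-region summary (n points, majority label, fraction).
#' @export
setClass("MotifMap",
  representation(points = "matrix", labels = "integer", trainX = "matrix",
                 pcaCenter = "numeric", pcaBasis = "matrix",
                 perplexity = "numeric", klTrace = "numeric",
                 density = "matrix", gridX = "numeric", gridY = "numeric",
                 sigma = "numeric", sigmaFrac = "numeric",
                 regionGrid = "matrix", regionTable = "data.frame"))

setValidity("MotifMap", function(object) {
  msg <- NULL
  if (ncol(object@points) != 2L)
    msg <- c(msg, "'points' must be n x 2")
  if (nrow(object@points) != nrow(object@trainX) ||
      nrow(object@points) != length(object@labels))
    msg <- c(msg, "points/labels/trainX disagree in length")
  if (is.null(msg)) TRUE else msg
})
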