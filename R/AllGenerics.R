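#' @describeIn VideoClip-class number of frames
#' @param x,object a \code{VideoClip}
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @export
setGeneric("fisherMatrix", function(x) standardGeneric("fisherMatrix"))

#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

#' @export
setGeneric("blockMap", function(x) standardGeneric("blockMap"))

#' @export
setGeneric("bodyParts", function(x) standardGeneric("bodyParts"))

#' @export
setGeneric("embeddedPoints", function(x) standardGeneric("embeddedPoints"))

#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @export
setGeneric("ethogramTable", function(x) standardGeneric("ethogramTable"))

setMethod("nFrames", "VideoClip", function(x) dim(x@frames)[3L])
setMethod("frames", "VideoClip", function(x) x@frames)
setMethod("frameRate", "VideoClip", function(x) x@frameRate)
setMethod("frames", "RegisteredWindow", function(x) x@frames)
setMethod("bodyParts", "RegisteredWindow", function(x) x@parts)
setMethod("fisherMatrix", "FisherWindows", function(x) x@vectors)
setMethod("windowInfo", "FisherWindows", function(x) x@info)
setMethod("blockMap", "FisherWindows", function(x) x@blockMap)
setMethod("frameRate", "FisherWindows", function(x) x@frameRate)
setMethod("embeddedPoints", "MotifMap", function(x) x@points)
setMethod("regionTable", "MotifMap", function(x) x@regionTable)
setMethod("ethogramTable", "Ethogram", function(x) x@table)
setMethod("frameRate", "Ethogram", function(x) x@frameRate)

setMethod("length", "TrajectorySet", function(x) nrow(x@x))

setMethod("show", "VideoClip", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoClip: %d frames of %d x %d px at %g Hz (%.1f s)\n",
              d[3L], d[1L], d[2L], object@frameRate,
              d[3L] / object@frameRate))
})

setMethod("show", "RegisteredWindow", function(object) {
  d <- dim(object@frames)
  cat(sprintf("RegisteredWindow %d: %d canonical frames (%d x %d px)\n",
              object@windowId, d[3L], d[1L], d[2L]))
  cat(sprintf("  scale %.3f, rotation %.1f deg\n",
              object@transform$scale, object@transform$angle))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d trajectories of %d frames\n",
              nrow(object@x), ncol(object@x)))
  if (nrow(object@x)) print(table(object@part))
})

setMethod("show", "GmmCodebook", function(object) {
  cat(sprintf("GmmCodebook [%s]: %d -> %d dims (whitened), K = %d\n",
              object@descType, nrow(object@pcaBasis),
              ncol(object@pcaBasis), length(object@weights)))
})

setMethod("show", "FisherWindows", function(object) {
  cat(sprintf("FisherWindows: %d windows x %d dims (%d blocks)\n",
              nrow(object@vectors), ncol(object@vectors),
              nrow(object@blockMap)))
  lb <- object@info$label
  if (any(!is.na(lb)))
    cat("  labels:", paste(names(table(lb)), table(lb), sep = ":",
                           collapse = " "), "\n")
})

setMethod("show", "BehaviorModel", function(object) {
  cat(sprintf("BehaviorModel: %d classes, RBF SVM (C = %g, gamma = %g)\n",
              length(object@classes), object@bestCost, object@bestGamma))
  cat(sprintf("  cross-validated accuracy %.3f\n", object@cvAccuracy))
})

setMethod("show", "Ethogram", function(object) {
  cat(sprintf("Ethogram: %d windows (%g s each)\n", nrow(object@table),
              object@windowFrames / object@frameRate))
})

setMethod("show", "MotifMap", function(object) {
  cat(sprintf("MotifMap: %d embedded windows, %d regions (sigma = %.3g)\n",
              nrow(object@points), nrow(object@regionTable), object@sigma))
})
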