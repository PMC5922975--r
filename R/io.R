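# Serialization of module outputs to portable text formats.

#' Read and write ground-truth sidecars (JSON)
#'
#' @param truth the \code{truth} element of \code{\link{makeBehaviorClip}}
#'   (per-frame labels, ellipse track, egestion times).
#' @param path JSON path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(per_frame_label = truth$per_frame_label,
                            ellipse_track = truth$ellipse_track,
                            egestion_times = truth$egestion_times),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_frame_label <- as.character(x$per_frame_label)
  x$egestion_times <- as.integer(x$egestion_times)
  x
}

#' Read and write a Gaussian-mixture codebook (versioned JSON)
#'
#' The whole codebook — per-part centering, PCA basis, eigenvalues and
#' mixture parameters — as one JSON document with a format version tag.
#'
#' @param cb a \code{\link{GmmCodebook-class}} object.
#' @param path JSON path.
#' @export
writeCodebook <- function(cb, path) {
  stopifnot(is(cb, "GmmCodebook"))
  jsonlite::write_json(list(
    format = "hydrabow-codebook", version = 1L,
    descType = cb@descType, partMeans = cb@partMeans,
    pcaBasis = cb@pcaBasis, eigenvalues = cb@eigenvalues,
    weights = cb@weights, means = cb@means, variances = cb@variances),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "hydrabow-codebook"))
    stop("not a hydrabow codebook file: ", path, call. = FALSE)
  new("GmmCodebook", descType = x$descType,
      partMeans = lapply(x$partMeans, as.numeric),
      pcaBasis = as.matrix(x$pcaBasis), eigenvalues = x$eigenvalues,
      weights = x$weights, means = as.matrix(x$means),
      variances = as.matrix(x$variances))
}

#' Write encoded windows as a dense matrix plus index CSV
#'
#' \code{<prefix>_matrix.csv} holds the Fisher-vector matrix (no header,
#' one window per row); \code{<prefix>_windows.csv} the window metadata;
#' \code{<prefix>_blocks.csv} the block index map.
#'
#' @param fw a \code{\link{FisherWindows-class}} object.
#' @param prefix output path prefix.
#' @export
writeFisherWindows <- function(fw, prefix) {
  stopifnot(is(fw, "FisherWindows"))
  write.table(fisherMatrix(fw), paste0(prefix, "_matrix.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  write.csv(windowInfo(fw), paste0(prefix, "_windows.csv"),
            row.names = FALSE)
  write.csv(blockMap(fw), paste0(prefix, "_blocks.csv"),
            row.names = FALSE)
  invisible(prefix)
}

#' Write a motif map as portable artifacts
#'
#' Embedded points (with labels and region ids) and the region report as
#' CSV, the density grid as a dense CSV matrix, and the watershed region
#' grid as a gray-coded PNG.
#'
#' @param map a \code{\link{MotifMap-class}} object.
#' @param dir output directory.
#' @export
writeMotifMap <- function(map, dir) {
  stopifnot(is(map, "MotifMap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- .pointRegions(map@points, map@regionGrid, map@gridX, map@gridY)
  write.csv(data.frame(x = map@points[, 1L], y = map@points[, 2L],
                       label = map@labels, region = reg),
            file.path(dir, "points.csv"), row.names = FALSE)
  write.csv(regionTable(map), file.path(dir, "regions.csv"),
            row.names = FALSE)
  write.table(map@density, file.path(dir, "density.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  png::writePNG(t(map@regionGrid / max(1L, max(map@regionGrid))),
                file.path(dir, "region_grid.png"))
  invisible(dir)
}
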