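# Egestion (rapid radial contraction) detection from body-width dynamics.

#' Body-width time series from per-frame geometry
#'
#' The minor-axis length per frame; missing frames are linearly
#' interpolated and flagged.
#'
#' @param geometry data.frame from \code{\link{analyzeClip}} (columns
#'   \code{frame}, \code{minor}).
#' @param frameRate frames per second.
#' @return list with \code{width} (numeric), \code{frameRate},
#'   \code{interpolated} (logical flags).
#' @export
widthTrace <- function(geometry, frameRate = 5) {
  w <- geometry$minor
  if (all(is.na(w))) stop("no width measurements available", call. = FALSE)
  interp <- is.na(w)
  if (any(interp)) {
    w <- approx(which(!interp), w[!interp], xout = seq_along(w),
                rule = 2)$y
  }
  list(width = w, frameRate = frameRate, interpolated = interp)
}

#' Before-minus-after mean filter of a width trace
#'
#' The value at time t is the mean width over the half-window before t
#' minus the mean width over the half-window after t (15 min halves by
#' default), so a sharp width decrease produces a positive peak at the
#' drop. Windows are truncated at the trace ends.
#'
#' @param width numeric width series (px).
#' @param frameRate frames per second.
#' @param halfWindowMin half-window length in minutes.
#' @return filtered numeric series of the same length.
#' @export
filterWidth <- function(width, frameRate = 5, halfWindowMin = 15) {
  n <- length(width)
  h <- max(1L, round(halfWindowMin * 60 * frameRate))
  if (n <= h) stop("trace shorter than one half-window", call. = FALSE)
  cs <- c(0, cumsum(width))
  idx <- seq_len(n)
  b0 <- pmax(idx - h, 1L); b1 <- idx - 1L
  a0 <- idx; a1 <- pmin(idx + h - 1L, n)
  before <- ifelse(b1 >= b0, (cs[b1 + 1L] - cs[b0]) / (b1 - b0 + 1L), NA)
  after <- (cs[a1 + 1L] - cs[a0]) / (a1 - a0 + 1L)
  out <- before - after
  out[1L] <- 0  # no before-window at the first sample
  out
}

# Topographic prominence of local maxima in a series.
.peakProminence <- function(x, peaks) {
  vapply(peaks, function(p) {
    higherL <- which(x[seq_len(p - 1L)] > x[p])
    lo <- if (length(higherL)) max(higherL) + 1L else 1L
    minL <- min(x[lo:p])
    higherR <- which(x[seq(p + 1L, length(x))] > x[p]) + p
    hi <- if (length(higherR)) min(higherR) - 1L else length(x)
    minR <- min(x[p:hi])
    x[p] - max(minL, minR)
  }, numeric(1L))
}

#' Detect egestion events on a filtered width trace
#'
#' Local maxima with topographic prominence at least \code{minProminence}
#' are reported as egestion events; events closer than the filter
#' half-window keep only the higher peak. The default threshold is 50
#' times the median absolute deviation of the filtered trace: the trace is
#' smooth at the half-window scale, so chance peak-to-trough excursions
#' reach an order of magnitude above the per-sample MAD, while genuine
#' egestion drops produce peaks another order above that (of the size of
#' the width drop itself).
#'
#' @param filtered filtered series from \code{\link{filterWidth}}.
#' @param frameRate frames per second.
#' @param halfWindowMin filter half-window (sets the minimum separation).
#' @param minProminence prominence threshold in px; NULL for the robust
#'   default.
#' @return data.frame \code{frame, time_s, height_px, edge_flag}.
#' @export
detectEgestion <- function(filtered, frameRate = 5, halfWindowMin = 15,
                           minProminence = NULL) {
  n <- length(filtered)
  h <- max(1L, round(halfWindowMin * 60 * frameRate))
  if (is.null(minProminence))
    minProminence <- 50 * mad(filtered, na.rm = TRUE)
  if (minProminence <= 0) minProminence <- 1e-6
  isPk <- which(filtered > c(-Inf, filtered[-n]) &
                filtered >= c(filtered[-1L], -Inf))
  isPk <- isPk[isPk > 1L & isPk < n]
  if (!length(isPk))
    return(data.frame(frame = integer(0), time_s = numeric(0),
                      height_px = numeric(0), edge_flag = logical(0)))
  # enforce minimum separation first (keeping higher peaks), so the O(n)
  # prominence computation only runs for the few surviving candidates;
  # a block-max prefilter keeps one candidate per half-window
  blk <- (isPk - 1L) %/% max(h %/% 2L, 1L)
  best <- tapply(seq_along(isPk), blk, function(ii)
    ii[which.max(filtered[isPk[ii]])])
  isPk <- isPk[as.integer(best)]
  ord <- isPk[order(-filtered[isPk])]
  taken <- integer(0)
  for (p in ord)
    if (!length(taken) || all(abs(p - taken) >= h)) taken <- c(taken, p)
  keep <- sort(taken)
  prom <- .peakProminence(filtered, keep)
  # truncated windows at the trace ends average fewer samples, inflating
  # their noise by sqrt(h / windowLength); scale the threshold to match
  shortWin <- pmax(pmin(pmin(keep - 1L, h), pmin(n - keep, h)), 1L)
  infl <- sqrt(h / shortWin)
  keep <- keep[prom >= minProminence * infl]
  data.frame(frame = keep, time_s = (keep - 1L) / frameRate,
             height_px = filtered[keep],
             edge_flag = keep <= h | keep > n - h)
}
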