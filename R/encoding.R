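# Fisher-vector encoding over per-descriptor-type Gaussian-mixture
# codebooks. Descriptors are centered per body part, reduced to half their
# dimension by a shared PCA, whitened, and modeled by a diagonal-covariance
# GMM; each window is the concatenation of power- and l2-normalized Fisher
# vectors over 3 body parts x 4 descriptor types.

.partLevels <- c("tentacle", "upper", "lower")

#' Fit the per-part centering + shared PCA/whitening transform
#'
#' Features from each body part are centered at zero separately; a single
#' PCA is then fitted on the pooled centered features, keeping
#' ceiling(D/2) components (5 for the 9-bin HOF, 4 for HOG/MBHx/MBHy), and
#' components are whitened by 1/sqrt(eigenvalue).
#'
#' @param X descriptor matrix (n x D).
#' @param part factor of part assignments (length n).
#' @return list with \code{partMeans}, \code{basis} (D x q),
#'   \code{eigenvalues} (length q).
#' @export
fitPcaWhiten <- function(X, part) {
  D <- ncol(X)
  q <- ceiling(D / 2)
  if (nrow(X) < max(q, 2L)) stop("fewer samples than output dimensions")
  part <- factor(part, levels = .partLevels)
  partMeans <- lapply(.partLevels, function(p) {
    rows <- which(part == p)
    if (length(rows)) colMeans(X[rows, , drop = FALSE]) else numeric(D)
  })
  names(partMeans) <- .partLevels
  Xc <- X
  for (p in .partLevels) {
    rows <- which(part == p)
    if (length(rows))
      Xc[rows, ] <- sweep(X[rows, , drop = FALSE], 2L, partMeans[[p]])
  }
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
  lam <- pc$sdev[seq_len(q)]^2
  lam <- pmax(lam, 1e-12)
  list(partMeans = lapply(partMeans, unname),
       basis = unname(pc$rotation[, seq_len(q), drop = FALSE]),
       eigenvalues = unname(lam))
}

#' Apply a fitted centering + PCA/whitening transform
#'
#' @param trans transform from \code{\link{fitPcaWhiten}} (or a
#'   \code{GmmCodebook}).
#' @param X descriptor matrix.
#' @param part factor of part assignments.
#' @return whitened matrix (n x q).
#' @export
applyPcaWhiten <- function(trans, X, part) {
  if (is(trans, "GmmCodebook"))
    trans <- list(partMeans = trans@partMeans, basis = trans@pcaBasis,
                  eigenvalues = trans@eigenvalues)
  part <- factor(part, levels = .partLevels)
  Xc <- X
  for (p in .partLevels) {
    rows <- which(part == p)
    if (length(rows))
      Xc[rows, ] <- sweep(X[rows, , drop = FALSE], 2L, trans$partMeans[[p]])
  }
  sweep(Xc %*% trans$basis, 2L, sqrt(trans$eigenvalues), "/")
}

# Log density of each point under each diagonal Gaussian component.
.logCompDens <- function(X, means, vars) {
  n <- nrow(X); K <- nrow(means); q <- ncol(X)
  out <- matrix(0, n, K)
  for (i in seq_len(K)) {
    d <- sweep(X, 2L, means[i, ])
    out[, i] <- -0.5 * (q * log(2 * pi) + sum(log(vars[i, ])) +
                        rowSums(sweep(d^2, 2L, vars[i, ], "/")))
  }
  out
}

#' Fit a diagonal-covariance Gaussian-mixture codebook by EM
#'
#' A seeded random subset of at most \code{nSubset} whitened descriptors is
#' fitted with K diagonal Gaussians. Initialization is by seeded k-means;
#' responsibilities are computed in log space; vanishing variances are
#' floored.
#'
#' @param X whitened descriptor matrix.
#' @param K number of mixture components (the codebook size; 128 by
#'   default, 256 also supported).
#' @param nSubset maximum number of points used for fitting.
#' @param seed integer seed for subset and initialization.
#' @param maxIter,tol EM stopping rule (relative log-likelihood change).
#' @param varFloor lower bound applied to component variances.
#' @return list with \code{weights}, \code{means}, \code{variances},
#'   \code{logLik} (trace).
#' @export
fitGmm <- function(X, K = 128L, nSubset = 256000L, seed = 1L,
                   maxIter = 100L, tol = 1e-6, varFloor = 1e-4) {
  stopifnot(K >= 1L, nrow(X) >= K)
  withSeed(seed, {
    if (nrow(X) > nSubset) X <- X[sample.int(nrow(X), nSubset), , drop = FALSE]
    n <- nrow(X); q <- ncol(X)
    if (K == 1L) {
      mu <- matrix(colMeans(X), 1L)
      v <- matrix(pmax(apply(X, 2L, var) * (n - 1) / n, varFloor), 1L)
      return(list(weights = 1, means = mu, variances = v, logLik = numeric(0)))
    }
    km <- suppressWarnings(kmeans(X, centers = K, nstart = 3L,
                                  iter.max = 30L))
    means <- km$centers
    counts <- tabulate(km$cluster, K)
    weights <- pmax(counts, 1) / sum(pmax(counts, 1))
    globalVar <- apply(X, 2L, var)
    vars <- matrix(0, K, q)
    for (i in seq_len(K)) {
      rows <- which(km$cluster == i)
      vars[i, ] <- if (length(rows) > 1L)
        pmax(apply(X[rows, , drop = FALSE], 2L, var), varFloor)
      else pmax(globalVar, varFloor)
    }
    ll <- -Inf; trace <- numeric(0)
    for (it in seq_len(maxIter)) {
      lp <- sweep(.logCompDens(X, means, vars), 2L, log(weights), "+")
      mx <- do.call(pmax, as.data.frame(lp))
      lse <- mx + log(rowSums(exp(lp - mx)))
      newLL <- sum(lse)
      resp <- exp(lp - lse)
      Nk <- colSums(resp)
      degenerate <- Nk < 1e-8
      if (any(degenerate)) Nk[degenerate] <- 1e-8
      weights <- Nk / sum(Nk)
      means <- t(resp) %*% X / Nk
      Ex2 <- t(resp) %*% X^2 / Nk
      vars <- pmax(Ex2 - means^2, varFloor)
      trace <- c(trace, newLL)
      if (is.finite(ll) && abs(newLL - ll) < tol * abs(newLL)) break
      ll <- newLL
    }
    list(weights = as.numeric(weights), means = unname(means),
         variances = unname(vars), logLik = trace)
  })
}

#' Fit the full codebook (PCA/whitening + GMM) for one descriptor type
#'
#' @param X raw descriptor matrix for one type.
#' @param part part assignment factor.
#' @param type descriptor type name.
#' @inheritParams fitGmm
#' @return a \code{\link{GmmCodebook-class}} object.
#' @export
fitCodebook <- function(X, part, type, K = 128L, nSubset = 256000L,
                        seed = 1L) {
  trans <- fitPcaWhiten(X, part)
  W <- applyPcaWhiten(trans, X, part)
  g <- fitGmm(W, K = K, nSubset = nSubset, seed = seed)
  new("GmmCodebook", descType = type, partMeans = trans$partMeans,
      pcaBasis = trans$basis, eigenvalues = trans$eigenvalues,
      weights = g$weights, means = g$means, variances = g$variances)
}

#' Fisher vector of a descriptor set under a GMM codebook
#'
#' The normalized gradient of the sample log-likelihood with respect to the
#' mixture means and standard deviations, with the closed-form diagonal
#' approximation of the Fisher information: per component i and dimension
#' d, G_mu = 1/(T sqrt(w_i)) sum_t gamma_t(i) (x_td - mu_id)/sigma_id and
#' G_sigma = 1/(T sqrt(2 w_i)) sum_t gamma_t(i) (((x_td - mu_id)/sigma_id)^2
#' - 1), where gamma are posterior responsibilities. Weight gradients are
#' omitted. Components with vanishing total responsibility contribute zero
#' blocks. The output layout is all mean gradients (component-major), then
#' all variance gradients.
#'
#' @param X whitened descriptor matrix (T x q).
#' @param gmm a \code{GmmCodebook} or a list with \code{weights},
#'   \code{means}, \code{variances}.
#' @return numeric vector of length 2 K q.
#' @export
fisherVector <- function(X, gmm) {
  if (is(gmm, "GmmCodebook"))
    gmm <- list(weights = gmm@weights, means = gmm@means,
                variances = gmm@variances)
  K <- length(gmm$weights); q <- ncol(gmm$means)
  if (ncol(X) != q) stop("descriptor dimension does not match codebook")
  Tn <- nrow(X)
  if (Tn == 0L) return(numeric(2L * K * q))
  lp <- sweep(.logCompDens(X, gmm$means, gmm$variances), 2L,
              log(gmm$weights), "+")
  mx <- do.call(pmax, as.data.frame(lp))
  resp <- exp(lp - (mx + log(rowSums(exp(lp - mx)))))
  sig <- sqrt(gmm$variances)
  Gmu <- matrix(0, K, q); Gsig <- matrix(0, K, q)
  Nk <- colSums(resp)
  for (i in seq_len(K)) {
    if (Nk[i] < 1e-10) next
    Z <- sweep(X, 2L, gmm$means[i, ])
    Z <- sweep(Z, 2L, sig[i, ], "/")
    Gmu[i, ] <- colSums(resp[, i] * Z) / (Tn * sqrt(gmm$weights[i]))
    Gsig[i, ] <- colSums(resp[, i] * (Z^2 - 1)) /
      (Tn * sqrt(2 * gmm$weights[i]))
  }
  c(t(Gmu), t(Gsig))
}

#' Power and l2 normalization of a Fisher vector
#'
#' f(z) = sign(z) |z|^alpha elementwise (alpha = 0.5 by default), followed
#' by division by the l2 norm; an all-zero vector stays all-zero.
#'
#' @param z numeric vector.
#' @param alpha power exponent in (0, 1].
#' @return normalized vector.
#' @export
normalizeFv <- function(z, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  z <- sign(z) * abs(z)^alpha
  l2normalize(z)
}

#' Fit codebooks for all four descriptor types
#'
#' Pools descriptors of every window per type and fits one
#' \code{GmmCodebook} each, with seeds derived from \code{seed}.
#'
#' @param trajSets list of \code{TrajectorySet} objects (training windows).
#' @inheritParams fitGmm
#' @return named list of four \code{GmmCodebook} objects.
#' @export
fitCodebooks <- function(trajSets, K = 128L, nSubset = 256000L, seed = 1L) {
  types <- names(descriptorDims())
  out <- vector("list", length(types)); names(out) <- types
  for (j in seq_along(types)) {
    ty <- types[[j]]
    X <- do.call(rbind, lapply(trajSets, function(ts) ts@descriptors[[ty]]))
    part <- factor(unlist(lapply(trajSets, function(ts)
      as.character(ts@part))), levels = .partLevels)
    out[[ty]] <- fitCodebook(X, part, ty, K = K, nSubset = nSubset,
                             seed = seed + j)
  }
  out
}

#' Encode windows as concatenated normalized Fisher vectors
#'
#' Per body part and descriptor type the whitened part descriptors are
#' Fisher-encoded and power+l2 normalized; blocks are concatenated in the
#' fixed order (tentacle, upper, lower) x (HOF, HOG, MBHx, MBHy) and the
#' concatenation is l2-normalized once more so every window has unit norm
#' (or is all-zero). Parts without trajectories contribute zero blocks.
#'
#' @param trajSets list of \code{TrajectorySet} objects, one per window.
#' @param codebooks list from \code{\link{fitCodebooks}}.
#' @param labels optional integer behavior codes per window.
#' @param frameRate,windowFrames acquisition metadata.
#' @param alpha power-normalization exponent.
#' @return a \code{\link{FisherWindows-class}} object.
#' @export
encodeWindows <- function(trajSets, codebooks, labels = NULL,
                          frameRate = 5, windowFrames = 25L, alpha = 0.5) {
  types <- names(descriptorDims())
  lens <- vapply(types, function(ty)
    2L * length(codebooks[[ty]]@weights) * ncol(codebooks[[ty]]@means), 1L)
  blockMap <- data.frame(part = rep(.partLevels, each = length(types)),
                         type = rep(types, times = 3L),
                         start = 0L, end = 0L)
  pos <- 1L
  for (r in seq_len(nrow(blockMap))) {
    ln <- lens[[blockMap$type[r]]]
    blockMap$start[r] <- pos
    blockMap$end[r] <- pos + ln - 1L
    pos <- pos + ln
  }
  D <- pos - 1L
  n <- length(trajSets)
  V <- matrix(0, n, D)
  for (w in seq_len(n)) {
    ts <- trajSets[[w]]
    vec <- numeric(D)
    for (r in seq_len(nrow(blockMap))) {
      p <- blockMap$part[r]; ty <- blockMap$type[r]
      rows <- which(ts@part == p)
      if (!length(rows)) next
      X <- ts@descriptors[[ty]][rows, , drop = FALSE]
      W <- applyPcaWhiten(codebooks[[ty]], X,
                          factor(rep(p, length(rows)), levels = .partLevels))
      z <- normalizeFv(fisherVector(W, codebooks[[ty]]), alpha)
      vec[blockMap$start[r]:blockMap$end[r]] <- z
    }
    V[w, ] <- l2normalize(vec)
  }
  info <- data.frame(window_id = seq_len(n),
                     t_start_s = (seq_len(n) - 1L) * windowFrames / frameRate,
                     label = if (is.null(labels)) NA_integer_
                             else as.integer(labels))
  new("FisherWindows", vectors = V, info = info, blockMap = blockMap,
      frameRate = frameRate, windowFrames = as.integer(windowFrames))
}
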