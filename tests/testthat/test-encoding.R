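partsOf <- function(n) factor(rep_len(c("tentacle", "upper", "lower"), n),
                              levels = c("tentacle", "upper", "lower"))

test_that("PCA halving keeps ceiling(D/2) components and whitens to unit variance", {
  set.seed(1)
  X <- matrix(rnorm(300 * 9), 300, 9)
  tr <- fitPcaWhiten(X, partsOf(300))
  expect_equal(ncol(tr$basis), 5L)           # 9-dim HOF -> 5
  X8 <- matrix(rnorm(300 * 8), 300, 8)
  expect_equal(ncol(fitPcaWhiten(X8, partsOf(300))$basis), 4L)
  W <- applyPcaWhiten(tr, X, partsOf(300))
  expect_equal(unname(apply(W, 2L, var)), rep(1, 5L), tolerance = 1e-6)
  # whitening is division by sqrt(eigenvalue): component 2, eigenvalue 4 -> 1
  tr2 <- tr; tr2$eigenvalues <- rep(4, 5)
  one <- matrix(0, 1, 9)
  proj <- applyPcaWhiten(tr2, one, factor("upper", levels = levels(partsOf(1))))
  raw <- (one - rep(tr$partMeans$upper, each = 1)) %*% tr$basis
  expect_equal(as.numeric(proj), as.numeric(raw) / 2)
  expect_error(fitPcaWhiten(X[1:3, ], partsOf(3)), "fewer samples")
})

test_that("diagonal EM recovers well-separated mixtures and closed forms", {
  set.seed(2)
  mu0 <- rbind(c(-3, 0), c(3, 1))
  X <- rbind(matrix(rnorm(1200, 0, 0.5), 600, 2) + rep(mu0[1, ], each = 600),
             matrix(rnorm(1200, 0, 0.5), 600, 2) + rep(mu0[2, ], each = 600))
  g <- fitGmm(X, K = 2L, seed = 7)
  # match components to truth by nearest mean
  perm <- apply(as.matrix(dist(rbind(mu0, g$means)))[1:2, 3:4], 1L,
                which.min)
  expect_true(all(perm == c(1, 2) | perm == c(2, 1)))
  expect_lt(max(abs(g$means[perm, ] - mu0)), 0.1)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_true(all(g$weights > 0))
  # K = 1 closed form
  g1 <- fitGmm(X, K = 1L)
  expect_equal(as.numeric(g1$means), colMeans(X), tolerance = 1e-9)
  expect_equal(as.numeric(g1$variances),
               apply(X, 2L, var) * (nrow(X) - 1) / nrow(X),
               tolerance = 1e-6)
  # cross-check against an independent EM implementation (mclust VVI)
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  permM <- apply(as.matrix(dist(rbind(t(mc$parameters$mean),
                                      g$means)))[1:2, 3:4], 1L, which.min)
  expect_lt(max(abs(g$means[permM, ] - t(mc$parameters$mean))), 0.05)
  # subsetting + seeding is deterministic
  expect_identical(fitGmm(X, K = 2L, nSubset = 500L, seed = 3)$means,
                   fitGmm(X, K = 2L, nSubset = 500L, seed = 3)$means)
})

test_that("Fisher vectors match the finite-difference oracle", {
  # closed-form check at a single point on the mean
  z1 <- fisherVector(matrix(c(1, 2), 1),
                     list(weights = 1, means = matrix(c(1, 2), 1),
                          variances = matrix(c(1, 1), 1)))
  expect_equal(z1, c(0, 0, -1 / sqrt(2), -1 / sqrt(2)))
  # numeric gradient of the GMM log-likelihood, scaled by the diagonal
  # Fisher-information normalization, on random small instances
  fvOracle <- function(X, w, mu, sig2) {
    K <- length(w); q <- ncol(mu); Tn <- nrow(X)
    loglik <- function(mu, sig) {
      s <- 0
      for (t in seq_len(Tn)) {
        comp <- vapply(seq_len(K), function(i)
          w[i] * prod(dnorm(X[t, ], mu[i, ], sig[i, ])), numeric(1L))
        s <- s + log(sum(comp))
      }
      s / Tn
    }
    sig <- sqrt(sig2); eps <- 1e-6
    Gmu <- matrix(0, K, q); Gsig <- matrix(0, K, q)
    for (i in seq_len(K)) for (d in seq_len(q)) {
      m1 <- mu; m1[i, d] <- m1[i, d] + eps
      m2 <- mu; m2[i, d] <- m2[i, d] - eps
      Gmu[i, d] <- (loglik(m1, sig) - loglik(m2, sig)) / (2 * eps) *
        sig[i, d] / sqrt(w[i])
      s1 <- sig; s1[i, d] <- s1[i, d] + eps
      s2 <- sig; s2[i, d] <- s2[i, d] - eps
      Gsig[i, d] <- (loglik(mu, s1) - loglik(mu, s2)) / (2 * eps) *
        sig[i, d] / sqrt(2 * w[i])
    }
    c(t(Gmu), t(Gsig))
  }
  set.seed(42)
  for (r in 1:20) {
    K <- 2L; q <- sample(2:3, 1L); Tn <- sample(3:10, 1L)
    w <- runif(K); w <- w / sum(w)
    mu <- matrix(rnorm(K * q), K)
    sig2 <- matrix(runif(K * q, 0.3, 2), K)
    X <- matrix(rnorm(Tn * q), Tn)
    z <- fisherVector(X, list(weights = w, means = mu, variances = sig2))
    expect_lt(max(abs(z - fvOracle(X, w, mu, sig2))), 1e-5)
  }
})

test_that("the expected score vanishes for data drawn from the codebook", {
  set.seed(9)
  w <- c(0.2, 0.5, 0.3)
  mu <- matrix(rnorm(6), 3)
  sig2 <- matrix(runif(6, 0.5, 1.5), 3)
  comp <- sample.int(3L, 1e5, TRUE, w)
  X <- mu[comp, ] + matrix(rnorm(2e5), ncol = 2) * sqrt(sig2[comp, ])
  z <- fisherVector(X, list(weights = w, means = mu, variances = sig2))
  expect_lt(sqrt(sum(z^2)), 0.05)
})

test_that("power + l2 normalization behaves as specified", {
  expect_equal(normalizeFv(-4), -1)              # sign(-4)*2 then /2
  set.seed(3)
  z <- rnorm(100)
  expect_equal(sqrt(sum(normalizeFv(z)^2)), 1, tolerance = 1e-12)
  expect_equal(normalizeFv(z, alpha = 1), z / sqrt(sum(z^2)))
  expect_equal(normalizeFv(numeric(10)), numeric(10))
})

test_that("window encoding concatenates blocks in the documented order", {
  dd <- descriptorDims()
  mkCb <- function(type, K, q) {
    D <- dd[[type]]
    new("GmmCodebook", descType = type,
        partMeans = list(tentacle = numeric(D), upper = numeric(D),
                         lower = numeric(D)),
        pcaBasis = diag(D)[, seq_len(q), drop = FALSE],
        eigenvalues = rep(1, q), weights = rep(1 / K, K),
        means = matrix(seq_len(K * q) / (K * q), K, q),
        variances = matrix(1, K, q))
  }
  qs <- c(hof = 5L, hog = 4L, mbhx = 4L, mbhy = 4L)
  cbs <- lapply(names(dd), function(ty) mkCb(ty, 128L, qs[[ty]]))
  names(cbs) <- names(dd)
  # a window with trajectories only in the tentacle part
  mkTs <- function(part) {
    n <- 6L
    new("TrajectorySet", x = matrix(1, n, 15), y = matrix(1, n, 15),
        startFrame = rep(1L, n),
        part = factor(rep(part, n), levels = c("tentacle", "upper", "lower")),
        descriptors = lapply(dd, function(d)
          matrix(abs(rnorm(n * d)), n, d)))
  }
  set.seed(5)
  fw <- encodeWindows(list(mkTs("tentacle")), cbs)
  expect_equal(ncol(fisherMatrix(fw)), 3L * 2L * 128L * (5L + 4L + 4L + 4L))
  expect_equal(ncol(fisherMatrix(fw)), 13056L)
  bm <- blockMap(fw)
  expect_equal(bm$part[1:4], rep("tentacle", 4L))
  expect_equal(bm$type[1:4], c("hof", "hog", "mbhx", "mbhy"))
  v <- fisherMatrix(fw)[1L, ]
  upperCols <- with(bm, unlist(mapply(seq, start[part == "upper"],
                                      end[part == "upper"])))
  expect_true(all(v[upperCols] == 0))
  expect_gt(sum(v != 0), 0)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
  # permuting trajectory order leaves the encoding unchanged
  ts <- mkTs("tentacle")
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  tsP <- new("TrajectorySet", x = ts@x[perm, ], y = ts@y[perm, ],
             startFrame = ts@startFrame[perm], part = ts@part[perm],
             descriptors = lapply(ts@descriptors, function(m) m[perm, ]))
  expect_equal(fisherMatrix(encodeWindows(list(ts), cbs)),
               fisherMatrix(encodeWindows(list(tsP), cbs)),
               tolerance = 1e-12)
  # duplicating the descriptor set leaves the encoding unchanged (T-norm)
  dup <- c(seq_len(6L), seq_len(6L))
  tsD <- new("TrajectorySet", x = ts@x[dup, ], y = ts@y[dup, ],
             startFrame = ts@startFrame[dup], part = ts@part[dup],
             descriptors = lapply(ts@descriptors, function(m) m[dup, ]))
  expect_equal(fisherMatrix(encodeWindows(list(ts), cbs)),
               fisherMatrix(encodeWindows(list(tsD), cbs)),
               tolerance = 1e-9)
})

test_that("codebooks round-trip through their JSON serialization", {
  set.seed(12)
  X <- matrix(rnorm(300 * 8), 300, 8)
  cb <- fitCodebook(X, partsOf(300), "hog", K = 3L, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeCodebook(cb, path)
  back <- readCodebook(path)
  expect_equal(back@weights, cb@weights, tolerance = 1e-12)
  expect_equal(back@means, cb@means, tolerance = 1e-12)
  expect_equal(back@pcaBasis, cb@pcaBasis, tolerance = 1e-12)
  # and it encodes identically
  z1 <- fisherVector(applyPcaWhiten(cb, X[1:20, ], partsOf(20)), cb)
  z2 <- fisherVector(applyPcaWhiten(back, X[1:20, ], partsOf(20)), back)
  expect_equal(z1, z2, tolerance = 1e-12)
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), other)
  expect_error(readCodebook(other), "not a hydrabow codebook")
})
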