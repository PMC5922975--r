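test_that("t-SNE separates well-separated clusters and is deterministic", {
  set.seed(1)
  n <- 240
  cl <- rep(1:2, each = n / 2)
  mu <- rbind(rep(0, 10), c(50, rep(0, 9)))
  X <- mu[cl, ] + matrix(rnorm(n * 10), n)
  em <- embedTsne(X, perplexity = 16, seed = 2, maxIter = 600L)
  km <- kmeans(em$Y, 2L, nstart = 5L)
  acc <- max(mean((km$cluster == 1) == (cl == 1)),
             mean((km$cluster == 2) == (cl == 1)))
  expect_gte(acc, 0.99)
  # KL decreases over the logged trace
  expect_lt(tail(em$klTrace, 1L), em$klTrace[1L])
  # fixed seed -> identical coordinates
  em2 <- embedTsne(X, perplexity = 16, seed = 2, maxIter = 600L)
  expect_identical(em$Y, em2$Y)
  # duplicated points embed within a small fraction of the map extent
  Xd <- rbind(X[1:40, ], X[1:40, ])
  emd <- embedTsne(Xd, perplexity = 10, seed = 1, maxIter = 400L)
  sep <- sqrt(rowSums((emd$Y[1:40, ] - emd$Y[41:80, ])^2))
  expect_lt(median(sep) / max(dist(emd$Y)), 0.05)
  # too few points for the perplexity
  expect_error(embedTsne(X[1:20, ], perplexity = 16), "too few")
})

test_that("perplexity calibration matches its definition", {
  set.seed(2)
  d2 <- runif(50, 0.5, 4)^2
  p <- hydrabow:::.condP(d2, perplexity = 8)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(exp(-sum(p * log(p))), 8, tolerance = 1e-3)
  # probabilities decay with distance
  expect_true(all(diff(p[order(d2)]) <= 1e-12))
})

test_that("the density map is a normalized kernel estimate", {
  set.seed(3)
  pts <- matrix(rnorm(100), 50, 2)
  dm <- densityMap(pts, sigmaFrac = 1 / 10, gridN = 201L)
  cell <- diff(dm$gx)[1L]
  expect_equal(sum(dm$density) * cell^2, 1, tolerance = 0.01)
  # single point: radially symmetric bump centered on it
  dm1 <- densityMap(matrix(c(0.3, -0.2), 1), sigmaFrac = 1 / 10,
                    gridN = 101L)
  pk <- which(dm1$density == max(dm1$density), arr.ind = TRUE)[1L, ]
  expect_lt(abs(dm1$gx[pk[1L]] - 0.3), diff(dm1$gx)[1L])
  expect_lt(abs(dm1$gy[pk[2L]] + 0.2), diff(dm1$gy)[1L])
  # halving sigma increases the peak density
  dmA <- densityMap(pts, sigmaFrac = 1 / 20, gridN = 201L)
  expect_gt(max(dmA$density), max(dm$density))
})

test_that("watershed segmentation finds one region per merged peak group", {
  gx <- seq(-5, 5, length.out = 301)
  d1 <- outer(dnorm(gx, -2, 0.6), dnorm(gx, 0, 0.6))
  d2 <- outer(dnorm(gx, 2, 0.6), dnorm(gx, 0.5, 0.6))
  reg <- segmentDensity(d1 + d2)
  expect_equal(max(reg), 2L)
  # basin assignment oracle: interior cells belong to the nearer peak
  pks <- rbind(which(d1 == max(d1), arr.ind = TRUE)[1L, ],
               which(d2 == max(d2), arr.ind = TRUE)[1L, ])
  r1 <- reg[pks[1L, 1L], pks[1L, 2L]]
  r2 <- reg[pks[2L, 1L], pks[2L, 2L]]
  expect_true(r1 != r2 && r1 > 0 && r2 > 0)
  set.seed(4)
  supp <- which(reg > 0, arr.ind = TRUE)
  samp <- supp[sample.int(nrow(supp), 200L), ]
  dPk <- cbind(rowSums((samp - rep(pks[1L, ], each = 200))^2),
               rowSums((samp - rep(pks[2L, ], each = 200))^2))
  nearer <- c(r1, r2)[max.col(-dPk)]
  agree <- mean(reg[samp] == nearer)
  expect_gte(agree, 0.95)
  # one bump -> one region; two peaks 2 px apart merge by the 3-px dilation
  expect_equal(max(segmentDensity(d1)), 1L)
  dd <- matrix(0, 50, 50); dd[25, 25] <- 1; dd[25, 27] <- 1
  dd <- as.matrix(EBImage::filter2(dd, matrix(1 / 9, 3, 3)))
  expect_equal(max(segmentDensity(dd)), 1L)
  # segmentation is invariant under positive rescaling of the density
  expect_identical(segmentDensity(d1 + d2), segmentDensity((d1 + d2) * 7.3))
})

test_that("regions take the majority label with prominence tie-breaks", {
  region <- c(rep(1L, 35), rep(2L, 10))
  labels <- c(rep(behaviorCode("elongation"), 30),
              rep(behaviorCode("silent"), 5),
              rep(behaviorCode("silent"), 5),
              rep(behaviorCode("contraction"), 5))
  tab <- labelRegions(region, labels, nRegions = 3L)
  expect_equal(tab$majority_label[1L], behaviorCode("elongation"))
  expect_equal(tab$fraction[1L], 30 / 35)
  # region 2 ties 5:5 -> contraction (more prominent)
  expect_equal(tab$majority_label[2L], behaviorCode("contraction"))
  # empty region -> none
  expect_equal(tab$majority_label[3L], 0L)
  expect_equal(tab$majority_name[3L], "none")
})

test_that("out-of-sample embedding is self-consistent on training points", {
  set.seed(5)
  n <- 90
  cl <- rep(1:3, each = n / 3)
  mu <- rbind(c(0, 0, 0, 0), c(12, 0, 0, 0), c(0, 12, 0, 0))
  X <- mu[cl, ] + matrix(rnorm(n * 4, 0, 0.5), n)
  fw <- new("FisherWindows", vectors = X,
            info = data.frame(window_id = seq_len(n),
                              t_start_s = (seq_len(n) - 1) * 5,
                              label = cl),
            blockMap = data.frame(part = "tentacle", type = "hof",
                                  start = 1L, end = 4L),
            frameRate = 5, windowFrames = 25L)
  map <- buildMotifMap(fw, perplexity = 10, gridN = 201L, pcaVar = 0.999,
                       seed = 2, maxIter = 500L)
  expect_true(validObject(map))
  # training points re-embedded as new land near their original position
  oos <- embedNew(map, fw)
  span <- max(dist(embeddedPoints(map)))
  d <- sqrt(rowSums((as.matrix(oos[, c("x", "y")]) -
                     embeddedPoints(map))^2))
  expect_lt(median(d) / span, 0.05)
  # and get the same region id
  trainReg <- hydrabow:::.pointRegions(embeddedPoints(map),
                                       map@regionGrid, map@gridX, map@gridY)
  expect_gte(mean(oos$region == trainReg), 0.9)
  # exported artifacts are written and consistent
  outDir <- withr::local_tempdir()
  writeMotifMap(map, outDir)
  pts <- read.csv(file.path(outDir, "points.csv"))
  expect_equal(nrow(pts), n)
  expect_equal(pts$region, unname(trainReg))
  expect_true(file.exists(file.path(outDir, "region_grid.png")))
  fwp <- file.path(outDir, "enc")
  writeFisherWindows(fw, fwp)
  M <- as.matrix(read.csv(paste0(fwp, "_matrix.csv"), header = FALSE))
  expect_equal(unname(M), unname(fisherMatrix(fw)), tolerance = 1e-9)
})
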