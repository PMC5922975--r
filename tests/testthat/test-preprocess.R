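test_that("background estimation is anti-extensive and removes the animal", {
  # uniform frame: opening changes nothing
  u <- matrix(0.4, 64, 64)
  expect_equal(estimateBackground(u, radius = 10, downscale = 1L), u)
  # all-zero frame
  z <- matrix(0, 64, 64)
  expect_equal(estimateBackground(z, radius = 10, downscale = 1L), z)
  # bright disk on dark field: oracle = direct erosion-then-dilation
  fr <- matrix(0.1, 120, 120)
  xs <- seq_len(120)
  disk <- outer((xs - 60)^2, (xs - 60)^2, "+") <= 20^2
  fr[disk] <- 0.9
  bg <- estimateBackground(fr, radius = 40, downscale = 1L)
  br <- EBImage::makeBrush(81, "disc")
  oracle <- as.matrix(EBImage::dilate(EBImage::erode(fr, br), br))
  expect_equal(bg, pmin(oracle, fr), tolerance = 1e-12)
  expect_true(all(bg <= fr + 1e-12))          # anti-extensive
  expect_gt(mean((fr - bg)[disk]), 0.5)       # disk survives subtraction
  # structuring element larger than image
  expect_error(estimateBackground(u, radius = 200), "larger")
})

test_that("segmentation recovers the animal and drops specks", {
  sc <- smallClip()
  fr <- sc$clip@frames[, , 1L]
  bg <- sc$analysis$background
  mask <- segmentAnimal(fr, bg)
  truth <- sc$truth$masks$body[[1L]] | sc$truth$masks$tentacle[[1L]]
  expect_gte(sum(mask & truth) / sum(truth), 0.99)
  # isolated small speck removed by the 0.25% area rule
  fr2 <- matrix(0, 640, 480)
  fr2[100:150, 100:150] <- 0.9         # 2601 px > 0.25% of 307200
  fr2[300:302, 300:302] <- 0.9         # 9 px speck
  m2 <- segmentAnimal(fr2, matrix(0, 640, 480))
  expect_false(any(m2[299:303, 299:303]))
  expect_true(any(m2[120:130, 120:130]))
  # dilation is extensive: mask area >= pre-dilation area
  m0 <- segmentAnimal(fr, bg, dilatePx = 0L)
  expect_gte(sum(mask), sum(m0))
})

test_that("two-pass Otsu ellipse fit recovers noise-free geometry", {
  sc <- smallClip()
  g <- sc$analysis$geometry
  tr <- sc$truth$ellipse_track
  expect_lt(max(abs(g$major - tr$major)), 2)
  expect_lt(max(abs(g$minor - tr$minor)), 2)
  dang <- abs(((g$angle_deg - tr$angle_deg + 90) %% 180) - 90)
  expect_lt(max(dang), 2)
  # circular body: degenerate symmetry accepted
  fr <- matrix(0, 150, 150)
  xs <- seq_len(150)
  fr[outer((xs - 75)^2, (xs - 75)^2, "+") <= 30^2] <- 0.9
  el <- fitBodyColumn(fr, matrix(0, 150, 150))
  expect_equal(el$major, el$minor, tolerance = 0.05)
})

test_that("polarity resolution points the head at the tentacles", {
  sc <- smallClip()
  g <- sc$analysis$geometry
  tr <- sc$truth$ellipse_track
  dots <- g$head_x * tr$head_x + g$head_y * tr$head_y
  expect_true(all(dots > 0.95))
  # mirror flip reverses the head direction
  fr <- sc$clip@frames[, , 1L]
  frF <- fr[rev(seq_len(nrow(fr))), ]
  bgF <- sc$analysis$background[rev(seq_len(nrow(fr))), ]
  mF <- segmentAnimal(frF, bgF)
  elF <- fitBodyColumn(frF, bgF, mF)
  elF <- resolvePolarity(mF, elF$bodyMask, elF)
  expect_equal(elF$head_x, -g$head_x[1L], tolerance = 0.1)
  expect_equal(elF$head_y, g$head_y[1L], tolerance = 0.1)
  # tentacle-free blob: fallback to previous polarity, else error
  fr0 <- matrix(0, 150, 150)
  xs <- seq_len(150)
  fr0[outer(((xs - 75) / 45)^2, ((xs - 75) / 15)^2, "+") <= 1] <- 0.9
  el0 <- fitBodyColumn(fr0, matrix(0, 150, 150))
  mask0 <- el0$bodyMask
  expect_error(resolvePolarity(mask0, el0$bodyMask, el0), "polarity")
  elPrev <- resolvePolarity(mask0, el0$bodyMask, el0, prevHead = c(1, 0))
  expect_equal(c(elPrev$head_x, elPrev$head_y), c(1, 0), tolerance = 1e-9)
})

test_that("body parts are disjoint and the tentacle mask covers the truth", {
  sc <- smallClip()
  g <- sc$analysis$geometry
  parts <- splitBodyParts(sc$analysis$masks[[1L]],
                          sc$analysis$bodyMasks[[1L]],
                          ellipseFromGeometry(g, 1L))
  tm <- sc$truth$masks$tentacle[[1L]]
  expect_gte(sum(parts$tentacle & tm) / sum(tm), 0.9)
  expect_equal(sum(parts$tentacle & parts$upper), 0)
  expect_equal(sum(parts$tentacle & parts$lower), 0)
  expect_equal(sum(parts$upper & parts$lower), 0)
  union <- parts$tentacle | parts$upper | parts$lower
  expect_true(all(!union | sc$analysis$masks[[1L]]))
  # the foot end lies in the lower mask
  foot <- c(g$cx[1L] - g$head_x[1L] * g$major[1L] / 2,
            g$cy[1L] - g$head_y[1L] * g$major[1L] / 2)
  expect_true(parts$lower[round(foot[1L]), round(foot[2L])])
})

test_that("window registration reaches the canonical pose", {
  # a clip with constant orientation registers to the vertical canonical
  # pose (a swaying clip keeps its within-window oscillation by design)
  sc <- smallClip()
  rws <- registerWindow(sc$clip, sc$analysis, 1L)
  regS <- fitBodyColumn(frames(rws)[, , 13L], matrix(0, 300, 300))
  expect_lt(abs(regS$major - 100), 5)
  expect_lt(abs(abs(regS$angle) - 90), 3)   # vertical body axis
  sw <- swayWindow()
  rw <- sw$rw
  reg <- fitBodyColumn(frames(rw)[, , 13L], matrix(0, 300, 300))
  expect_lt(abs(reg$major - 100), 5)
  # a translated copy registers to (nearly) the same pixels
  res <- sw$res
  sh <- res$clip
  sh@frames <- sh@frames[c(11:dim(sh@frames)[1L], 1:10),
                         c(6:dim(sh@frames)[2L], 1:5), , drop = FALSE]
  anS <- analyzeClip(sh)
  rwS <- registerWindow(sh, anS, 1L)
  diffs <- abs(frames(rwS)[, , 13L] - frames(rw)[, , 13L])
  expect_lt(mean(diffs) * 255, 2)
  # short window rejected
  expect_error(registerWindow(res$clip, sw$analysis, 99L), "shorter")
})

test_that("registration is invariant to similarity transforms of the input", {
  # rotating the scene rotates the fitted frame back to the same canonical
  # pose: compare registered output of two different-seed views indirectly
  # via the transform consistency (angle + head direction round trip)
  sw <- swayWindow()
  tr <- sw$rw@transform
  hb <- tr$head
  ang <- tr$angle * pi / 180
  rot <- c(cos(ang) * hb[1L] - sin(ang) * hb[2L],
           sin(ang) * hb[1L] + cos(ang) * hb[2L])
  expect_equal(rot, c(0, 1), tolerance = 1e-6)  # head maps to +y
})
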