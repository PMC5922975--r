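mkFW <- function(X, labels = NULL)
  new("FisherWindows", vectors = X,
      info = data.frame(window_id = seq_len(nrow(X)),
                        t_start_s = (seq_len(nrow(X)) - 1) * 5,
                        label = if (is.null(labels)) NA_integer_
                                else as.integer(labels)),
      blockMap = data.frame(part = "tentacle", type = "hof", start = 1L,
                            end = ncol(X)),
      frameRate = 5, windowFrames = 25L)

sepFW <- function(n = 60, d = 20, sd = 0.3, seed = 1) {
  set.seed(seed)
  mu <- rbind(rep(0, d), c(rep(3, 5), rep(0, d - 5)),
              c(rep(0, d - 5), rep(3, 5)))
  y <- rep(1:3, each = n / 3)
  mkFW(mu[y, ] + matrix(rnorm(n * d, 0, sd), n), y)
}

test_that("window labels aggregate by the prominence-weighted rule", {
  silent <- behaviorCode("silent"); contr <- behaviorCode("contraction")
  expect_equal(aggregateWindowLabel(c(rep(silent, 18), rep(contr, 7))),
               contr)    # 18 <= 3*7 and contraction is more prominent
  expect_equal(aggregateWindowLabel(c(rep(silent, 20), rep(contr, 5))),
               silent)   # 20 > 15
  expect_equal(aggregateWindowLabel(rep(behaviorCode("elongation"), 25)),
               behaviorCode("elongation"))
  # none frames are ignored unless the window is all none
  expect_equal(aggregateWindowLabel(c(rep(0L, 20), rep(silent, 5))), silent)
  expect_equal(aggregateWindowLabel(rep(0L, 25)), 0L)
})

test_that("training selects a separable model with the stated class weights", {
  fw <- sepFW()
  m <- trainBehaviorClassifier(fw, seed = 3)
  expect_equal(m@cvAccuracy, 1)
  eth <- predictHard(m, fw)
  expect_equal(mean(ethogramTable(eth)$label1 == windowInfo(fw)$label), 1)
  # fixed seed: identical selected (cost, gamma)
  m2 <- trainBehaviorClassifier(fw, seed = 3)
  expect_identical(c(m@bestCost, m@bestGamma), c(m2@bestCost, m2@bestGamma))
  # single-class input rejected
  expect_error(trainBehaviorClassifier(mkFW(matrix(rnorm(40), 10),
                                            rep(1L, 10))), "two classes")
  # class weights w_i = sum(N)/N_i: counts (100, 300) -> (4, 4/3)
  set.seed(2)
  X <- rbind(matrix(rnorm(100 * 4), 100) + 3, matrix(rnorm(300 * 4), 300))
  mw <- trainBehaviorClassifier(mkFW(X, rep(1:2, c(100, 300))),
                                cGrid = 1, gGrid = 0.1)
  expect_equal(unname(mw@classWeights), c(4, 4 / 3))
})

test_that("hard prediction takes the argmax and is reproducible", {
  fw <- sepFW()
  m <- trainBehaviorClassifier(fw, seed = 3)
  pr <- hydrabow:::.classProbs(m, fw)
  eth <- predictHard(m, fw)
  expect_equal(ethogramTable(eth)$label1,
               m@classes[max.col(pr, ties.method = "first")])
  # identical window encoded twice -> identical prediction
  two <- mkFW(fisherMatrix(fw)[c(1L, 1L), ])
  e2 <- predictHard(m, two)
  expect_identical(ethogramTable(e2)$label1[1L],
                   ethogramTable(e2)$label1[2L])
})

test_that("the soft rule admits up to three labels by the 50% cascade", {
  fw <- mkFW(matrix(0, 3, 2))
  mk <- function(p) hydrabow:::.ethogramFromProbs(
    matrix(p, 1, length(p)), seq_along(p), mkFW(matrix(0, 1, 2)),
    soft = TRUE)
  t1 <- ethogramTable(mk(c(0.5, 0.3, 0.15, 0.05)))
  expect_equal(unlist(t1[, c("label1", "label2", "label3")],
                      use.names = FALSE), c(1L, 2L, NA))  # 0.15 not > 0.15
  t2 <- ethogramTable(mk(c(0.4, 0.3, 0.2)))
  expect_equal(unlist(t2[, c("label1", "label2", "label3")],
                      use.names = FALSE), c(1L, 2L, 3L))
  t3 <- ethogramTable(mk(c(0.8, 0.2)))
  expect_equal(unlist(t3[, c("label1", "label2", "label3")],
                      use.names = FALSE), c(1L, NA, NA))
})

test_that("evaluation reproduces plug-in metrics and ROC properties", {
  truth <- c(rep(1L, 14), rep(2L, 86))
  pred <- c(rep(1L, 9), rep(2L, 5), 1L, rep(2L, 85))  # TP9 FN5 FP1 TN85
  eth <- new("Ethogram",
             table = data.frame(window_id = 1:100, t_start_s = 0,
                                label1 = pred, prob1 = 1,
                                label2 = NA_integer_, prob2 = NA_real_,
                                label3 = NA_integer_, prob3 = NA_real_),
             frameRate = 5, windowFrames = 25L)
  ev <- evaluateClassification(eth, truth)
  pc <- ev$perClass[ev$perClass$code == 1L, ]
  expect_equal(pc$accuracy, 0.94)
  expect_equal(pc$precision, 0.9)
  expect_equal(pc$recall, 9 / 14)
  # confusion rows sum to per-class truth counts; trace/total = accuracy
  expect_equal(unname(rowSums(ev$confusion)), c(14, 86))
  expect_equal(sum(diag(ev$confusion)) / 100, ev$overallAccuracy)
  # ROC monotone, AUC in [0, 1], perfect scores give AUC 1
  set.seed(4)
  sc <- rnorm(500); tr <- runif(500) < plogis(sc)
  rc <- rocCurve(sc, tr)
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
  expect_gte(rc$auc, 0); expect_lte(rc$auc, 1)
  expect_equal(rocCurve(as.numeric(tr), tr)$auc, 1)
  # cross-check the trapezoid AUC against pROC
  expect_equal(rc$auc,
               as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("soft-classification accuracy dominates hard accuracy", {
  fw <- sepFW(sd = 1.2, seed = 8)   # overlapping classes
  m <- trainBehaviorClassifier(fw, seed = 1)
  truth <- windowInfo(fw)$label
  hard <- evaluateClassification(predictHard(m, fw), truth)$overallAccuracy
  soft <- evaluateClassification(predictSoft(m, fw), truth)$overallAccuracy
  expect_gte(soft, hard)
})

test_that("ethogram summaries report fractions and block variability", {
  mkEth <- function(labels) new("Ethogram",
    table = data.frame(window_id = seq_along(labels),
                       t_start_s = (seq_along(labels) - 1) * 5,
                       label1 = labels, prob1 = 1, label2 = NA_integer_,
                       prob2 = NA_real_, label3 = NA_integer_,
                       prob3 = NA_real_),
    frameRate = 5, windowFrames = 25L)
  # all-silent: fraction 1, zero block SD (blocks of 2 windows = 10 s)
  s <- summarizeEthogram(mkEth(rep(1L, 20)), blockMinutes = 10 / 60)
  expect_equal(s$fraction[s$code == 1L], 1)
  expect_equal(s$blockSd[s$code == 1L], 0)
  # identically alternating blocks: SD 0
  s2 <- summarizeEthogram(mkEth(rep(c(1L, 2L), 10)), blockMinutes = 10 / 60)
  expect_equal(s2$blockSd, c(0, 0))
  # two blocks with fractions 0.2 / 0.4
  lb <- c(c(2L, rep(1L, 9)), c(2L, 2L, rep(1L, 8)))  # fractions .1/.2 of 2
  s3 <- summarizeEthogram(mkEth(lb), blockMinutes = 50 / 60)
  expect_equal(s3$blockSd[s3$code == 2L], sd(c(0.1, 0.2)))
})
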