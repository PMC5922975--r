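# Supervised behavior classification of Fisher windows.

#' Aggregate per-frame labels into one window label
#'
#' None-class frames (code 0) are ignored unless the whole window is none.
#' Let L1 and L2 be the two most frequent labels (ties broken by
#' prominence). The window is labeled L2 when L2 is the more prominent
#' behavior and L1's count does not exceed three times L2's count;
#' otherwise L1. This promotes brief large-motion behaviors (e.g. a few
#' contraction frames inside a mostly silent window).
#'
#' @param frameLabels integer behavior codes for the frames of one window.
#' @return a single integer behavior code.
#' @export
aggregateWindowLabel <- function(frameLabels) {
  frameLabels <- as.integer(frameLabels)
  stopifnot(length(frameLabels) > 0)
  lab <- frameLabels[frameLabels != 0L]
  if (!length(lab)) return(0L)
  cnt <- table(lab)
  codes <- as.integer(names(cnt))
  ord <- order(-as.integer(cnt), -prominenceOf(codes))
  L1 <- codes[ord[1L]]
  if (length(codes) == 1L) return(L1)
  L2 <- codes[ord[2L]]
  n1 <- as.integer(cnt[as.character(L1)])
  n2 <- as.integer(cnt[as.character(L2)])
  if (prominenceOf(L2) > prominenceOf(L1) && n1 <= 3L * n2) L2 else L1
}

#' Train the class-weighted RBF-SVM behavior classifier
#'
#' PCA reduces the Fisher vectors keeping 90\% of the training variance;
#' an RBF-kernel SVM with per-class weights w_i = sum(N)/N_i is selected
#' by cross-validated grid search over log2(cost) and log2(gamma) in
#' -5, -3, ..., 15, then refitted on all training data with probability
#' estimates.
#'
#' @param fw a labeled \code{\link{FisherWindows-class}} object.
#' @param cvFolds cross-validation folds.
#' @param cGrid,gGrid cost and kernel-width grids.
#' @param pcaVar fraction of variance retained by the PCA.
#' @param seed seed for the fold assignment.
#' @param groups optional grouping vector (e.g. animal id per window);
#'   when given, cross-validation folds keep whole groups together, so the
#'   grid search measures generalization to unseen animals rather than to
#'   near-duplicate windows of the same clip.
#' @return a \code{\link{BehaviorModel-class}} object.
#' @export
trainBehaviorClassifier <- function(fw, cvFolds = 5L,
                                    cGrid = 2^seq(-5, 15, 2),
                                    gGrid = 2^seq(-5, 15, 2),
                                    pcaVar = 0.9, seed = 1L,
                                    groups = NULL) {
  stopifnot(is(fw, "FisherWindows"))
  y <- windowInfo(fw)$label
  if (anyNA(y)) stop("all training windows must be labeled")
  if (length(unique(y)) < 2L) stop("at least two classes are required")
  X <- fisherMatrix(fw)
  ctr <- colMeans(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  cums <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  qd <- max(which(cums >= pcaVar)[1L], 2L)
  basis <- pc$rotation[, seq_len(qd), drop = FALSE]
  Z <- sweep(X, 2L, ctr) %*% basis
  yf <- factor(y)
  Ns <- table(yf)
  wts <- as.numeric(sum(Ns) / Ns)
  names(wts) <- names(Ns)
  folds <- withSeed(seed, {
    if (!is.null(groups)) {
      stopifnot(length(groups) == length(y))
      gids <- unique(groups)
      gf <- sample(rep_len(seq_len(cvFolds), length(gids)))
      gf[match(groups, gids)]
    } else {
      f <- integer(length(y))
      for (cl in levels(yf)) {
        rows <- which(yf == cl)
        f[rows] <- sample(rep_len(seq_len(cvFolds), length(rows)))
      }
      f
    }
  })
  # the cross-validated accuracy is measured the way the model is used:
  # argmax of the calibrated class probabilities (a degenerate grid point
  # can separate by decision values while its probability calibration
  # collapses, and the selection must see that)
  grid <- expand.grid(cost = cGrid, gamma = gGrid)
  accs <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    for (k in seq_len(cvFolds)) {
      tr <- folds != k
      if (!any(!tr) || length(unique(yf[tr])) < 2L) next
      fit <- e1071::svm(Z[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = grid$cost[gi], gamma = grid$gamma[gi],
                        class.weights = wts, scale = FALSE,
                        probability = TRUE)
      pr <- attr(predict(fit, Z[!tr, , drop = FALSE], probability = TRUE),
                 "probabilities")
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      correct <- correct + sum(pred == as.character(yf[!tr]))
    }
    accs[gi] <- correct / length(y)
  }
  best <- which.max(accs)
  cvTable <- cbind(grid, accuracy = accs)
  finalFit <- withSeed(seed + 1L,
    e1071::svm(Z, yf, kernel = "radial", cost = grid$cost[best],
               gamma = grid$gamma[best], class.weights = wts,
               probability = TRUE, scale = FALSE))
  new("BehaviorModel", pcaCenter = ctr, pcaBasis = basis, svm = finalFit,
      classes = as.integer(levels(yf)), classWeights = wts,
      bestCost = grid$cost[best], bestGamma = grid$gamma[best],
      cvAccuracy = accs[best], cvTable = cvTable)
}

# Class probabilities for new windows, columns ordered as model@classes.
.classProbs <- function(model, fw) {
  X <- fisherMatrix(fw)
  if (ncol(X) != length(model@pcaCenter))
    stop("Fisher-vector dimension does not match the trained model")
  Z <- sweep(X, 2L, model@pcaCenter) %*% model@pcaBasis
  pred <- predict(model@svm, Z, probability = TRUE)
  pr <- attr(pred, "probabilities")
  pr[, as.character(model@classes), drop = FALSE]
}

.ethogramFromProbs <- function(pr, classes, fw, soft) {
  n <- nrow(pr)
  tb <- data.frame(window_id = windowInfo(fw)$window_id,
                   t_start_s = windowInfo(fw)$t_start_s,
                   label1 = NA_integer_, prob1 = NA_real_,
                   label2 = NA_integer_, prob2 = NA_real_,
                   label3 = NA_integer_, prob3 = NA_real_)
  prom <- prominenceOf(classes)
  for (i in seq_len(n)) {
    p <- pr[i, ]
    ord <- order(-p, -prom)     # argmax ties broken by prominence
    tb$label1[i] <- classes[ord[1L]]; tb$prob1[i] <- p[ord[1L]]
    if (soft) {
      if (length(p) >= 2L && p[ord[2L]] > 0.5 * p[ord[1L]]) {
        tb$label2[i] <- classes[ord[2L]]; tb$prob2[i] <- p[ord[2L]]
        if (length(p) >= 3L && p[ord[3L]] > 0.5 * p[ord[2L]]) {
          tb$label3[i] <- classes[ord[3L]]; tb$prob3[i] <- p[ord[3L]]
        }
      }
    }
  }
  new("Ethogram", table = tb, frameRate = frameRate(fw),
      windowFrames = fw@windowFrames)
}

#' Predict behavior labels for encoded windows
#'
#' \code{predictHard} assigns the single class with the highest calibrated
#' probability. \code{predictSoft} allows up to three labels: a second
#' label if its probability exceeds 50\% of the first, and a third if it
#' exceeds 50\% of the second (strict inequalities).
#'
#' @param model a trained \code{\link{BehaviorModel-class}}.
#' @param fw a \code{\link{FisherWindows-class}} object.
#' @return an \code{\link{Ethogram-class}} object.
#' @export
predictHard <- function(model, fw) {
  pr <- .classProbs(model, fw)
  .ethogramFromProbs(pr, model@classes, fw, soft = FALSE)
}

#' @rdname predictHard
#' @export
predictSoft <- function(model, fw) {
  pr <- .classProbs(model, fw)
  .ethogramFromProbs(pr, model@classes, fw, soft = TRUE)
}

#' Area under an ROC curve by the trapezoid rule
#'
#' @param scores numeric scores (larger = more positive).
#' @param truth logical or 0/1 vector.
#' @return list with \code{fpr}, \code{tpr} (curve, threshold-descending)
#'   and \code{auc}.
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0 || nN == 0)
    return(list(fpr = c(0, 1), tpr = c(0, 1), auc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord]); fp <- cumsum(!truth[ord])
  # collapse tied thresholds
  last <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[last] / nP); fpr <- c(0, fp[last] / nN)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluate predictions against manual window labels
#'
#' One-vs-rest per class: a window counts as a true positive for a class
#' when the truth is that class and the class is among the predicted
#' labels (so soft predictions are credited for any matching label).
#' Accuracy is (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), recall
#' TP/(TP+FN); the ROC/AUC per class uses the calibrated class
#' probability. The confusion matrix uses the top label only.
#'
#' @param eth an \code{\link{Ethogram-class}} of predictions.
#' @param truth integer behavior codes per window.
#' @param probs optional probability matrix (columns = classes, in
#'   \code{classes} order) for ROC/AUC.
#' @param classes integer class codes to evaluate (default: classes present
#'   in truth or predictions).
#' @return list with \code{perClass} data.frame, \code{confusion} matrix,
#'   \code{overallAccuracy}, and optional \code{roc} per class.
#' @export
evaluateClassification <- function(eth, truth, probs = NULL,
                                   classes = NULL) {
  tb <- ethogramTable(eth)
  truth <- as.integer(truth)
  stopifnot(nrow(tb) == length(truth))
  predSet <- lapply(seq_len(nrow(tb)), function(i)
    stats::na.omit(c(tb$label1[i], tb$label2[i], tb$label3[i])))
  if (is.null(classes))
    classes <- sort(unique(c(truth, tb$label1)))
  n <- length(truth)
  perClass <- data.frame(code = classes, name = behaviorName(classes),
                         TP = NA_integer_, FP = NA_integer_,
                         TN = NA_integer_, FN = NA_integer_,
                         accuracy = NA_real_, precision = NA_real_,
                         recall = NA_real_, auc = NA_real_)
  roc <- list()
  for (r in seq_along(classes)) {
    cl <- classes[r]
    predPos <- vapply(predSet, function(s) cl %in% s, TRUE)
    truthPos <- truth == cl
    TP <- sum(predPos & truthPos); FP <- sum(predPos & !truthPos)
    FN <- sum(!predPos & truthPos); TN <- n - TP - FP - FN
    perClass[r, c("TP", "FP", "TN", "FN")] <- c(TP, FP, TN, FN)
    if (any(truthPos)) {
      perClass$accuracy[r] <- (TP + TN) / n
      perClass$precision[r] <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
      perClass$recall[r] <- TP / (TP + FN)
      if (!is.null(probs)) {
        rc <- rocCurve(probs[, as.character(cl)], truthPos)
        perClass$auc[r] <- rc$auc
        roc[[as.character(cl)]] <- rc
      }
    }
  }
  present <- sort(unique(c(truth, tb$label1)))
  confusion <- table(factor(truth, levels = present),
                     factor(tb$label1, levels = present))
  names(dimnames(confusion)) <- c("truth", "predicted")
  overall <- mean(mapply(function(s, t) t %in% s, predSet, truth))
  out <- list(perClass = perClass, confusion = confusion,
              overallAccuracy = overall)
  if (length(roc)) out$roc <- roc
  out
}

#' Summarize an ethogram as per-behavior time budgets
#'
#' Fraction of windows assigned to each behavior (top label), plus the
#' standard deviation of that fraction across consecutive blocks (30 min
#' by default) — the within-animal behavior variability measure.
#'
#' @param eth an \code{\link{Ethogram-class}}.
#' @param blockMinutes block length in minutes for the variability measure.
#' @param classes integer codes to report (default: classes present).
#' @return data.frame with \code{code}, \code{name}, \code{fraction},
#'   \code{blockSd} (NA when fewer than two complete blocks exist).
#' @export
summarizeEthogram <- function(eth, blockMinutes = 30, classes = NULL) {
  tb <- ethogramTable(eth)
  if (is.null(classes)) classes <- sort(unique(tb$label1))
  winSec <- eth@windowFrames / eth@frameRate
  perBlock <- max(1L, floor(blockMinutes * 60 / winSec))
  block <- (seq_len(nrow(tb)) - 1L) %/% perBlock + 1L
  complete <- block <= nrow(tb) %/% perBlock
  out <- data.frame(code = classes, name = behaviorName(classes),
                    fraction = NA_real_, blockSd = NA_real_)
  for (r in seq_along(classes)) {
    cl <- classes[r]
    out$fraction[r] <- mean(tb$label1 == cl)
    if (any(complete)) {
      bf <- tapply(tb$label1[complete] == cl, block[complete], mean)
      out$blockSd[r] <- if (length(bf) >= 2L) sd(bf) else NA_real_
    }
  }
  out
}
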