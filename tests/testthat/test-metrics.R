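# Confusion matrix, one-vs-rest metrics, ROC / PR curves and areas.

test_that("confusion counts true-by-predicted occurrences", {
  cm <- confusion(c("P", "P", "QRS", "ISO"), c("P", "QRS", "QRS", "ISO"))
  expect_equal(cm["P", "P"], 1L)
  expect_equal(cm["P", "QRS"], 1L)
  expect_equal(cm["QRS", "QRS"], 1L)
  expect_equal(sum(cm), 4L)
  expect_error(confusion("P", c("P", "QRS")), "length")
})

test_that("confusion agrees with a counting oracle on random labels", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      tr <- sample(ecg_classes(), 200, replace = TRUE)
      pr <- sample(ecg_classes(), 200, replace = TRUE)
      cm <- confusion(tr, pr)
      for (i in ecg_classes()) for (j in ecg_classes())
        expect_equal(cm[i, j], sum(tr == i & pr == j))
    }
  })
})

test_that("perfect prediction gives a diagonal matrix and all metrics 1", {
  lab <- rep(ecg_classes(), times = c(10, 5, 8, 20, 7))
  cm <- confusion(lab, lab)
  expect_true(all(cm[row(cm) != col(cm)] == 0))
  m <- per_class_metrics(cm)
  expect_true(all(abs(as.matrix(m[, -1]) - 1) < 1e-12))
})

test_that("per-class metrics match hand arithmetic on a 2-class toy matrix", {
  cm <- confusion(rep(c("P", "QRS"), times = c(10, 10)),
                  c(rep("P", 8), rep("QRS", 2), rep("P", 1), rep("QRS", 9)))
  m <- per_class_metrics(cm)
  p <- m[m$class == "P", ]
  expect_equal(p$sensitivity, 0.8)
  expect_equal(p$precision, 8 / 9)
  expect_equal(p$specificity, 9 / 10)
  expect_equal(p$accuracy, 17 / 20)
  expect_equal(p$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  # Average row is the unweighted mean over classes with defined metrics?
  # Here classes T/ISO/PAD are absent: their sensitivity is NaN and the
  # average over all five classes is NaN by propagation.
  expect_true(is.nan(m$sensitivity[m$class == "Average"]))
})

test_that("undefined metrics are NaN, not silently zero", {
  cm <- confusion(rep("ISO", 5), rep("ISO", 5))
  m <- per_class_metrics(cm)
  expect_true(is.nan(m$precision[m$class == "P"]))
  expect_equal(m$sensitivity[m$class == "ISO"], 1)
})

test_that("metrics commute with a label permutation", {
  withr::with_seed(11, {
    tr <- sample(ecg_classes(), 500, replace = TRUE)
    pr <- sample(ecg_classes(), 500, replace = TRUE)
    cm <- confusion(tr, pr)
    perm <- c(P = "T", QRS = "ISO", T = "P", ISO = "PAD", PAD = "QRS")
    cm2 <- confusion(unname(perm[tr]), unname(perm[pr]))
    m <- per_class_metrics(cm)
    m2 <- per_class_metrics(cm2)
    for (cl in ecg_classes())
      expect_equal(m2[m2$class == perm[[cl]], -1], m[m$class == cl, -1],
                   ignore_attr = TRUE)
    expect_equal(sum(cm), sum(cm2))
  })
})

test_that("perfectly separating scores give ROC and PR areas of 1", {
  truth <- c(rep("P", 5), rep("ISO", 5))
  probs <- cbind(P = c(rep(0.9, 5), rep(0.1, 5)),
                 ISO = c(rep(0.1, 5), rep(0.9, 5)))
  cv <- roc_pr_curves(truth, probs)
  expect_equal(cv$per_class$P$auc_roc, 1)
  expect_equal(cv$per_class$P$auc_pr, 1)
  expect_equal(cv$micro$auc_roc, 1)
})

test_that("label-independent scores give ROC area near 0.5", {
  withr::with_seed(29, {
    n <- 10000
    truth <- sample(c("P", "ISO"), n, replace = TRUE)
    p <- stats::runif(n)
    probs <- cbind(P = p, ISO = 1 - p)
    cv <- roc_pr_curves(truth, probs)
    expect_equal(cv$per_class$P$auc_roc, 0.5, tolerance = 0.05)
    # PR area of an uninformative scorer approaches the class prevalence
    expect_equal(cv$per_class$P$auc_pr, mean(truth == "P"), tolerance = 0.05)
  })
})

test_that("areas agree with exhaustive threshold enumeration on tiny instances", {
  # brute-force oracle: try every threshold midpoint, build the staircase
  oracle_auc_roc <- function(truth, score) {
    ths <- sort(unique(score), decreasing = TRUE)
    pts <- data.frame(fpr = 0, tpr = 0)
    for (th in ths) {
      pred <- score >= th
      pts <- rbind(pts, data.frame(fpr = sum(pred & !truth) / sum(!truth),
                                   tpr = sum(pred & truth) / sum(truth)))
    }
    sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  }
  oracle_auc_pr <- function(truth, score) {
    ths <- sort(unique(score), decreasing = TRUE)
    rec_prev <- 0; area <- 0
    for (th in ths) {
      pred <- score >= th
      prec <- sum(pred & truth) / sum(pred)
      rec <- sum(pred & truth) / sum(truth)
      area <- area + (rec - rec_prev) * prec
      rec_prev <- rec
    }
    area
  }
  cases <- list(
    list(truth = c(1, 0, 1, 0), score = c(0.9, 0.8, 0.3, 0.1)),
    list(truth = c(1, 1, 0, 0), score = c(0.6, 0.6, 0.6, 0.2)),
    list(truth = c(0, 1, 0, 1), score = c(0.2, 0.4, 0.6, 0.8)))
  for (cs in cases) {
    probs <- cbind(P = cs$score, ISO = 1 - cs$score)
    labs <- ifelse(cs$truth == 1, "P", "ISO")
    cv <- roc_pr_curves(labs, probs)
    expect_equal(cv$per_class$P$auc_roc, oracle_auc_roc(cs$truth, cs$score))
    expect_equal(cv$per_class$P$auc_pr, oracle_auc_pr(cs$truth, cs$score))
  }
})

test_that("ROC area matches pROC and is invariant to monotone transforms", {
  withr::with_seed(17, {
    n <- 300
    truth <- sample(c("P", "ISO"), n, replace = TRUE, prob = c(0.3, 0.7))
    score <- stats::runif(n) + 0.5 * (truth == "P")
    probs <- cbind(P = score, ISO = 1 - score)
    # rescale rows to sum to 1
    probs <- probs / rowSums(probs)
    cv <- roc_pr_curves(truth, probs)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = as.integer(truth == "P"), predictor = probs[, "P"],
      direction = "<", quiet = TRUE)))
    expect_equal(cv$per_class$P$auc_roc, as.numeric(ref), tolerance = 1e-10)
    # strictly monotone transform of scores leaves the area unchanged
    probs2 <- cbind(P = probs[, "P"]^3, ISO = 1 - probs[, "P"]^3)
    cv2 <- roc_pr_curves(truth, probs2)
    expect_equal(cv2$per_class$P$auc_roc, cv$per_class$P$auc_roc)
  })
})

test_that("a class absent from the truth yields NA areas", {
  truth <- rep("ISO", 4)
  probs <- matrix(0.2, 4, 5, dimnames = list(NULL, ecg_classes()))
  cv <- roc_pr_curves(truth, probs)
  expect_true(is.na(cv$per_class$P$auc_roc))
  expect_true(is.na(cv$per_class$P$auc_pr))
})
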