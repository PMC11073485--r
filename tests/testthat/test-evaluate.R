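test_that("confusion metrics follow the printed formulas", {
  cm <- structure(list(TP = 5, FP = 5, TN = 0, FN = 0),
                  class = "if_confusion")
  m <- metrics(cm)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$accuracy, 0.5)

  none <- structure(list(TP = 0, FP = 3, TN = 7, FN = 0),
                    class = "if_confusion")
  expect_true(is.na(metrics(none)$sensitivity))
  expect_false(is.nan(metrics(none)$sensitivity))
})

test_that("confusion counting matches brute-force enumeration", {
  withr::local_seed(41)
  for (k in 1:25) {
    n <- sample(5:60, 1)
    pred <- stats::runif(n) < 0.5
    truth <- stats::runif(n) < 0.4
    cm <- confusion_matrix(pred, truth)
    expect_equal(cm$TP, sum(mapply(function(p, t) p && t, pred, truth)))
    expect_equal(cm$FN, sum(mapply(function(p, t) !p && t, pred, truth)))
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, n)
  }
})

test_that("ROC endpoints and tie conventions are correct", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  expect_equal(sep$roc_points$fpr[1], 0)
  expect_equal(utils::tail(sep$roc_points$tpr, 1), 1)

  ties <- roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "if_data_error")
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  withr::local_seed(19)
  for (k in 1:40) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    auc <- roc_auc(scores, labels)$auc
    pos <- scores[labels]; neg <- scores[!labels]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(29)
  scores <- stats::rnorm(50)
  labels <- stats::runif(50) < 0.45
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("LOOCV trains n models and ignores subject ordering", {
  withr::local_seed(37)
  n <- 12
  dat <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    omega1_bpm = c(stats::runif(6, 115, 140),
                                   stats::runif(6, 80, 100)),
                    omegai1 = stats::runif(n, 1, 1.8),
                    label = rep(c(TRUE, FALSE), each = 6))
  cv <- loocv(dat, c("omega1_bpm", "omegai1"))
  expect_equal(nrow(cv), n)
  expect_setequal(cv$subject_id, dat$subject_id)
  perm <- sample(n)
  cv2 <- loocv(dat[perm, ], c("omega1_bpm", "omegai1"))
  m <- match(cv$subject_id, cv2$subject_id)
  expect_equal(cv$score, cv2$score[m])
  expect_equal(cv$predicted, cv2$predicted[m])
})

test_that("a widely separated cohort is perfectly classified in and out of sample", {
  withr::local_seed(43)
  n <- 30
  dat <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    omega1_bpm = c(stats::rnorm(n / 2, 130, 2),
                                   stats::rnorm(n / 2, 90, 2)),
                    label = rep(c(TRUE, FALSE), each = n / 2))
  tree <- train_cart(dat, "omega1_bpm")
  expect_identical(predict(tree, dat)$label, dat$label)
  cv <- loocv(dat, "omega1_bpm")
  expect_identical(cv$predicted, cv$truth)
  rep <- screening_report(cv$score, cv$truth, cv$subject_id)
  expect_equal(rep$metrics$accuracy, 1)
  expect_equal(rep$auc, 1)
})

test_that("pooled ROC is invariant to monotone score transformations", {
  withr::local_seed(47)
  scores <- stats::runif(40)
  labels <- stats::runif(40) < 0.5
  if (any(labels) && !all(labels)) {
    a <- roc_auc(scores, labels)$auc
    b <- roc_auc(exp(3 * scores) - 1, labels)$auc
    expect_equal(a, b, tolerance = 1e-12)
  }
})
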