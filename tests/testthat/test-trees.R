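test_that("fixed rule A reproduces the published decision boundaries", {
  expect_equal(classify_fixed_tree_A(100, 10, -1.0)$label, "normal")
  expect_equal(classify_fixed_tree_A(120, 12, 0.0)$label, "low")
  expect_equal(classify_fixed_tree_A(120, 4, -0.8)$label, "low")
  expect_equal(classify_fixed_tree_A(120, 4, 0.0)$label, "normal")
  # below the frequency threshold age and phase are irrelevant
  expect_true(all(classify_fixed_tree_A(107.59, c(1, 6, 19),
                                        c(-2, 0, 2))$label == "normal"))
})

test_that("fixed rule B reproduces the published decision boundaries", {
  expect_equal(classify_fixed_tree_B(90, 1.7)$label, "low")
  expect_equal(classify_fixed_tree_B(150, 1.1)$label, "normal")
  expect_equal(classify_fixed_tree_B(110, 1.3)$label, "low")
  expect_equal(classify_fixed_tree_B(100, 1.3)$label, "normal")
})

test_that("the JSON rule fixtures agree with the hard-coded rules", {
  treeA <- load_fixed_tree("A")
  treeB <- load_fixed_tree("B")
  withr::local_seed(31)
  dat <- data.frame(
    omega1_bpm = c(stats::runif(300, 60, 160), 107.6, 107.6),
    age = c(stats::runif(300, 0, 21), 6, 5),
    phi1 = c(stats::runif(300, -1.5, 1), -0.65, -0.66),
    omegai1 = c(stats::runif(300, 0.8, 2), 1.6, 1.22))
  expect_identical(classify_rule_tree(treeA, dat),
                   classify_fixed_tree_A(dat$omega1_bpm, dat$age, dat$phi1)$label)
  expect_identical(classify_rule_tree(treeB, dat),
                   classify_fixed_tree_B(dat$omega1_bpm, dat$omegai1)$label)
})

test_that("a separable single-predictor cohort yields one clean split", {
  withr::local_seed(2)
  n <- 40
  dat <- data.frame(
    omega1_bpm = c(stats::runif(n / 2, 115, 140), stats::runif(n / 2, 80, 100)),
    label = rep(c(TRUE, FALSE), each = n / 2))
  tree <- train_cart(dat, "omega1_bpm")
  expect_equal(sum(!tree$leaf), 1)
  thr <- tree$threshold[!tree$leaf]
  expect_gt(thr, 100); expect_lt(thr, 115)
  pr <- predict(tree, dat)
  expect_identical(pr$label, dat$label)
  expect_true(audit_cart(tree))
})

test_that("nodes of ten or fewer samples are never split", {
  dat <- data.frame(omega1_bpm = 1:10, label = rep(c(TRUE, FALSE), 5))
  tree <- train_cart(dat, "omega1_bpm")
  expect_equal(sum(!tree$leaf), 0)
  expect_equal(nrow(tree), 1)
})

test_that("planted two-threshold structure is recovered inside the midpoint gaps", {
  withr::local_seed(17)
  dat <- planted_two_threshold_cohort()
  tree <- train_cart(dat, c("omega1_bpm", "omegai1"))
  expect_planted_recovery(tree, dat)
  # the root must be the exhaustive-search optimum on the same impurity
  best <- oracle_best_split(dat, c("omega1_bpm", "omegai1"))
  root <- tree[1, ]
  expect_equal(root$feature, best$f)
  expect_equal(root$threshold, best$thr)
})

test_that("single-class input trains a single-leaf tree with sane scores", {
  dat <- data.frame(omega1_bpm = stats::runif(20, 80, 120), label = FALSE)
  tree <- train_cart(dat, "omega1_bpm")
  expect_equal(nrow(tree), 1)
  pr <- predict(tree, data.frame(omega1_bpm = c(10, 200)))
  expect_identical(pr$label, c(FALSE, FALSE))
  expect_equal(pr$score, c(0, 0))
})

test_that("leaf scores are piecewise constant over the feature space", {
  withr::local_seed(23)
  dat <- data.frame(omega1_bpm = stats::runif(40, 80, 140),
                    label = stats::runif(40) < 0.4)
  tree <- train_cart(dat, "omega1_bpm")
  thr <- sort(tree$threshold[!tree$leaf])
  if (length(thr)) {
    probes <- data.frame(omega1_bpm = c(thr[1] - 0.2, thr[1] - 0.1))
    pr <- predict(tree, probes)
    expect_equal(pr$score[1], pr$score[2])
  }
  expect_true(audit_cart(tree))
})

test_that("trees survive a JSON round trip", {
  dat <- data.frame(omega1_bpm = c(stats::runif(20, 115, 140),
                                   stats::runif(20, 80, 100)),
                    label = rep(c(TRUE, FALSE), each = 20))
  tree <- train_cart(dat, "omega1_bpm")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, tmp)
  back <- read_tree_json(tmp)
  expect_equal(predict(back, dat), predict(tree, dat))
  expect_identical(attr(back, "predictors"), attr(tree, "predictors"))
})
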