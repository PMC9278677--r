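# Model fitting, prediction, evaluation metrics and importance.

sep_data <- function(n = 80, seed = 1) {
  # two well-separated clusters: f1 alone determines the class
  set.seed(seed)
  f1 <- c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3))
  data.frame(f1 = f1, f2 = rnorm(n), f3 = rnorm(n),
             y = factor(rep(c("FAIL", "PASS"), each = n / 2),
                        levels = c("FAIL", "PASS")))
}

test_that("AdaBoost separates planted clusters perfectly and ranks the
           informative feature first", {
  d <- sep_data()
  m <- gpr_model(y ~ f1 + f2 + f3, d, n_learners = 30, cv_folds = 3, seed = 1)
  expect_equal(m$method, "adaboost")
  expect_equal(as.character(predict(m, d)), as.character(d$y))
  expect_gt(m$cv$estimate, 0.95)
  imp <- feature_importance(m, top_k = 3)
  expect_equal(names(imp)[1], "f1")
  # a constant feature gets zero importance
  d$f4 <- 1
  m4 <- gpr_model(y ~ ., d, n_learners = 20, cv_folds = 0, seed = 1)
  expect_equal(unname(feature_importance(m4, top_k = 4)["f4"]), 0)
})

test_that("regression on a constant target predicts that constant", {
  set.seed(2)
  d <- data.frame(f1 = rnorm(40), f2 = rnorm(40), y = 95)
  # randomForest warns about the degenerate (constant) response; expected here
  m <- suppressWarnings(
    gpr_model(y ~ f1 + f2, d, n_learners = 50, cv_folds = 0, seed = 2))
  expect_equal(m$method, "bagging")
  expect_true(all(abs(predict(m, d) - 95) < 1e-9))
})

test_that("fits are deterministic under a fixed seed", {
  d <- sep_data(seed = 3)
  m1 <- gpr_model(y ~ ., d, n_learners = 25, cv_folds = 0, seed = 9)
  m2 <- gpr_model(y ~ ., d, n_learners = 25, cv_folds = 0, seed = 9)
  expect_identical(predict(m1, d, type = "score"), predict(m2, d, type = "score"))
  dr <- d; dr$y <- NULL; dr$g <- 90 + 2 * d$f1 + rnorm(nrow(d), sd = 0.1)
  r1 <- gpr_model(g ~ ., dr, n_learners = 100, cv_folds = 0, seed = 9)
  r2 <- gpr_model(g ~ ., dr, n_learners = 100, cv_folds = 0, seed = 9)
  expect_identical(predict(r1, dr), predict(r2, dr))
})

test_that("single-class input and missing feature columns are rejected", {
  d <- sep_data()
  d$y <- factor("PASS", levels = c("FAIL", "PASS"))
  expect_error(gpr_model(y ~ f1, d, seed = 1, cv_folds = 0), "2 classes")
  d2 <- sep_data()
  m <- gpr_model(y ~ f1 + f2, d2, n_learners = 10, cv_folds = 0, seed = 1)
  expect_error(predict(m, d2["f1"]), "lacks feature column.*f2")
})

test_that("regressor labels use the warning-level tie rule", {
  # predicted exactly at the level passes, just below fails
  expect_equal(as.character(label_gpr(c(96, 93.69, 93.70), 93.70)),
               c("PASS", "FAIL", "PASS"))
})

test_that("sensitivity and specificity follow the TP/FN and TN/FP forms", {
  ss <- sensitivity_specificity(c(TP = 16, FP = 0, TN = 37, FN = 1))
  expect_equal(unname(ss["sensitivity"]), 94.12)
  expect_equal(unname(ss["specificity"]), 100)
  ss <- sensitivity_specificity(c(TP = 0, FP = 2, TN = 3, FN = 5))
  expect_equal(unname(ss["sensitivity"]), 0)
  # empty positive class: sensitivity undefined, not zero
  ss <- sensitivity_specificity(c(TP = 0, FP = 1, TN = 3, FN = 0))
  expect_true(is.na(ss["sensitivity"]))
  expect_false(is.na(ss["specificity"]))
})

test_that("confusion counts treat FAIL as the positive class", {
  pred <- factor(c("FAIL", "FAIL", "PASS", "PASS"), c("FAIL", "PASS"))
  meas <- factor(c("FAIL", "PASS", "FAIL", "PASS"), c("FAIL", "PASS"))
  cm <- confusion_counts(pred, meas)
  expect_equal(unname(cm), c(1, 1, 1, 1))
  expect_equal(cm[["TP"]] + cm[["FN"]], sum(meas == "FAIL"))
  expect_equal(cm[["TN"]] + cm[["FP"]], sum(meas == "PASS"))
})

test_that("regression accuracy: RMSE and the +/-3 band with boundary", {
  acc <- regression_accuracy(c(95, 95), c(95, 95))
  expect_equal(unname(acc), c(0, 100))
  acc <- regression_accuracy(c(3, 5), c(1, 1))
  expect_equal(unname(acc["rmse"]), sqrt(10))
  expect_equal(unname(acc["pct_within"]), 50)
  # a difference of exactly 3 counts as within the band
  expect_equal(unname(regression_accuracy(98, 95)["pct_within"]), 100)
  expect_error(regression_accuracy(1:3, 1:2), "lengths differ")
})

test_that("raising the warning level never decreases measured FAILs", {
  set.seed(6)
  gpr <- runif(60, 88, 100)
  fails <- vapply(seq(90, 99, by = 0.5),
                  function(w) sum(label_gpr(gpr, w) == "FAIL"), numeric(1))
  expect_true(all(diff(fails) >= 0))
})

test_that("thresholded regressor labels match externally computed labels", {
  set.seed(7)
  d <- data.frame(f1 = rnorm(50), f2 = rnorm(50))
  d$g <- 94 + 2 * d$f1 + rnorm(50, sd = 0.3)
  m <- gpr_model(g ~ f1 + f2, d, n_learners = 60, cv_folds = 0, seed = 7)
  wl <- 94
  lab_direct <- predict(m, d, type = "label", warning_level = wl)
  lab_external <- label_gpr(predict(m, d), wl)
  expect_identical(lab_direct, lab_external)
  expect_error(predict(m, d, type = "label"), "warning_level")
})
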