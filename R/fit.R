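# GPR prediction models: discrete AdaBoost (SAMME) with shallow rpart trees
# for PASS/FAIL classification, and bagged regression trees (randomForest
# with mtry = p) for direct GPR regression.

#' Fit a GPR prediction model
#'
#' Fits an ensemble of trees predicting patient-specific QA outcome from the
#' 37 plan-complexity features.  A factor response gives the AdaBoost
#' PASS/FAIL classifier (discrete AdaBoost with shallow `rpart` trees,
#' learning rate 0.1, 500 learners by default); a numeric response gives the
#' bagged regression-tree model (500 bootstrap trees, minimum leaf size 8).
#' A k-fold cross-validation estimate of training performance is recorded
#' as an overfitting guard; the returned model is fit on all supplied rows.
#'
#' @param formula model formula, e.g. `label_2_2 ~ .` over the feature
#'   columns.
#' @param data data.frame holding the response and features (typically the
#'   training rows of a [build_dataset()] result).
#' @param method `"adaboost"` (classification) or `"bagging"` (regression);
#'   defaults by response type.
#' @param n_learners ensemble size (default 500).
#' @param learning_rate AdaBoost shrinkage on the learner weights
#'   (default 0.1; ignored by bagging, which has no learning rate).
#' @param min_leaf_size minimum observations per terminal node for the
#'   bagged regression trees (default 8).
#' @param max_depth depth cap for the AdaBoost weak learners (default 3).
#' @param cv_folds folds for the recorded cross-validation estimate
#'   (default 5; `0` skips it).
#' @param seed integer RNG seed (required: bootstrap resampling and fold
#'   assignment are stochastic).
#' @return Object of class `gpr_model`.
#' @examples
#' set.seed(1)
#' d <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
#' d$y <- 90 + 3 * d$f1 + rnorm(60, sd = 0.5)
#' m <- gpr_model(y ~ ., d, n_learners = 50, cv_folds = 3, seed = 1)
#' predict(m, d[1:3, ])
#' @export
gpr_model <- function(formula, data, method = NULL, n_learners = 500,
                      learning_rate = 0.1, min_leaf_size = 8, max_depth = 3,
                      cv_folds = 5, seed) {
  if (missing(seed)) stop("seed is required")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  if (!ncol(x)) stop("no predictor columns in formula")
  if (anyNA(x)) stop("missing values in the feature matrix")
  if (is.null(method)) method <- if (is.factor(y)) "adaboost" else "bagging"
  method <- match.arg(method, c("adaboost", "bagging"))
  if (method == "adaboost") {
    if (!is.factor(y)) y <- factor(y)
    y <- droplevels(y)
    if (nlevels(y) != 2)
      stop("AdaBoost classifier needs exactly 2 classes, got ", nlevels(y))
  } else {
    if (!is.numeric(y)) stop("bagging regression needs a numeric response")
    if (nrow(x) < max(cv_folds, 2)) stop("too few rows for ", cv_folds, "-fold CV")
  }

  fit_once <- function(xtr, ytr, sub_seed) {
    set.seed(sub_seed)
    if (method == "adaboost")
      fit_adaboost(xtr, ytr, n_learners, learning_rate, max_depth)
    else
      randomForest::randomForest(
        x = xtr, y = ytr, ntree = n_learners, mtry = ncol(xtr),
        nodesize = min_leaf_size, replace = TRUE)
  }
  pred_once <- function(fit, xte) {
    if (method == "adaboost") predict_adaboost(fit, xte)$label
    else as.numeric(stats::predict(fit, xte))
  }

  cv <- NULL
  if (cv_folds >= 2) {
    set.seed(seed + 1L)
    fold <- sample(rep_len(seq_len(cv_folds), nrow(x)))
    per_fold <- vapply(seq_len(cv_folds), function(k) {
      tr <- fold != k
      if (method == "adaboost" && nlevels(droplevels(y[tr])) < 2)
        return(NA_real_)
      f <- fit_once(x[tr, , drop = FALSE], y[tr], seed + 100L + k)
      p <- pred_once(f, x[!tr, , drop = FALSE])
      if (method == "adaboost") mean(p == y[!tr])
      else sqrt(mean((p - y[!tr])^2))
    }, numeric(1))
    cv <- list(folds = cv_folds,
               metric = if (method == "adaboost") "accuracy" else "rmse",
               per_fold = per_fold,
               estimate = mean(per_fold, na.rm = TRUE))
  }

  fit <- fit_once(x, y, seed)
  structure(list(
    method = method, fit = fit, feature_names = colnames(x),
    response = all.vars(formula)[1], levels = if (is.factor(y)) levels(y),
    n_learners = n_learners, learning_rate = learning_rate,
    min_leaf_size = min_leaf_size, max_depth = max_depth,
    cv = cv, seed = seed, call = match.call()
  ), class = "gpr_model")
}

# ---- discrete AdaBoost (SAMME) with rpart weak learners -------------------

fit_adaboost <- function(x, y, n_learners, learning_rate, max_depth) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  df <- data.frame(.y = y, x, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 4,
                               xval = 0, maxsurrogate = 0)
  for (m in seq_len(n_learners)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = ctrl)
    h <- stats::predict(tr, df, type = "class")
    miss <- h != y
    err <- sum(w[miss])
    if (err >= 0.5) break               # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    trees[[length(trees) + 1]] <- tr
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break             # perfect learner: ensemble saturated
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(trees)) stop("AdaBoost: no usable weak learner (degenerate data)")
  list(trees = trees, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, x) {
  score <- numeric(nrow(x))
  for (m in seq_along(fit$trees)) {
    h <- stats::predict(fit$trees[[m]], x, type = "class")
    score <- score + fit$alphas[m] * ifelse(h == fit$levels[2], 1, -1)
  }
  label <- factor(ifelse(score > 0, fit$levels[2], fit$levels[1]),
                  levels = fit$levels)
  list(label = label, score = score)
}

# ---- methods --------------------------------------------------------------

#' Predict from a fitted GPR model
#'
#' For the classifier, returns PASS/FAIL labels (`type = "label"`, default)
#' or the signed ensemble score.  For the regressor, returns predicted GPR
#' (`type = "response"`, default) or labels obtained by thresholding the
#' prediction at `warning_level` with the same tie rule as the dataset
#' labels (predicted GPR equal to the level passes).
#'
#' @param object a `gpr_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param type `"label"`, `"score"` or `"response"` (see above).
#' @param warning_level required when thresholding regression predictions.
#' @param ... unused.
#' @return Factor of labels, or numeric vector.
#' @export
predict.gpr_model <- function(object, newdata, type = NULL,
                              warning_level = NULL, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop("newdata lacks feature column(s): ", paste(miss, collapse = ", "))
  x <- newdata[, object$feature_names, drop = FALSE]
  if (object$method == "adaboost") {
    type <- if (is.null(type)) "label" else match.arg(type, c("label", "score"))
    p <- predict_adaboost(object$fit, x)
    if (type == "label") p$label else p$score
  } else {
    type <- if (is.null(type)) "response"
            else match.arg(type, c("response", "label"))
    p <- as.numeric(stats::predict(object$fit, x))
    if (type == "response") return(p)
    if (is.null(warning_level))
      stop("warning_level is required for type = \"label\"")
    label_gpr(p, warning_level)
  }
}

#' Per-feature importance of a fitted GPR model
#'
#' Mean impurity-based importance across the ensemble's trees: for AdaBoost,
#' the learner-weight-weighted sum of each `rpart` tree's variable
#' importance; for the bagged trees, the total decrease in node impurity
#' (residual sum of squares) from `randomForest`.  Scores are normalized to
#' sum to 1 over all features.
#'
#' @param model a `gpr_model`.
#' @param top_k number of top features to return (default 5); a value above
#'   the feature count returns the full ranking with a warning.
#' @return Named numeric vector, descending, length `min(top_k, p)`.
#' @export
feature_importance <- function(model, top_k = 5) {
  stopifnot(inherits(model, "gpr_model"))
  imp <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  if (model$method == "adaboost") {
    for (m in seq_along(model$fit$trees)) {
      vi <- model$fit$trees[[m]]$variable.importance
      if (!is.null(vi))
        imp[names(vi)] <- imp[names(vi)] + model$fit$alphas[m] * vi
    }
  } else {
    vi <- randomForest::importance(model$fit, type = 2)[, 1]
    imp[names(vi)] <- vi
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  if (top_k > length(imp)) {
    warning("top_k exceeds feature count; returning full ranking")
    top_k <- length(imp)
  }
  imp[seq_len(top_k)]
}

#' @export
print.gpr_model <- function(x, ...) {
  kind <- if (x$method == "adaboost")
    paste0("AdaBoost classification (", length(x$fit$trees),
           " learners, learning rate ", x$learning_rate,
           ", max depth ", x$max_depth, ")")
  else
    paste0("bagged regression trees (", x$n_learners,
           " learners, min leaf size ", x$min_leaf_size, ")")
  cat("GPR model: ", kind, "\n", sep = "")
  cat("  features: ", length(x$feature_names),
      "; response: ", x$response, "\n", sep = "")
  if (!is.null(x$cv))
    cat(sprintf("  %d-fold CV %s: %.4f\n", x$cv$folds, x$cv$metric,
                x$cv$estimate))
  invisible(x)
}

#' @export
summary.gpr_model <- function(object, top_k = 5, ...) {
  print(object)
  cat("  top features:\n")
  imp <- feature_importance(object, top_k)
  for (i in seq_along(imp))
    cat(sprintf("    %d. %-14s %.4f\n", i, names(imp)[i], imp[i]))
  invisible(object)
}

#' Plot the feature-importance ranking of a fitted model
#' @param x a `gpr_model`.
#' @param top_k number of features to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gpr_model <- function(x, top_k = 10, ...) {
  imp <- rev(feature_importance(x, min(top_k, length(x$feature_names))))
  op <- graphics::par(mar = c(4, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "normalized importance",
                    main = paste("GPR model:", x$method), ...)
  invisible(x)
}

#' @export
residuals.gpr_model <- function(object, newdata, observed, ...) {
  if (object$method != "bagging")
    stop("residuals are defined for the regression model only")
  observed - predict(object, newdata)
}
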