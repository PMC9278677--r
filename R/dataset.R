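# Dataset assembly: per-arc feature extraction, institutional warning
# levels, PASS/FAIL labels, and the plan-level train/test split.

#' Feature column names (37 features)
#'
#' 32 kinematic features (16 per leaf bank) followed by the 5 fluence
#' texture features.
#' @return Character vector of length 37.
#' @export
feature_names <- function()
  c(kin_feature_names("A"), kin_feature_names("B"),
    "Contrast", "Correlation", "Energy", "Entropy", "Homogeneity")

#' Extract the 37 per-arc complexity features
#'
#' For each arc of each plan: the 32 kinematic features
#' ([kinematic_features()]) and the 5 GLCM texture features of the
#' integrated fluence map ([arc_texture_features()]).
#'
#' @param plans list of `vmat_plan` objects.
#' @param spacing fluence pixel size, mm (default 1).
#' @param gray_levels GLCM quantization levels (default 256).
#' @param all_leaves include parked leaf pairs in kinematics.
#' @return data.frame: `plan_id`, `arc_id`, then the 37 feature columns.
#' @export
extract_features <- function(plans, spacing = 1, gray_levels = 256,
                             all_leaves = FALSE) {
  rows <- list()
  for (plan in plans) for (arc in plan$arcs) {
    kin <- kinematic_features(arc, all_leaves = all_leaves)
    tex <- arc_texture_features(arc, spacing = spacing,
                                gray_levels = gray_levels)
    rows[[length(rows) + 1]] <-
      cbind(data.frame(plan_id = plan$plan_id, arc_id = arc$arc_id,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(c(kin, tex))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Institutional warning level
#'
#' The historical mean GPR.  Using the mean (rather than a universal
#' tolerance) centres the PASS/FAIL split near 50/50, which keeps the
#' failure class populated and the classifier sensitive.
#'
#' @param historical_gpr non-empty numeric GPR series (percent).
#' @return The arithmetic mean (percent).
#' @export
warning_level <- function(historical_gpr) {
  if (!length(historical_gpr)) stop("empty historical GPR series")
  mean(historical_gpr)
}

#' PASS/FAIL label against a warning level
#'
#' PASS when GPR is greater than or equal to the warning level (ties pass);
#' FAIL otherwise.
#'
#' @param gpr numeric GPR (percent).
#' @param warning warning level (percent).
#' @return Factor with levels `FAIL`, `PASS` (`PASS` = 1, `FAIL` = 0 in the
#'   0/1 coding).
#' @export
label_gpr <- function(gpr, warning) {
  factor(ifelse(gpr >= warning, "PASS", "FAIL"), levels = c("FAIL", "PASS"))
}

#' Plan-level train/test split
#'
#' Randomly assigns `round(fraction * n_plans)` plans to training; every arc
#' inherits its plan's assignment, so no plan straddles the boundary
#' (plan arcs are correlated and would otherwise leak).
#'
#' @param plan_ids character vector of unique plan identifiers.
#' @param fraction training fraction in (0, 1), default 0.8.
#' @param seed integer RNG seed (mandatory, for reproducibility).
#' @return Named character vector (`"train"`/`"test"`) indexed by plan id.
#' @export
split_train_test <- function(plan_ids, fraction = 0.8, seed) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (missing(seed)) stop("seed is required")
  plan_ids <- unique(plan_ids)
  if (length(plan_ids) < 2) stop("need at least 2 plans to split")
  n_train <- round(fraction * length(plan_ids))
  set.seed(seed)
  train <- sample(plan_ids, n_train)
  out <- ifelse(plan_ids %in% train, "train", "test")
  names(out) <- plan_ids
  out
}

#' Assemble the labelled modelling dataset
#'
#' Joins the feature table with the QA table, labels each arc PASS/FAIL at
#' each gamma criterion against its warning level, and assigns the
#' plan-level split.  Arcs missing a QA record are dropped with a message.
#' Warning levels default to the mean of the supplied historical series
#' (or of the QA table itself when no history is given).
#'
#' @param features data.frame from [extract_features()].
#' @param qa data.frame from [read_qa_table()].
#' @param history optional data.frame with historical `gpr_2_2`, `gpr_3_2`
#'   columns used for the warning levels (and, upstream, the control chart).
#' @param fraction training fraction for [split_train_test()].
#' @param seed integer RNG seed.
#' @return Object of class `qa_dataset`: list with `data` (features + gpr +
#'   labels + split), `warning_levels`, `feature_names`, `seed`.
#' @export
build_dataset <- function(features, qa, history = NULL, fraction = 0.8, seed) {
  merged <- merge(features, qa, by = c("plan_id", "arc_id"))
  n_miss <- nrow(features) - nrow(merged)
  if (n_miss > 0)
    message(n_miss, " arc(s) without a QA record dropped")
  if (!nrow(merged)) stop("no arcs with both features and QA records")
  hist2 <- if (!is.null(history)) history$gpr_2_2 else merged$gpr_2_2
  hist3 <- if (!is.null(history)) history$gpr_3_2 else merged$gpr_3_2
  wl <- c(gpr_2_2 = warning_level(hist2), gpr_3_2 = warning_level(hist3))
  merged$label_2_2 <- label_gpr(merged$gpr_2_2, wl["gpr_2_2"])
  merged$label_3_2 <- label_gpr(merged$gpr_3_2, wl["gpr_3_2"])
  split <- split_train_test(merged$plan_id, fraction, seed)
  merged$split <- unname(split[merged$plan_id])
  miss_f <- setdiff(feature_names(), names(merged))
  if (length(miss_f))
    stop("feature table lacks column(s): ", paste(miss_f, collapse = ", "))
  if (anyNA(merged[feature_names()]))
    stop("missing values in the feature matrix")
  structure(list(data = merged, warning_levels = wl,
                 feature_names = feature_names(), seed = seed),
            class = "qa_dataset")
}

#' @export
print.qa_dataset <- function(x, ...) {
  d <- x$data
  cat("QA modelling dataset: ", nrow(d), " arcs / ",
      length(unique(d$plan_id)), " plans (",
      sum(d$split == "train"), " train / ", sum(d$split == "test"),
      " test arcs)\n", sep = "")
  cat(sprintf("  warning levels: %.2f%% (2%%/2mm), %.2f%% (3%%/2mm)\n",
              x$warning_levels["gpr_2_2"], x$warning_levels["gpr_3_2"]))
  invisible(x)
}

#' PASS/FAIL class balance of a dataset slice
#'
#' @param dataset a `qa_dataset`.
#' @param criterion `"gpr_2_2"` or `"gpr_3_2"`.
#' @param split `"train"`, `"test"` or `"all"`.
#' @return List with `pass_pct`, `fail_pct` (percent, 2 decimals) and
#'   `counts` (named PASS/FAIL counts).
#' @export
class_balance <- function(dataset, criterion = c("gpr_2_2", "gpr_3_2"),
                          split = c("train", "test", "all")) {
  criterion <- match.arg(criterion)
  split <- match.arg(split)
  d <- dataset$data
  if (split != "all") d <- d[d$split == split, , drop = FALSE]
  if (!nrow(d)) stop("empty split: ", split)
  lab <- d[[if (criterion == "gpr_2_2") "label_2_2" else "label_3_2"]]
  counts <- table(lab)
  list(pass_pct = round(100 * counts[["PASS"]] / length(lab), 2),
       fail_pct = round(100 * counts[["FAIL"]] / length(lab), 2),
       counts = c(PASS = counts[["PASS"]], FAIL = counts[["FAIL"]]))
}
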