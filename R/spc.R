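# Individuals (I-chart) statistical process control for historical GPR
# series: center line, mean moving range, and the lower control limit used
# to drop out-of-control QA records before modelling.

#' Mean moving range of a series
#'
#' `mR = (1 / (n - 1)) * sum_{i=2..n} |x_i - x_{i-1}|` — the average absolute
#' difference of successive observations.
#'
#' @param x numeric series (GPR percent), `n >= 2`.
#' @return The mean moving range.
#' @export
mean_moving_range <- function(x) {
  if (length(x) < 2) stop("moving range needs at least 2 observations")
  mean(abs(diff(x)))
}

#' Individuals control chart for a GPR series
#'
#' Center line is the series mean; the lower control limit is
#' `center - 2.66 * mR` with `mR` the mean moving range (2.66 = 3 / d2 for
#' the moving range of two observations).  The upper limit
#' `center + 2.66 * mR` is computed for completeness but is not used for
#' filtering (QA failures are one-sided: low GPR).
#'
#' @param x numeric GPR series (percent), `n >= 2`.
#' @return Object of class `gpr_ichart`: list with `center_line`,
#'   `mean_moving_range`, `lower_control_limit`, `upper_control_limit`, `n`.
#' @export
control_chart <- function(x) {
  mr <- mean_moving_range(x)
  cl <- mean(x)
  structure(list(
    center_line = cl,
    mean_moving_range = mr,
    lower_control_limit = cl - 2.66 * mr,
    upper_control_limit = cl + 2.66 * mr,
    n = length(x)
  ), class = "gpr_ichart")
}

#' @export
print.gpr_ichart <- function(x, digits = 4, ...) {
  cat("Individuals chart (n = ", x$n, ")\n",
      "  center line : ", round(x$center_line, digits), "\n",
      "  mean mR     : ", round(x$mean_moving_range, digits), "\n",
      "  LCL         : ", round(x$lower_control_limit, digits), "\n",
      "  UCL         : ", round(x$upper_control_limit, digits), "\n", sep = "")
  invisible(x)
}

#' Remove out-of-control QA records
#'
#' A record is out of control when its GPR falls strictly below the chart's
#' lower control limit (records exactly at the limit are retained).  By
#' default removal cascades to the plan: when any arc of a plan is out of
#' control the whole plan is removed, since its arcs share a delivery and
#' measurement session; `level = "arc"` removes only the offending arcs.
#'
#' @param qa data.frame with `plan_id`, `arc_id` and the GPR column.
#' @param chart a `gpr_ichart` built from the same criterion's GPR.
#' @param criterion `"gpr_2_2"` or `"gpr_3_2"`: which column to test.
#' @param level `"plan"` (default) or `"arc"` removal granularity.
#' @return List with `retained` and `removed` data.frames and the `chart`.
#' @export
filter_out_of_control <- function(qa, chart,
                                  criterion = c("gpr_2_2", "gpr_3_2"),
                                  level = c("plan", "arc")) {
  criterion <- match.arg(criterion)
  level <- match.arg(level)
  ooc <- qa[[criterion]] < chart$lower_control_limit
  if (level == "plan") {
    bad_plans <- unique(qa$plan_id[ooc])
    drop <- qa$plan_id %in% bad_plans
  } else {
    drop <- ooc
  }
  list(retained = qa[!drop, , drop = FALSE],
       removed = qa[drop, , drop = FALSE],
       chart = chart)
}
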