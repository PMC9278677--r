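#' Read a plan from the portable JSON exchange format
#'
#' The exchange document mirrors the in-memory model:
#' \preformatted{
#' {"plan_id": ..., "arcs": [{"arc_id", "arc_mu", "gantry_speed_deg_s",
#'   "cp_interval_deg", "leaf_widths_mm": [...],
#'   "control_points": [{"gantry_deg", "mu_fraction",
#'     "bankA_mm": [...], "bankB_mm": [...],
#'     "jaw_x_mm": [x1, x2], "jaw_y_mm": [y1, y2]}]}]}
#' }
#' Jaw fields are optional.  Schema violations raise an error carrying a
#' JSON-pointer-style path to the offending field.
#'
#' @param path path to a JSON plan document.
#' @return A validated [vmat_plan()].
#' @seealso [write_simple_plan()], [read_dicom_plan()]
#' @export
read_simple_plan <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(x, field, ptr) {
    if (is.null(x[[field]]))
      stop("plan schema violation at ", ptr, "/", field, ": field missing")
    x[[field]]
  }
  plan_id <- need(doc, "plan_id", "")
  arcs_doc <- need(doc, "arcs", "")
  if (length(arcs_doc) < 1) stop("plan schema violation at /arcs: empty")
  arcs <- lapply(seq_along(arcs_doc), function(ai) {
    aptr <- paste0("/arcs/", ai - 1)
    a <- arcs_doc[[ai]]
    lw <- as.numeric(unlist(need(a, "leaf_widths_mm", aptr)))
    cps_doc <- need(a, "control_points", aptr)
    cps <- lapply(seq_along(cps_doc), function(ci) {
      cptr <- paste0(aptr, "/control_points/", ci - 1)
      cp <- cps_doc[[ci]]
      bA <- as.numeric(unlist(need(cp, "bankA_mm", cptr)))
      bB <- as.numeric(unlist(need(cp, "bankB_mm", cptr)))
      if (length(bA) != length(lw))
        stop("plan schema violation at ", cptr,
             "/bankA_mm: length ", length(bA),
             " does not match leaf_widths_mm length ", length(lw))
      control_point(
        index = ci - 1L,
        gantry_angle = as.numeric(need(cp, "gantry_deg", cptr)),
        mu_fraction = as.numeric(need(cp, "mu_fraction", cptr)),
        bankA = bA, bankB = bB,
        jaw_x = if (!is.null(cp$jaw_x_mm)) as.numeric(unlist(cp$jaw_x_mm)),
        jaw_y = if (!is.null(cp$jaw_y_mm)) as.numeric(unlist(cp$jaw_y_mm))
      )
    })
    vmat_arc(
      arc_id = need(a, "arc_id", aptr),
      control_points = cps,
      arc_mu = as.numeric(need(a, "arc_mu", aptr)),
      leaf_widths = lw,
      gantry_speed = if (!is.null(a$gantry_speed_deg_s))
        as.numeric(a$gantry_speed_deg_s) else NA_real_,
      cp_interval = if (!is.null(a$cp_interval_deg))
        as.numeric(a$cp_interval_deg) else NA_real_
    )
  })
  vmat_plan(plan_id, arcs)
}

#' Write a plan to the portable JSON exchange format
#'
#' @param plan a `vmat_plan`.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_simple_plan <- function(plan, path) {
  doc <- list(
    plan_id = jsonlite::unbox(plan$plan_id),
    arcs = lapply(plan$arcs, function(a) {
      list(
        arc_id = jsonlite::unbox(a$arc_id),
        arc_mu = jsonlite::unbox(a$arc_mu),
        gantry_speed_deg_s = jsonlite::unbox(a$gantry_speed),
        cp_interval_deg = jsonlite::unbox(a$cp_interval),
        leaf_widths_mm = a$leaf_widths,
        control_points = lapply(a$control_points, function(cp) {
          out <- list(
            gantry_deg = jsonlite::unbox(cp$gantry_angle),
            mu_fraction = jsonlite::unbox(cp$mu_fraction),
            bankA_mm = cp$bankA,
            bankB_mm = cp$bankB
          )
          if (!is.null(cp$jaw_x)) out$jaw_x_mm <- cp$jaw_x
          if (!is.null(cp$jaw_y)) out$jaw_y_mm <- cp$jaw_y
          out
        })
      )
    })
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a per-arc QA results table
#'
#' Expects a CSV with header `plan_id,arc_id,gpr_2_2,gpr_3_2`: measured gamma
#' passing rates (percent) at the 2%/2 mm and 3%/2 mm criteria (10% dose
#' threshold) for each arc.
#'
#' @param path CSV file path.
#' @return A data.frame with one row per arc and those four columns.
#' @export
read_qa_table <- function(path) {
  qa <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plan_id", "arc_id", "gpr_2_2", "gpr_3_2")
  miss <- setdiff(need, names(qa))
  if (length(miss))
    stop("QA table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("gpr_2_2", "gpr_3_2")) {
    v <- qa[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 100)
    if (length(bad))
      stop("QA table row ", bad[1], ": ", col, " = ", v[bad[1]],
           " outside [0, 100]")
  }
  qa[need]
}

#' Write a per-arc QA results table
#' @param qa data.frame as returned by [read_qa_table()].
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_qa_table <- function(qa, path) {
  utils::write.csv(qa, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
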