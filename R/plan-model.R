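#' Construct a VMAT control point
#'
#' A control point is one snapshot of the delivery: gantry angle, cumulative
#' monitor-unit (MU) fraction, and the positions of the two opposing MLC leaf
#' banks.  Positions are signed millimetres at the isocenter plane along the
#' leaf-travel (x) axis; an aperture is open where bank B sits to the right of
#' bank A (`bankB >= bankA`, equality meaning a closed pair).
#'
#' @param index integer control-point index (0-based, strictly increasing
#'   within an arc).
#' @param gantry_angle gantry angle in degrees.
#' @param mu_fraction cumulative MU fraction in `[0, 1]`.
#' @param bankA,bankB numeric vectors of leaf positions (mm), one per leaf
#'   pair; bank A is the lower (negative-travel) bank.
#' @param jaw_x,jaw_y optional length-2 numeric `(lo, hi)` jaw positions (mm),
#'   or `NULL` when the jaws are not recorded.
#' @return An object of class `vmat_control_point`.
#' @export
control_point <- function(index, gantry_angle, mu_fraction, bankA, bankB,
                          jaw_x = NULL, jaw_y = NULL) {
  cp <- structure(list(
    index = as.integer(index),
    gantry_angle = as.numeric(gantry_angle),
    mu_fraction = as.numeric(mu_fraction),
    bankA = as.numeric(bankA),
    bankB = as.numeric(bankB),
    jaw_x = if (!is.null(jaw_x)) as.numeric(jaw_x),
    jaw_y = if (!is.null(jaw_y)) as.numeric(jaw_y)
  ), class = "vmat_control_point")
  cp
}

#' Construct a VMAT arc
#'
#' @param arc_id character arc identifier, unique within a plan.
#' @param control_points list of [control_point()] objects in delivery order.
#' @param arc_mu total monitor units delivered by the arc.
#' @param leaf_widths numeric vector of per-pair physical leaf widths (mm at
#'   isocenter); its length fixes the leaf-pair count.
#' @param gantry_speed gantry rotation speed, deg/s.  If `NA`, a machine
#'   default of 4.8 deg/s is assumed downstream.
#' @param cp_interval control-point angular spacing, degrees.  If `NA` it is
#'   derived from the mean absolute difference of consecutive gantry angles.
#' @param validate run [validate_arc()] (default `TRUE`).
#' @return An object of class `vmat_arc`.
#' @export
vmat_arc <- function(arc_id, control_points, arc_mu, leaf_widths,
                     gantry_speed = NA_real_, cp_interval = NA_real_,
                     validate = TRUE) {
  arc <- structure(list(
    arc_id = as.character(arc_id),
    control_points = control_points,
    arc_mu = as.numeric(arc_mu),
    leaf_widths = as.numeric(leaf_widths),
    gantry_speed = as.numeric(gantry_speed),
    cp_interval = as.numeric(cp_interval)
  ), class = "vmat_arc")
  if (is.na(arc$cp_interval)) {
    ang <- vapply(control_points, function(cp) cp$gantry_angle, numeric(1))
    if (length(ang) >= 2) {
      d <- abs(diff(ang))
      d <- pmin(d, 360 - d)  # wrap through 0/360
      arc$cp_interval <- mean(d)
    }
  }
  if (is.na(arc$gantry_speed)) arc$gantry_speed <- 4.8
  if (validate) validate_arc(arc)
  arc
}

#' Construct a VMAT plan
#'
#' @param plan_id character plan identifier.
#' @param arcs list of [vmat_arc()] objects (2-4 arcs typical for head and
#'   neck VMAT).
#' @param beam_energy nominal beam energy, MV (metadata only).
#' @param site treatment site label (metadata only).
#' @return An object of class `vmat_plan`.
#' @export
vmat_plan <- function(plan_id, arcs, beam_energy = 6, site = "head-neck") {
  stopifnot(length(arcs) >= 1)
  ids <- vapply(arcs, function(a) a$arc_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate arc_id within plan '", plan_id, "': ",
         paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(
    plan_id = as.character(plan_id),
    arcs = arcs,
    beam_energy = beam_energy,
    site = site
  ), class = "vmat_plan")
}

#' Validate an arc against the delivery invariants
#'
#' Checks: at least two control points with strictly increasing indices;
#' equal bank lengths matching the leaf-pair count; no bank collision
#' (`bankB >= bankA` for every pair, with a small numeric tolerance);
#' cumulative MU fraction non-decreasing, starting at 0 and ending at 1;
#' positive leaf widths.
#'
#' @param arc a `vmat_arc`.
#' @param tol numeric tolerance for the collision and MU-endpoint checks.
#' @return `invisible(TRUE)`; stops with an informative error on violation.
#' @export
validate_arc <- function(arc, tol = 1e-6) {
  cps <- arc$control_points
  if (length(cps) < 2)
    stop("arc '", arc$arc_id, "': needs >= 2 control points")
  idx <- vapply(cps, function(cp) cp$index, integer(1))
  if (any(diff(idx) <= 0))
    stop("arc '", arc$arc_id, "': control point indices not strictly increasing")
  npairs <- length(arc$leaf_widths)
  if (any(arc$leaf_widths <= 0))
    stop("arc '", arc$arc_id, "': leaf widths must all be positive")
  for (cp in cps) {
    if (length(cp$bankA) != npairs || length(cp$bankB) != npairs)
      stop("arc '", arc$arc_id, "' CP ", cp$index,
           ": bank lengths (", length(cp$bankA), ", ", length(cp$bankB),
           ") do not match leaf pair count ", npairs)
    bad <- which(cp$bankB < cp$bankA - tol)
    if (length(bad))
      stop("arc '", arc$arc_id, "' CP ", cp$index,
           ": bank collision (bankB < bankA) at leaf pair ", bad[1])
  }
  mu <- vapply(cps, function(cp) cp$mu_fraction, numeric(1))
  drop <- which(diff(mu) < -tol)
  if (length(drop))
    stop("arc '", arc$arc_id, "': cumulative MU fraction decreases at CP ",
         idx[drop[1] + 1])
  if (abs(mu[1]) > tol || abs(mu[length(mu)] - 1) > tol)
    stop("arc '", arc$arc_id, "': cumulative MU fraction must run from 0 to 1 (got ",
         signif(mu[1], 6), " .. ", signif(mu[length(mu)], 6), ")")
  invisible(TRUE)
}

#' Validate every arc of a plan
#' @param plan a `vmat_plan`.
#' @return `invisible(TRUE)`.
#' @export
validate_plan <- function(plan) {
  for (arc in plan$arcs) validate_arc(arc)
  invisible(TRUE)
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat("VMAT plan '", x$plan_id, "': ", length(x$arcs), " arc(s), ",
      x$beam_energy, " MV, site ", x$site, "\n", sep = "")
  for (a in x$arcs)
    cat("  arc '", a$arc_id, "': ", length(a$control_points), " CPs, ",
        length(a$leaf_widths), " leaf pairs, ", a$arc_mu, " MU\n", sep = "")
  invisible(x)
}

#' @export
print.vmat_arc <- function(x, ...) {
  cat("VMAT arc '", x$arc_id, "': ", length(x$control_points), " CPs, ",
      length(x$leaf_widths), " leaf pairs, ", x$arc_mu, " MU, ",
      "gantry ", x$gantry_speed, " deg/s, CP interval ",
      signif(x$cp_interval, 5), " deg\n", sep = "")
  invisible(x)
}

# Leaf-pair y extents (mm) from the widths, centred on y = 0.
leaf_pair_bounds <- function(leaf_widths) {
  edges <- cumsum(c(0, leaf_widths)) - sum(leaf_widths) / 2
  cbind(lo = edges[-length(edges)], hi = edges[-1])
}

# Matrix [cp x pair] of bank positions for one arc.
bank_matrix <- function(arc, bank = c("A", "B")) {
  bank <- match.arg(bank)
  fld <- if (bank == "A") "bankA" else "bankB"
  do.call(rbind, lapply(arc$control_points, `[[`, fld))
}

mu_fractions <- function(arc)
  vapply(arc$control_points, function(cp) cp$mu_fraction, numeric(1))
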