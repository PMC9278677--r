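# Fluence-map reconstruction: MU-weighted accumulation of the open MLC
# aperture over control-point intervals, on a regular grid at the isocenter
# plane.  x is the leaf-travel axis, y runs across the leaf pairs.

#' Define the fluence grid for an arc
#'
#' A regular pixel grid covering the union bounding box of all apertures
#' (leaf openings clipped by the jaws where present), padded on every side.
#' Rows (y) follow the leaf-pair layout; columns (x) follow leaf travel.
#'
#' @param arc a `vmat_arc`.
#' @param spacing pixel size, mm (default 1).
#' @param pad padding around the aperture bounding box, mm (default 5).
#' @return List with `x`, `y` (pixel-centre coordinates, mm), `spacing`, and
#'   `origin` (grid corner).
#' @export
fluence_grid <- function(arc, spacing = 1, pad = 5) {
  A <- bank_matrix(arc, "A"); B <- bank_matrix(arc, "B")
  open <- B > A
  if (!any(open)) {  # degenerate: fully closed arc
    xr <- c(-spacing, spacing)
  } else {
    xr <- range(A[open], B[open])
  }
  b <- leaf_pair_bounds(arc$leaf_widths)
  rows_open <- apply(open, 2, any)
  yr <- if (any(rows_open))
    range(b[rows_open, , drop = FALSE]) else c(-spacing, spacing)
  jy <- lapply(arc$control_points, `[[`, "jaw_y")
  jy <- Filter(Negate(is.null), jy)
  if (length(jy)) {
    yr[1] <- max(yr[1], min(vapply(jy, `[`, numeric(1), 1)))
    yr[2] <- min(yr[2], max(vapply(jy, `[`, numeric(1), 2)))
  }
  xr <- xr + c(-pad, pad); yr <- yr + c(-pad, pad)
  x <- seq(xr[1] + spacing / 2, xr[2], by = spacing)
  y <- seq(yr[1] + spacing / 2, yr[2], by = spacing)
  list(x = x, y = y, spacing = spacing, origin = c(xr[1], yr[1]))
}

# fraction of each pixel column [x - s/2, x + s/2] covered by [a, b]
coverage_1d <- function(x, spacing, a, b) {
  lo <- pmax(x - spacing / 2, a)
  hi <- pmin(x + spacing / 2, b)
  pmax(hi - lo, 0) / spacing
}

#' Fluence contribution of one control-point interval
#'
#' The aperture is taken from the interval's starting control point: each
#' leaf-pair row is open between the bank-A and bank-B positions, clipped by
#' the x jaws; rows outside the y jaws are closed.  The map is the aperture
#' indicator weighted by the interval's MU increment; pixels partially
#' covered along the leaf-travel axis get the covered fraction.
#'
#' @param cp_from,cp_to consecutive control points of `arc`.
#' @param arc the parent `vmat_arc`.
#' @param grid grid from [fluence_grid()].
#' @return Matrix `[y x x]` (rows = leaf-travel-transverse axis) of
#'   MU-fraction-weighted open-beam fraction.
#' @export
cp_aperture_fluence <- function(cp_from, cp_to, arc, grid) {
  dmu <- cp_to$mu_fraction - cp_from$mu_fraction
  if (dmu < -1e-9)
    stop("negative MU increment between CP ", cp_from$index,
         " and CP ", cp_to$index)
  map <- matrix(0, nrow = length(grid$y), ncol = length(grid$x))
  if (dmu <= 0) return(map)
  a <- cp_from$bankA; b <- cp_from$bankB
  if (!is.null(cp_from$jaw_x)) {
    a <- pmax(a, cp_from$jaw_x[1]); b <- pmin(b, cp_from$jaw_x[2])
  }
  bounds <- leaf_pair_bounds(arc$leaf_widths)
  # map grid rows to leaf pairs by pixel-centre y
  pair_of_row <- findInterval(grid$y, c(bounds[, "lo"], bounds[nrow(bounds), "hi"]))
  pair_of_row[grid$y >= bounds[nrow(bounds), "hi"]] <- 0L
  if (!is.null(cp_from$jaw_y))
    pair_of_row[grid$y < cp_from$jaw_y[1] | grid$y > cp_from$jaw_y[2]] <- 0L
  open_pairs <- which(b > a)
  rows <- which(pair_of_row %in% open_pairs)
  if (!length(rows)) return(map)
  # per-pair coverage profile along x, then spread to that pair's rows
  for (p in unique(pair_of_row[rows])) {
    cov <- coverage_1d(grid$x, grid$spacing, a[p], b[p])
    rr <- rows[pair_of_row[rows] == p]
    map[rr, ] <- matrix(dmu * cov, nrow = length(rr), ncol = length(grid$x),
                        byrow = TRUE)
  }
  map
}

#' Integrated intensity fluence map of an arc
#'
#' Accumulates [cp_aperture_fluence()] over every consecutive control-point
#' pair.  The result is the per-arc fluence map from which the GLCM texture
#' features are computed.
#'
#' @param arc a `vmat_arc`.
#' @param spacing pixel size, mm.
#' @param pad bounding-box padding, mm.
#' @param grid optional precomputed grid.
#' @return Object of class `fluence_map`: list with `intensity` (matrix
#'   `[y x x]`), `x`, `y`, `spacing`, `origin`.
#' @export
integrate_fluence <- function(arc, spacing = 1, pad = 5, grid = NULL) {
  if (is.null(grid)) grid <- fluence_grid(arc, spacing, pad)
  cps <- arc$control_points
  ncp <- length(cps)
  nx <- length(grid$x); ny <- length(grid$y)
  total <- matrix(0, nrow = ny, ncol = nx)
  mu <- mu_fractions(arc)
  dmu <- diff(mu)
  if (any(dmu < -1e-9)) stop("negative MU increment in arc '", arc$arc_id, "'")
  # apertures come from each interval's starting control point
  A <- bank_matrix(arc, "A")[-ncp, , drop = FALSE]   # [interval x pair]
  B <- bank_matrix(arc, "B")[-ncp, , drop = FALSE]
  for (i in seq_len(ncp - 1)) {
    jx <- cps[[i]]$jaw_x
    if (!is.null(jx)) {
      A[i, ] <- pmax(A[i, ], jx[1]); B[i, ] <- pmin(B[i, ], jx[2])
    }
  }
  bounds <- leaf_pair_bounds(arc$leaf_widths)
  pair_of_row <- findInterval(grid$y,
                              c(bounds[, "lo"], bounds[nrow(bounds), "hi"]))
  pair_of_row[grid$y >= bounds[nrow(bounds), "hi"]] <- 0L
  # per-interval y-jaw openness is resolved per grid row below
  jy <- lapply(cps[-ncp], `[[`, "jaw_y")
  jlo <- vapply(jy, function(j) if (is.null(j)) -Inf else j[1], numeric(1))
  jhi <- vapply(jy, function(j) if (is.null(j)) Inf else j[2], numeric(1))
  xlo <- matrix(grid$x - spacing / 2, nrow = ncp - 1, ncol = nx, byrow = TRUE)
  xhi <- xlo + spacing
  for (p in seq_len(ncol(A))) {
    rows <- which(pair_of_row == p)
    if (!length(rows)) next
    open <- B[, p] > A[, p] & dmu > 0
    if (!any(open)) next
    cov <- (pmin(xhi, B[, p]) - pmax(xlo, A[, p])) / spacing
    cov[cov < 0] <- 0
    cov[!open, ] <- 0
    for (r in rows) {
      w <- dmu
      w[grid$y[r] < jlo | grid$y[r] > jhi] <- 0
      total[r, ] <- total[r, ] + as.vector(w %*% cov)
    }
  }
  structure(list(intensity = total, x = grid$x, y = grid$y,
                 spacing = grid$spacing, origin = grid$origin),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat("fluence map: ", nrow(x$intensity), " x ", ncol(x$intensity),
      " pixels at ", x$spacing, " mm, total intensity ",
      signif(sum(x$intensity), 6), "\n", sep = "")
  invisible(x)
}

#' Display a fluence map
#' @param x a `fluence_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.fluence_map <- function(x, ...) {
  graphics::image(x$x, x$y, t(x$intensity), xlab = "x (mm)", ylab = "y (mm)",
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}
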