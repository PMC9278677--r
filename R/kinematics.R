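# MLC kinematics: per-interval leaf speeds/accelerations and the 32 per-bank
# summary features (max/mean/SD and bin-occupancy fractions).

#' Time between consecutive control points
#'
#' For a VMAT arc delivered at constant gantry speed the control points are
#' equally spaced in angle, so one interval lasts `cp_interval / gantry_speed`
#' seconds (e.g. 2.0341 deg at 4.8 deg/s gives 0.424 s).
#'
#' @param gantry_speed gantry rotation speed, deg/s (> 0).
#' @param cp_interval control-point angular spacing, degrees (> 0).
#' @return Interval duration in seconds.
#' @export
cp_time <- function(gantry_speed, cp_interval) {
  if (!is.finite(gantry_speed) || gantry_speed <= 0)
    stop("gantry_speed must be > 0")
  if (!is.finite(cp_interval) || cp_interval <= 0)
    stop("cp_interval must be > 0")
  cp_interval / gantry_speed
}

#' Leaf speeds for one bank of an arc
#'
#' Speed is the magnitude of the position change between consecutive control
#' points divided by the interval time: `|x[l, i+1] - x[l, i]| / dt`.
#'
#' @param arc a `vmat_arc`.
#' @param bank `"A"` or `"B"`.
#' @param dt interval time in seconds; defaults to
#'   `cp_time(arc$gantry_speed, arc$cp_interval)`.
#' @param leaves optional integer vector of leaf-pair indices to include
#'   (default all).
#' @return Matrix `[leaf x interval]` of speeds (mm/s); attribute `cp_time`
#'   carries `dt`.
#' @export
leaf_speeds <- function(arc, bank = c("A", "B"), dt = NULL, leaves = NULL) {
  bank <- match.arg(bank)
  if (is.null(dt)) dt <- cp_time(arc$gantry_speed, arc$cp_interval)
  pos <- t(bank_matrix(arc, bank))          # [leaf x cp]
  if (!is.null(leaves)) pos <- pos[leaves, , drop = FALSE]
  if (ncol(pos) < 2) stop("arc '", arc$arc_id, "': needs >= 2 control points")
  sp <- abs(pos[, -1, drop = FALSE] - pos[, -ncol(pos), drop = FALSE]) / dt
  attr(sp, "cp_time") <- dt
  sp
}

#' Leaf accelerations from a speed matrix
#'
#' Acceleration is the magnitude of the change between consecutive interval
#' speeds divided by the interval time: `|v[l, i+1] - v[l, i]| / dt`.  A
#' single-interval speed matrix yields a zero-column result with a message.
#'
#' @param speeds matrix `[leaf x interval]` from [leaf_speeds()].
#' @param dt interval time in seconds; defaults to the matrix's `cp_time`
#'   attribute.
#' @return Matrix `[leaf x (interval - 1)]` of accelerations (mm/s^2).
#' @export
leaf_accelerations <- function(speeds, dt = attr(speeds, "cp_time")) {
  if (is.null(dt)) stop("dt not supplied and speeds carries no cp_time")
  if (ncol(speeds) < 2) {
    message("single speed interval: no accelerations computable")
    return(speeds[, 0, drop = FALSE])
  }
  acc <- abs(speeds[, -1, drop = FALSE] -
             speeds[, -ncol(speeds), drop = FALSE]) / dt
  attr(acc, "cp_time") <- dt
  acc
}

# default bin edges (half-open [lo, hi); topmost bin closed)
LS_BREAKS <- c(0, 4, 8, 12, 16, 20)
LA_BREAKS <- c(0, 40, 80, 120, 160, 200)

bin_fractions <- function(x, breaks) {
  n <- length(x)
  k <- length(breaks) - 1
  # half-open [lo, hi), last bin closed at the cap
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  over <- sum(idx > k | x > breaks[k + 1])
  if (over > 0)
    message(over, " sample(s) above the top bin (", breaks[k + 1],
            "); counted as overflow")
  frac <- tabulate(idx[idx >= 1 & idx <= k & x <= breaks[k + 1]], nbins = k) / n
  list(frac = frac, overflow = over / n)
}

# Leaf pairs whose physical span intersects the y-jaw opening at any CP.
included_leaves <- function(arc, all_leaves = FALSE) {
  n <- length(arc$leaf_widths)
  if (all_leaves) return(seq_len(n))
  jaws <- lapply(arc$control_points, `[[`, "jaw_y")
  jaws <- Filter(Negate(is.null), jaws)
  if (!length(jaws)) return(seq_len(n))
  lo <- min(vapply(jaws, `[`, numeric(1), 1))
  hi <- max(vapply(jaws, `[`, numeric(1), 2))
  b <- leaf_pair_bounds(arc$leaf_widths)
  which(b[, "hi"] > lo & b[, "lo"] < hi)
}

kin_feature_names <- function(bank) {
  paste0(c("MaxLS", "MeanLS", "SDLS",
           "LS0_4", "LS4_8", "LS8_12", "LS12_16", "LS16_20",
           "MaxLA", "MeanLA", "SDLA",
           "LA0_40", "LA40_80", "LA80_120", "LA120_160", "LA160_200"),
         "_", bank)
}

#' The 32 kinematic features of an arc
#'
#' Per bank: maximum, mean and standard deviation of leaf speed over all
#' included (leaf, interval) samples; the fraction of speed samples in the
#' five bins 0-4, 4-8, 8-12, 12-16 and 16-20 mm/s; the same three moments
#' for leaf acceleration plus fractions in the bins 0-40, 40-80, 80-120,
#' 120-160 and 160-200 mm/s^2.  Bins are half-open `[lo, hi)` with the top
#' bin closed at the cap; samples above the cap are counted in an overflow
#' bucket (reported via a message), so fractions may then sum to less than 1.
#'
#' By default only leaf pairs whose physical span intersects the y-jaw
#' opening at some control point are included (parked out-of-field leaves
#' never modulate dose and would dilute the fractions); `all_leaves = TRUE`
#' includes every pair.
#'
#' @param arc a `vmat_arc`.
#' @param all_leaves include parked out-of-field leaf pairs (default `FALSE`).
#' @param dt interval time override, seconds.
#' @return Named numeric vector of 32 features
#'   (`MaxLS_A ... LA160_200_A`, `MaxLS_B ... LA160_200_B`).
#' @export
kinematic_features <- function(arc, all_leaves = FALSE, dt = NULL) {
  leaves <- included_leaves(arc, all_leaves)
  if (!length(leaves))
    stop("arc '", arc$arc_id, "': no leaf pairs inside the y-jaw opening")
  out <- numeric(0)
  for (bank in c("A", "B")) {
    sp <- leaf_speeds(arc, bank, dt = dt, leaves = leaves)
    ac <- leaf_accelerations(sp)
    spv <- as.vector(sp)
    acv <- as.vector(ac)
    if (!length(spv))
      stop("arc '", arc$arc_id, "': zero kinematic samples")
    sfr <- bin_fractions(spv, LS_BREAKS)
    sd_pop <- function(v) if (length(v) > 1) stats::sd(v) else 0
    afr <- if (length(acv)) bin_fractions(acv, LA_BREAKS)
           else list(frac = rep(NA_real_, 5))
    vals <- c(max(spv), mean(spv), sd_pop(spv), sfr$frac,
              if (length(acv)) c(max(acv), mean(acv), sd_pop(acv))
              else rep(NA_real_, 3),
              afr$frac)
    names(vals) <- kin_feature_names(bank)
    out <- c(out, vals)
  }
  out
}
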