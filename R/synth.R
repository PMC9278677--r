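# Seeded synthetic VMAT cohort generator.  Emulates the delivery structure
# of head-and-neck VMAT arcs (178 control points per full arc at 2.0341 deg
# spacing, 4.8 deg/s gantry, two opposing 60-pair leaf banks, speeds capped
# below 20 mm/s) and a GPR response with a planted monotone dependence on
# complexity features plus bounded noise, so every pipeline stage is
# testable without clinical data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the emulated study conditions: 106 plans of 2-4 arcs,
#' 178 control points per arc, a 60-pair MLC (10 mm outer, 5 mm central
#' leaves), gantry at 4.8 deg/s with 2.0341 deg control-point spacing.  Leaf
#' speeds are drawn per interval from a five-bin mixture whose per-arc
#' weights jitter around the cohort profile, giving bin-fraction features
#' that vary between arcs; speeds never reach 20 mm/s, which (at the 0.424 s
#' interval) also caps accelerations below 48 mm/s^2.  GPR is linear in
#' standardized features with truncated Gaussian noise, clipped to
#' `[0, 100]`; the dominant planted coefficient is on `LS0_4_B` (slow-leaf
#' fraction up, GPR up - equivalently, high-speed fractions depress GPR).
#' Optional out-of-control plans have all arcs depressed by `outlier_depth`
#' GPR points at both criteria.
#'
#' @param n_plans number of plans (default 106).
#' @param arcs_per_plan integer range, default `c(2, 4)`.
#' @param n_control_points control points per arc (default 178).
#' @param leaf_pairs leaf pairs per bank (default 60).
#' @param cp_interval control-point spacing, degrees (default 2.0341).
#' @param gantry_speed gantry speed, deg/s (default 4.8).
#' @param speed_bin_weights cohort-mean occupancy of the five speed bins.
#' @param weight_concentration Dirichlet concentration for the per-arc
#'   jitter of the bin weights (larger = less between-arc variation).
#' @param max_speed speed cap, mm/s (strictly below 20).
#' @param gpr_intercept named intercepts (percent) per criterion.
#' @param gpr_coef named list (per criterion) of named coefficient vectors:
#'   GPR decreases by `coef` points per standard deviation of the feature.
#' @param noise_sd named per-criterion noise SD (percent); noise is Gaussian
#'   truncated at 2.5 SD (QA measurement scatter is bounded in practice).
#' @param n_outliers number of planted out-of-control plans (default 0).
#' @param outlier_depth GPR depression of planted outliers, percent.
#' @param fluence_spacing fluence pixel size for feature extraction, mm.
#' @param gray_levels GLCM quantization levels.
#' @param seed integer master seed; all randomness derives from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_plans = 106,
                          arcs_per_plan = c(2, 4),
                          n_control_points = 178,
                          leaf_pairs = 60,
                          cp_interval = 2.0341,
                          gantry_speed = 4.8,
                          speed_bin_weights = c(0.63, 0.09, 0.05, 0.03, 0.19),
                          weight_concentration = 55,
                          max_speed = 19.8,
                          gpr_intercept = c(gpr_2_2 = 93.50, gpr_3_2 = 96.53),
                          gpr_coef = list(
                            gpr_2_2 = c(LS0_4_B = -2.0, LS0_4_A = -0.8,
                                        MeanLA_A = 0.5, Entropy = 0.4),
                            gpr_3_2 = c(LS0_4_B = -1.2, LS0_4_A = -0.5,
                                        MeanLA_A = 0.3, Entropy = 0.25)),
                          noise_sd = c(gpr_2_2 = 1.2, gpr_3_2 = 0.8),
                          n_outliers = 0,
                          outlier_depth = 15,
                          fluence_spacing = 1,
                          gray_levels = 256,
                          seed = 1) {
  stopifnot(n_plans >= 1, n_control_points >= 2, leaf_pairs >= 2,
            max_speed < 20, all(noise_sd >= 0), n_outliers <= n_plans)
  w <- speed_bin_weights / sum(speed_bin_weights)
  structure(list(
    n_plans = n_plans, arcs_per_plan = arcs_per_plan,
    n_control_points = n_control_points, leaf_pairs = leaf_pairs,
    cp_interval = cp_interval, gantry_speed = gantry_speed,
    speed_bin_weights = w, weight_concentration = weight_concentration,
    max_speed = max_speed, gpr_intercept = gpr_intercept,
    gpr_coef = gpr_coef, noise_sd = noise_sd,
    n_outliers = n_outliers, outlier_depth = outlier_depth,
    fluence_spacing = fluence_spacing, gray_levels = gray_levels,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# default leaf widths: 10 outer pairs of 10 mm each side, central 5 mm
default_leaf_widths <- function(n) {
  n_out <- max(0, min(10, n %/% 6))
  c(rep(10, n_out), rep(5, n - 2 * n_out), rep(10, n_out))
}

# one reflecting constant-|step| walk: speeds fixed, direction persistent
walk_positions <- function(x0, steps, lo, hi, persist = 0.92) {
  n <- length(steps)
  x <- numeric(n + 1); x[1] <- x0
  dir <- sample(c(-1, 1), 1)
  flips <- stats::runif(n) > persist
  for (i in seq_len(n)) {
    if (flips[i]) dir <- -dir
    nxt <- x[i] + dir * steps[i]
    if (nxt > hi || nxt < lo) { dir <- -dir; nxt <- x[i] + dir * steps[i] }
    x[i + 1] <- min(max(nxt, lo), hi)
  }
  x
}

# speeds for one bank: per-interval bin draw then uniform within the bin
draw_speeds <- function(n_leaves, n_int, weights, max_speed) {
  lo <- c(0, 4, 8, 12, 16); hi <- c(4, 8, 12, 16, max_speed)
  bin <- sample.int(5, n_leaves * n_int, replace = TRUE, prob = weights)
  sp <- stats::runif(n_leaves * n_int, lo[bin], hi[bin])
  matrix(sp, nrow = n_leaves)
}

generate_arc <- function(config, arc_id, arc_weights) {
  ncp <- config$n_control_points
  n_int <- ncp - 1
  widths <- default_leaf_widths(config$leaf_pairs)
  bounds <- leaf_pair_bounds(widths)
  dt <- cp_time(config$gantry_speed, config$cp_interval)

  # active contiguous block of leaf pairs inside the y jaws
  hi <- min(36, config$leaf_pairs)
  lo <- min(16, max(2, config$leaf_pairs - 2))
  n_active <- sample(seq(min(lo, hi), hi), 1)
  first <- sample.int(config$leaf_pairs - n_active + 1, 1)
  active <- first:(first + n_active - 1)
  jaw_y <- c(bounds[active[1], "lo"], bounds[active[length(active)], "hi"])
  jaw_x <- c(-55, 55)

  posA <- matrix(0, nrow = config$leaf_pairs, ncol = ncp)
  posB <- matrix(0, nrow = config$leaf_pairs, ncol = ncp)
  spA <- draw_speeds(n_active, n_int, arc_weights, config$max_speed)
  spB <- draw_speeds(n_active, n_int, arc_weights, config$max_speed)
  for (k in seq_along(active)) {
    l <- active[k]
    posA[l, ] <- walk_positions(stats::runif(1, -40, -5), spA[k, ] * dt,
                                lo = -50, hi = -0.5)
    posB[l, ] <- walk_positions(stats::runif(1, 5, 40), spB[k, ] * dt,
                                lo = 0.5, hi = 50)
  }

  mu <- cumsum(c(0, stats::runif(n_int, 0.5, 1.5)))
  mu <- mu / mu[ncp]
  ang <- (181 + (seq_len(ncp) - 1) * config$cp_interval) %% 360

  cps <- lapply(seq_len(ncp), function(i)
    control_point(index = i - 1L, gantry_angle = ang[i], mu_fraction = mu[i],
                  bankA = posA[, i], bankB = posB[, i],
                  jaw_x = jaw_x, jaw_y = jaw_y))
  vmat_arc(arc_id = arc_id, control_points = cps,
           arc_mu = stats::runif(1, 300, 600), leaf_widths = widths,
           gantry_speed = config$gantry_speed,
           cp_interval = config$cp_interval)
}

#' Generate one synthetic VMAT plan
#'
#' Deterministic per `(config$seed, plan_index)`.  Each arc draws its own
#' speed-bin weights (Dirichlet jitter around the cohort profile), active
#' leaf block, aperture walks and MU increments.
#'
#' @param config a [cohort_config()].
#' @param plan_index 1-based plan index within the cohort.
#' @return A validated `vmat_plan` with id `sprintf("P%03d", plan_index)`.
#' @export
generate_plan <- function(config, plan_index) {
  set.seed(config$seed * 1000L + plan_index)
  n_arcs <- sample(seq(config$arcs_per_plan[1], config$arcs_per_plan[2]), 1)
  arcs <- lapply(seq_len(n_arcs), function(ai) {
    g <- stats::rgamma(5, shape = config$weight_concentration *
                            config$speed_bin_weights)
    generate_arc(config, sprintf("A%d", ai), g / sum(g))
  })
  vmat_plan(sprintf("P%03d", plan_index), arcs)
}

# truncated standard normal draws (cut at +/- trunc SD)
rnorm_trunc <- function(n, trunc = 2.5) {
  x <- stats::rnorm(n)
  while (any(bad <- abs(x) > trunc)) x[bad] <- stats::rnorm(sum(bad))
  x
}

#' Synthetic GPR response for a feature table
#'
#' `gpr = clip(intercept - sum(coef_k * z_k) + noise, 0, 100)` per
#' criterion, where `z_k` is the feature standardized over the supplied
#' table (constant features contribute 0).  Noise is Gaussian with the
#' configured SD, truncated at 2.5 SD.  Deterministic under the caller's
#' RNG state; [generate_cohort()] seeds it from `config$seed`.
#'
#' @param features data.frame from [extract_features()].
#' @param config a [cohort_config()].
#' @return data.frame `plan_id, arc_id, gpr_2_2, gpr_3_2`.
#' @export
gpr_response <- function(features, config) {
  out <- features[c("plan_id", "arc_id")]
  for (crit in c("gpr_2_2", "gpr_3_2")) {
    coefs <- config$gpr_coef[[crit]]
    unknown <- setdiff(names(coefs), names(features))
    if (length(unknown))
      stop("unknown feature name(s) in gpr_coef: ",
           paste(unknown, collapse = ", "))
    lp <- rep(0, nrow(features))
    for (k in names(coefs)) {
      v <- features[[k]]
      s <- stats::sd(v)
      if (is.na(s) || s == 0) next
      lp <- lp + coefs[[k]] * (v - mean(v)) / s
    }
    noise <- if (config$noise_sd[[crit]] > 0)
      config$noise_sd[[crit]] * rnorm_trunc(nrow(features)) else 0
    out[[crit]] <- pmin(pmax(config$gpr_intercept[[crit]] - lp + noise, 0), 100)
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Generates the plans, extracts the 37 features, draws the GPR response,
#' and plants `n_outliers` out-of-control plans whose arcs are depressed by
#' `outlier_depth` GPR points at both criteria.  The returned truth record
#' (planted coefficients, outlier plan ids, noise SDs, dominant feature)
#' lets recovery tests check against what was planted rather than
#' re-deriving it.
#'
#' @param config a [cohort_config()].
#' @return List with `plans` (list of `vmat_plan`), `features` (data.frame),
#'   `qa` (data.frame `plan_id, arc_id, gpr_2_2, gpr_3_2`), and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  plans <- lapply(seq_len(config$n_plans),
                  function(i) generate_plan(config, i))
  features <- extract_features(plans, spacing = config$fluence_spacing,
                               gray_levels = config$gray_levels)
  set.seed(config$seed * 1000L + 999983L)
  qa <- gpr_response(features, config)
  outliers <- character(0)
  if (config$n_outliers > 0) {
    outliers <- sort(sample(unique(qa$plan_id), config$n_outliers))
    sel <- qa$plan_id %in% outliers
    for (crit in c("gpr_2_2", "gpr_3_2"))
      qa[[crit]][sel] <- pmax(qa[[crit]][sel] - config$outlier_depth -
                                stats::runif(sum(sel), 0, 2), 0)
  }
  list(plans = plans, features = features, qa = qa,
       truth = list(coef = config$gpr_coef,
                    noise_sd = config$noise_sd,
                    intercept = config$gpr_intercept,
                    outlier_plans = outliers,
                    dominant_feature = "LS0_4_B"))
}
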