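# Fixture builders and naive oracle implementations used across the suite.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorized code paths.

# Build an arc from position matrices [cp x pair]; mu defaults to equal steps.
make_arc <- function(posA, posB, widths = rep(5, ncol(posA)),
                     mu = seq(0, 1, length.out = nrow(posA)),
                     gantry_speed = 4.8, cp_interval = 2.0341,
                     jaw_x = NULL, jaw_y = NULL, arc_id = "A1",
                     arc_mu = 400, validate = TRUE) {
  cps <- lapply(seq_len(nrow(posA)), function(i)
    control_point(index = i - 1L,
                  gantry_angle = (181 + (i - 1) * cp_interval) %% 360,
                  mu_fraction = mu[i],
                  bankA = posA[i, ], bankB = posB[i, ],
                  jaw_x = jaw_x, jaw_y = jaw_y))
  vmat_arc(arc_id, cps, arc_mu = arc_mu, leaf_widths = widths,
           gantry_speed = gantry_speed, cp_interval = cp_interval,
           validate = validate)
}

# a tiny valid 3-CP, 2-pair arc
toy_arc <- function() {
  posA <- rbind(c(-10, -12), c(-11, -12), c(-12, -12))
  posB <- rbind(c(10, 12), c(11, 12), c(12, 12))
  make_arc(posA, posB)
}

# random small arc for oracle-equivalence sweeps (no jaws: all leaves count)
random_arc <- function(seed, n_cp = 8, n_pairs = 6) {
  set.seed(seed)
  posA <- matrix(runif(n_cp * n_pairs, -30, -1), n_cp, n_pairs)
  posB <- matrix(runif(n_cp * n_pairs, 1, 30), n_cp, n_pairs)
  mu <- cumsum(c(0, runif(n_cp - 1)))
  make_arc(posA, posB, mu = mu / max(mu))
}

# --- naive kinematic features: explicit per-leaf, per-interval loops -------
naive_kinematic_features <- function(arc) {
  dt <- arc$cp_interval / arc$gantry_speed
  out <- numeric(0)
  for (bank in c("A", "B")) {
    speeds <- c(); accels <- c()
    n_cp <- length(arc$control_points)
    n_pairs <- length(arc$leaf_widths)
    for (l in seq_len(n_pairs)) {
      pos <- sapply(arc$control_points, function(cp)
        if (bank == "A") cp$bankA[l] else cp$bankB[l])
      v <- c()
      for (i in seq_len(n_cp - 1)) v <- c(v, abs(pos[i + 1] - pos[i]) / dt)
      a <- c()
      if (length(v) >= 2)
        for (i in seq_len(length(v) - 1)) a <- c(a, abs(v[i + 1] - v[i]) / dt)
      speeds <- c(speeds, v); accels <- c(accels, a)
    }
    frac <- function(x, lo, hi, top) {
      if (top) mean(x >= lo & x <= hi) else mean(x >= lo & x < hi)
    }
    vals <- c(max(speeds), mean(speeds), sd(speeds),
              frac(speeds, 0, 4, FALSE), frac(speeds, 4, 8, FALSE),
              frac(speeds, 8, 12, FALSE), frac(speeds, 12, 16, FALSE),
              frac(speeds, 16, 20, TRUE),
              max(accels), mean(accels), sd(accels),
              frac(accels, 0, 40, FALSE), frac(accels, 40, 80, FALSE),
              frac(accels, 80, 120, FALSE), frac(accels, 120, 160, FALSE),
              frac(accels, 160, 200, TRUE))
    out <- c(out, vals)
  }
  names(out) <- c(vmatqa::feature_names()[1:32])
  out
}

# --- brute-force fluence: per-pixel, per-interval triple loop --------------
brute_force_fluence <- function(arc, grid) {
  bounds <- vmatqa:::leaf_pair_bounds(arc$leaf_widths)
  total <- matrix(0, length(grid$y), length(grid$x))
  cps <- arc$control_points
  for (i in seq_len(length(cps) - 1)) {
    cp <- cps[[i]]
    dmu <- cps[[i + 1]]$mu_fraction - cp$mu_fraction
    for (r in seq_along(grid$y)) {
      yc <- grid$y[r]
      p <- which(bounds[, "lo"] <= yc & yc < bounds[, "hi"])
      if (!length(p)) next
      if (!is.null(cp$jaw_y) && (yc < cp$jaw_y[1] || yc > cp$jaw_y[2])) next
      a <- cp$bankA[p]; b <- cp$bankB[p]
      if (!is.null(cp$jaw_x)) { a <- max(a, cp$jaw_x[1]); b <- min(b, cp$jaw_x[2]) }
      if (b <= a) next
      for (cc in seq_along(grid$x)) {
        xlo <- grid$x[cc] - grid$spacing / 2
        xhi <- grid$x[cc] + grid$spacing / 2
        ov <- max(0, min(xhi, b) - max(xlo, a)) / grid$spacing
        total[r, cc] <- total[r, cc] + dmu * ov
      }
    }
  }
  total
}

# --- naive texture statistics from one GLCM: double loop -------------------
naive_texture_one <- function(P) {
  L <- nrow(P)
  contrast <- 0; energy <- 0; entropy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + (i - 1) * P[i, j]; mu_j <- mu_j + (j - 1) * P[i, j]
  }
  var_i <- 0; var_j <- 0; cov_ij <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + p * (i - j)^2
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log(p)
    homog <- homog + p / (1 + abs(i - j))
    var_i <- var_i + (i - 1 - mu_i)^2 * p
    var_j <- var_j + (j - 1 - mu_j)^2 * p
    cov_ij <- cov_ij + (i - 1 - mu_i) * (j - 1 - mu_j) * p
  }
  corr <- if (var_i > 0 && var_j > 0) cov_ij / sqrt(var_i * var_j) else 0
  c(Contrast = contrast, Correlation = corr, Energy = energy,
    Entropy = entropy, Homogeneity = homog)
}

# naive GLCM by walking every pixel pair at the given offset
naive_glcm <- function(img, drow, dcol, levels, exclude_background = TRUE) {
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
    r2 <- r + drow; c2 <- cc + dcol
    if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
    i <- img[r, cc]; j <- img[r2, c2]
    if (exclude_background && i == 0 && j == 0) next
    P[i + 1, j + 1] <- P[i + 1, j + 1] + 1
    P[j + 1, i + 1] <- P[j + 1, i + 1] + 1
  }
  P / sum(P)
}
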