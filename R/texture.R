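# GLCM texture of the fluence map: quantization, co-occurrence matrices at
# displacement d and angles {0, 45, 90, 135} deg, and the five Haralick-style
# statistics (contrast, correlation, energy, entropy, homogeneity).

#' Quantize a fluence map to integer gray levels
#'
#' Linear quantization of `[0, max]` into `gray_levels` bins: level
#' `floor(v / max * L)` clamped to `L - 1`, so 0 maps to level 0 and the
#' maximum to `L - 1`.  An all-zero map quantizes to all level 0.
#'
#' @param map a `fluence_map` or a numeric matrix.
#' @param gray_levels number of levels `L >= 2` (default 256).
#' @return Integer matrix of levels in `0 .. L-1`.
#' @export
quantize_map <- function(map, gray_levels = 256) {
  if (inherits(map, "fluence_map")) map <- map$intensity
  if (gray_levels < 2) stop("gray_levels must be >= 2")
  mx <- max(map)
  if (mx <= 0) return(matrix(0L, nrow(map), ncol(map)))
  lev <- pmin(as.integer(floor(map / mx * gray_levels)), gray_levels - 1L)
  matrix(lev, nrow(map), ncol(map))
}

# pixel offsets (drow, dcol) for the standard GLCM angles; row 1 is the top
# of the image, so angle 45 looks up-right
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("unsupported GLCM angle: ", angle))
}

#' Gray-level co-occurrence matrices
#'
#' For each angle, counts co-occurring level pairs at pixel displacement `d`,
#' optionally symmetrized (each pair counted in both directions) and
#' normalized to sum 1.  With `exclude_background = TRUE` (the default),
#' pairs whose two pixels are both at level 0 are dropped before
#' normalization, so the statistics describe the irradiated region rather
#' than the empty surround.
#'
#' @param image integer matrix of levels from [quantize_map()].
#' @param d displacement in pixels (default 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param levels number of gray levels in `image` (default `max(image) + 1`).
#' @param symmetric count both directions (default `TRUE`).
#' @param exclude_background drop level-0/level-0 pairs (default `TRUE`).
#' @return Named list (one `levels x levels` matrix per angle), each summing
#'   to 1.
#' @export
glcm <- function(image, d = 1, angles = c(0, 45, 90, 135),
                 levels = max(image) + 1L, symmetric = TRUE,
                 exclude_background = TRUE) {
  if (d < 1) stop("displacement d must be >= 1")
  nr <- nrow(image); nc <- ncol(image)
  out <- list()
  for (ang in angles) {
    off <- glcm_offset(ang, d)
    r0 <- max(1, 1 - off[1]); r1 <- min(nr, nr - off[1])
    c0 <- max(1, 1 - off[2]); c1 <- min(nc, nc - off[2])
    if (r1 < r0 || c1 < c0)
      stop("image smaller than offset for angle ", ang)
    i <- image[r0:r1, c0:c1]
    j <- image[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2])]
    i <- as.vector(i); j <- as.vector(j)
    if (exclude_background) {
      keep <- i > 0L | j > 0L
      i <- i[keep]; j <- j[keep]
    }
    counts <- numeric(levels * levels)
    idx <- i * levels + j + 1  # row-major cell index
    tab <- tabulate(idx, nbins = levels * levels)
    counts <- counts + tab
    P <- matrix(counts, nrow = levels, byrow = TRUE)
    if (symmetric) P <- P + t(P)
    s <- sum(P)
    if (s == 0) stop("empty GLCM at angle ", ang,
                     " (all pairs excluded as background)")
    out[[as.character(ang)]] <- P / s
  }
  out
}

#' Texture statistics of GLCMs, averaged over angles
#'
#' Per angle, with `p(i, j)` the normalized co-occurrence matrix over levels
#' `i, j = 0 .. L-1`:
#' \itemize{
#'   \item contrast: `sum p(i,j) (i - j)^2`
#'   \item correlation: `sum (i - mu_i)(j - mu_j) p(i,j) / (sd_i sd_j)`
#'     (reported as 0 with a message when a marginal SD is 0)
#'   \item energy: `sum p^2`
#'   \item entropy: `-sum p log p` (natural log by default; `0 log 0 = 0`)
#'   \item homogeneity: `sum p / (1 + |i - j|)`
#' }
#' The returned features are the means across the supplied angles.
#'
#' @param glcms list of normalized GLCMs from [glcm()].
#' @param log_base `"natural"` or `"2"` for the entropy logarithm.
#' @return Named numeric vector `Contrast, Correlation, Energy, Entropy,
#'   Homogeneity`.
#' @export
texture_features <- function(glcms, log_base = c("natural", "2")) {
  log_base <- match.arg(log_base)
  feats <- vapply(glcms, function(P) {
    L <- nrow(P)
    lv <- seq_len(L) - 1
    I <- matrix(lv, L, L)
    J <- t(I)
    contrast <- sum(P * (I - J)^2)
    pi_m <- rowSums(P); pj_m <- colSums(P)
    mu_i <- sum(lv * pi_m); mu_j <- sum(lv * pj_m)
    sd_i <- sqrt(sum((lv - mu_i)^2 * pi_m))
    sd_j <- sqrt(sum((lv - mu_j)^2 * pj_m))
    correlation <- if (sd_i == 0 || sd_j == 0) {
      message("degenerate GLCM marginal (sd = 0): correlation set to 0")
      0
    } else sum((I - mu_i) * (J - mu_j) * P) / (sd_i * sd_j)
    energy <- sum(P^2)
    pos <- P[P > 0]
    entropy <- -sum(pos * log(pos))
    if (log_base == "2") entropy <- entropy / log(2)
    homogeneity <- sum(P / (1 + abs(I - J)))
    c(contrast, correlation, energy, entropy, homogeneity)
  }, numeric(5))
  out <- rowMeans(feats)
  names(out) <- c("Contrast", "Correlation", "Energy", "Entropy", "Homogeneity")
  out
}

#' The five texture features of an arc
#'
#' Convenience wrapper: integrated fluence map, quantization, GLCM at the
#' four standard angles, features averaged over angles.
#'
#' @param arc a `vmat_arc`.
#' @param spacing fluence pixel size, mm.
#' @param gray_levels quantization levels.
#' @param d GLCM displacement, pixels.
#' @param ... passed to [glcm()].
#' @return Named numeric vector of the 5 texture features.
#' @export
arc_texture_features <- function(arc, spacing = 1, gray_levels = 256, d = 1,
                                 ...) {
  fm <- integrate_fluence(arc, spacing = spacing)
  q <- quantize_map(fm, gray_levels)
  texture_features(glcm(q, d = d, levels = gray_levels, ...))
}
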