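#' Texture features from grey-level matrices
#'
#' Each `*_features()` function reduces one texture matrix to its named
#' scalar features; the family cardinalities are fixed at 20 (co-occurrence),
#' 15 (run length), 14 (size zone), 12 (dependence) and 5 (grey-tone
#' difference). Degenerate inputs (zero-total matrices, zero-variance
#' marginals) yield `NaN` sentinels, which the screening filter removes, with
#' one exception: coarseness on a texture-free ROI is capped at 1e6 rather
#' than infinite.
#'
#' Four co-occurrence features carry bespoke definitions (the field has no
#' published formula under these names); with `p` the joint probability,
#' `p'` the normalized complement `max(p) - p(i,j)`, and `s = B/4`:
#' * inverse cluster shade: the cluster-shade cubic computed on `p'`;
#' * inverse cluster tendency: the cluster-tendency quadratic on `p'`;
#' * Gaussian left polar: `sum_{i >= j} p(i,j) exp(-(i-j)^2 / (2 s^2))`;
#' * inverse Gaussian left polar: the same sum with weight
#'   `1 - exp(-(i-j)^2 / (2 s^2))`.
#'
#' @param matrix the corresponding texture matrix object.
#' @param levels,params for [ngtdm_features()], a `level_map` and
#'   [texture_params()] (the statistics are computed on the fly), or a
#'   precomputed `ngtdm_row`.
#' @return A named numeric vector of the family's features.
#' @name texture_features
NULL

xlogx2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' @rdname texture_features
#' @export
glcm_features <- function(matrix) {
  stopifnot(inherits(matrix, "glc_matrix"))
  cm <- matrix$counts
  b <- nrow(cm)
  total <- sum(cm)
  nm <- c("autocorrelation", "contrast", "cluster_shade", "cluster_prominence",
          "cluster_tendency", "correlation", "joint_energy", "joint_entropy",
          "homogeneity", "inverse_difference_moment", "maximum_probability",
          "sum_average", "sum_entropy", "difference_entropy",
          "difference_variance", "dissimilarity", "inverse_cluster_shade",
          "inverse_cluster_tendency", "gaussian_left_polar",
          "inverse_gaussian_left_polar")
  if (total == 0) return(setNames(rep(NaN, 20L), nm))
  p <- cm / total
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  mu_x <- sum(seq_len(b) * px)
  mu_y <- mu_x  # symmetric matrix
  sd_x <- sqrt(sum((seq_len(b) - mu_x)^2 * px))
  # sum and difference marginals, grouped in one pass (groups are complete)
  pxy_sum <- as.vector(rowsum(as.vector(p), as.vector(i + j)))
  pxy_dif <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j))))
  da <- sum((0:(b - 1)) * pxy_dif)

  corr <- if (sd_x > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_x)
  } else NaN

  # complement distribution for the "inverse" cluster features
  comp <- max(p) - p
  inv_shade <- inv_tend <- NaN
  if (sum(comp) > 0) {
    pc <- comp / sum(comp)
    mu_cx <- sum(seq_len(b) * rowSums(pc))
    mu_cy <- sum(seq_len(b) * colSums(pc))
    inv_shade <- sum((i + j - mu_cx - mu_cy)^3 * pc)
    inv_tend <- sum((i + j - mu_cx - mu_cy)^2 * pc)
  }
  sigma <- b / 4
  gauss <- exp(-(i - j)^2 / (2 * sigma^2))
  lower <- i >= j

  setNames(c(
    sum(i * j * p),
    sum((i - j)^2 * p),
    sum((i + j - mu_x - mu_y)^3 * p),
    sum((i + j - mu_x - mu_y)^4 * p),
    sum((i + j - mu_x - mu_y)^2 * p),
    corr,
    sum(p^2),
    xlogx2(p),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + (i - j)^2)),
    max(p),
    sum((2:(2 * b)) * pxy_sum),
    xlogx2(pxy_sum),
    xlogx2(pxy_dif),
    sum(((0:(b - 1)) - da)^2 * pxy_dif),
    sum(abs(i - j) * p),
    inv_shade,
    inv_tend,
    sum(p[lower] * gauss[lower]),
    sum(p[lower] * (1 - gauss[lower]))
  ), nm)
}

#' @rdname texture_features
#' @export
glrlm_features <- function(matrix) {
  stopifnot(inherits(matrix, "glrl_matrix"))
  cm <- matrix$counts
  nr <- sum(cm)
  np <- matrix$n_roi
  nm <- c("short_run_emphasis", "long_run_emphasis",
          "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
          "short_run_low_grey_level_emphasis",
          "short_run_high_grey_level_emphasis",
          "long_run_low_grey_level_emphasis",
          "long_run_high_grey_level_emphasis",
          "grey_level_non_uniformity", "run_length_non_uniformity",
          "run_length_non_uniformity_normalized", "run_percentage",
          "run_entropy", "run_variance", "grey_level_variance")
  if (nr == 0) return(setNames(rep(NaN, 15L), nm))
  i <- row(cm)
  j <- col(cm)
  p <- cm / nr
  mu_j <- sum(j * p)
  mu_i <- sum(i * p)
  setNames(c(
    sum(cm / j^2) / nr,
    sum(cm * j^2) / nr,
    sum(cm / i^2) / nr,
    sum(cm * i^2) / nr,
    sum(cm / (i^2 * j^2)) / nr,
    sum(cm * i^2 / j^2) / nr,
    sum(cm * j^2 / i^2) / nr,
    sum(cm * i^2 * j^2) / nr,
    sum(rowSums(cm)^2) / nr,
    sum(colSums(cm)^2) / nr,
    sum(colSums(cm)^2) / nr^2,
    nr / np,
    xlogx2(p),
    sum((j - mu_j)^2 * p),
    sum((i - mu_i)^2 * p)
  ), nm)
}

#' @rdname texture_features
#' @export
glszm_features <- function(matrix) {
  stopifnot(inherits(matrix, "glsz_matrix"))
  cm <- matrix$counts
  nz <- sum(cm)
  np <- matrix$n_roi
  nm <- c("small_area_emphasis", "large_area_emphasis",
          "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
          "small_area_low_grey_level_emphasis",
          "small_area_high_grey_level_emphasis",
          "large_area_low_grey_level_emphasis",
          "large_area_high_grey_level_emphasis",
          "grey_level_non_uniformity", "size_zone_non_uniformity",
          "size_zone_non_uniformity_normalized", "zone_percentage",
          "zone_variance", "zone_entropy")
  if (nz == 0) return(setNames(rep(NaN, 14L), nm))
  i <- row(cm)
  s <- col(cm)
  p <- cm / nz
  mu_s <- sum(s * p)
  setNames(c(
    sum(cm / s^2) / nz,
    sum(cm * s^2) / nz,
    sum(cm / i^2) / nz,
    sum(cm * i^2) / nz,
    sum(cm / (i^2 * s^2)) / nz,
    sum(cm * i^2 / s^2) / nz,
    sum(cm * s^2 / i^2) / nz,
    sum(cm * i^2 * s^2) / nz,
    sum(rowSums(cm)^2) / nz,
    sum(colSums(cm)^2) / nz,
    sum(colSums(cm)^2) / nz^2,
    nz / np,
    sum((s - mu_s)^2 * p),
    xlogx2(p)
  ), nm)
}

#' @rdname texture_features
#' @export
gldm_features <- function(matrix) {
  stopifnot(inherits(matrix, "gld_matrix"))
  cm <- matrix$counts
  nd <- sum(cm)
  nm <- c("small_dependence_emphasis", "large_dependence_emphasis",
          "low_grey_level_emphasis", "high_grey_level_emphasis",
          "small_dependence_low_grey_level_emphasis",
          "small_dependence_high_grey_level_emphasis",
          "large_dependence_low_grey_level_emphasis",
          "large_dependence_high_grey_level_emphasis",
          "dependence_non_uniformity", "dependence_non_uniformity_normalized",
          "dependence_entropy", "dependence_variance")
  if (nd == 0) return(setNames(rep(NaN, 12L), nm))
  i <- row(cm)
  k <- col(cm)  # dependence + 1: the (k+1)^2 weighting on dependence k
  p <- cm / nd
  mu_k <- sum((k - 1) * p)
  setNames(c(
    sum(cm / k^2) / nd,
    sum(cm * k^2) / nd,
    sum(cm / i^2) / nd,
    sum(cm * i^2) / nd,
    sum(cm / (i^2 * k^2)) / nd,
    sum(cm * i^2 / k^2) / nd,
    sum(cm * k^2 / i^2) / nd,
    sum(cm * i^2 * k^2) / nd,
    sum(colSums(cm)^2) / nd,
    sum(colSums(cm)^2) / nd^2,
    xlogx2(p),
    sum((k - 1 - mu_k)^2 * p)
  ), nm)
}

#' @rdname texture_features
#' @export
ngtdm_features <- function(levels, params = texture_params()) {
  row <- if (inherits(levels, "ngtdm_row")) levels else {
    compute_ngtdm(levels, params)
  }
  nm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  nv <- row$n_valid
  if (nv == 0) return(setNames(rep(NaN, 5L), nm))
  p <- row$p
  s <- row$s
  lev <- seq_along(p)
  occ <- which(p > 0)
  ngp <- length(occ)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) min(1 / ps, 1e6) else 1e6

  dif2 <- outer(occ, occ, `-`)^2
  pp <- outer(p[occ], p[occ], `+`)
  contrast <- if (ngp > 1) {
    sum(outer(p[occ], p[occ]) * dif2) / (ngp * (ngp - 1)) * sum(s) / nv
  } else 0

  ipd <- abs(outer(lev[occ] * p[occ], lev[occ] * p[occ], `-`))
  busyness <- if (sum(ipd) > 0) ps / sum(ipd) else 0

  ps_occ <- p[occ] * s[occ]
  complexity <- sum(sqrt(dif2) * outer(ps_occ, ps_occ, `+`) / pp) / nv
  strength <- if (sum(s) > 0) sum(pp * dif2) / sum(s) else 0

  setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}
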