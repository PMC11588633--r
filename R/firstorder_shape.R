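#' First-order intensity statistics of an ROI
#'
#' Fifteen order-free statistics of the in-ROI intensities: mean, median,
#' minimum, maximum, range, 10th/25th/75th/90th percentiles, variance
#' (population), skewness, kurtosis, energy, entropy and mean absolute
#' deviation. Percentiles use the empirical-CDF-with-linear-interpolation
#' rule (`quantile(type = 4)`). Kurtosis is non-excess (a normal sample gives
#' 3, not 0). Entropy is computed on an equal-width `entropy_bins`-bin
#' discretization of the ROI range. A constant ROI yields `NaN` sentinels for
#' skewness and kurtosis (0/0), removed by the screening filter.
#'
#' @param volume a [volume3d()] (normalized intensities).
#' @param roi a [mask3d()]; non-zero voxels form the ROI.
#' @param entropy_bins bin count for the entropy histogram (default 32).
#' @return Named numeric vector of 15 features.
#' @export
firstorder_features <- function(volume, roi, entropy_bins = 32L) {
  stopifnot(inherits(volume, "volume3d"), inherits(roi, "mask3d"))
  check_same_grid(volume, roi, "volume", "roi")
  x <- volume$voxels[roi$labels != 0L]
  if (length(x) == 0L) stop("ROI is empty", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 4, names = FALSE)
  # histogram entropy over the ROI's own range
  rng <- range(x)
  ent <- if (rng[2] > rng[1]) {
    lv <- pmin(floor((x - rng[1]) / ((rng[2] - rng[1]) / entropy_bins)) + 1,
               entropy_bins)
    xlogx2(tabulate(lv, entropy_bins) / n)
  } else 0
  c(
    mean = mu,
    median = median(x),
    minimum = rng[1],
    maximum = rng[2],
    range = rng[2] - rng[1],
    p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
    variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else NaN,
    kurtosis = if (m2 > 0) m4 / m2^2 else NaN,
    energy = sum(x^2),
    entropy = ent,
    mean_absolute_deviation = mean(abs(x - mu))
  )
}

#' 2D / 3D shape features of a tumor mask
#'
#' Twenty parameter-free morphology features. 3D: voxel volume, mesh volume,
#' mesh surface area, surface-to-volume ratio, sphericity, compactness,
#' equivalent-sphere diameter, maximum 3D diameter, major/minor/least axis
#' lengths and elongation/flatness from the principal components of the voxel
#' coordinates. 2D (on the largest-area axial slice): area, perimeter,
#' perimeter-to-area ratio, circularity; plus the maximum in-plane diameters
#' in the axial, coronal and sagittal plane families.
#'
#' The mesh is a marching-tetrahedra iso-surface of the binary mask at
#' iso-level 0.5 (face counting would overestimate curved surfaces badly);
#' sphericity is `pi^(1/3) (6 V)^(2/3) / A` with mesh volume and area, and
#' compactness is `V / (sqrt(pi) A^(3/2))`. Axis lengths are `4 sqrt(lambda)`
#' of the physical-coordinate covariance eigenvalues. Volume and area scale
#' as `s^3` and `s^2` under a spacing scale factor `s`. A mask that is
#' degenerate along an axis (e.g. a single slice) returns a `NaN` flatness
#' sentinel.
#'
#' @param roi a non-empty [mask3d()] with spacing in mm.
#' @return Named numeric vector of 20 features (mm-based units).
#' @export
shape_features <- function(roi) {
  stopifnot(inherits(roi, "mask3d"))
  in_roi <- roi$labels != 0L
  n <- sum(in_roi)
  if (n == 0L) stop("ROI is empty", call. = FALSE)
  sp <- roi$spacing
  voxvol <- prod(sp)

  # iso-surface of the Gaussian-smoothed indicator (sigma 1 voxel): the 0.5
  # level set tracks the underlying boundary instead of the voxel staircase,
  # which a raw binary mesh overestimates badly on curved surfaces. For thin
  # masks whose smoothed peak falls below the iso level, fall back to a
  # binary/smoothed blend whose surface always exists and separates exactly
  # the mask voxels.
  bin <- array(as.numeric(in_roi), dim = roi$shape)
  field <- smooth3d(bin, sigma = 1)
  mesh <- cpp_mesh_area_volume(field, dim(roi$labels), sp, 0.5)
  if (mesh$area <= 0 || mesh$volume <= 0) {
    mesh <- cpp_mesh_area_volume(0.5 * (bin + field), dim(roi$labels), sp, 0.5)
  }
  area <- mesh$area
  mvol <- mesh$volume

  idx <- which(in_roi, arr.ind = TRUE)
  coords <- sweep(idx, 2L, sp, `*`)

  # principal axes of the physical voxel coordinates (population covariance)
  lambda <- rep(0, 3)
  if (n > 1L) {
    cc <- sweep(coords, 2L, colMeans(coords))
    lambda <- sort(eigen(crossprod(cc) / n, symmetric = TRUE,
                         only.values = TRUE)$values, decreasing = TRUE)
    lambda[lambda < 0] <- 0
  }

  # boundary voxels (any 6-neighbor outside) are enough for diameters
  boundary <- in_roi & !erode6(in_roi)
  bidx <- which(boundary, arr.ind = TRUE)
  bc <- sweep(bidx, 2L, sp, `*`)
  max3d <- if (nrow(bc) > 1L) cpp_max_pairwise(bc) else 0

  max2d <- function(drop_axis) {
    if (nrow(bc) < 2L) return(0)
    planes <- split.data.frame(bc, bidx[, drop_axis])
    max(vapply(planes, function(m) {
      if (nrow(m) < 2L) return(0)
      m2 <- m
      m2[, drop_axis] <- 0
      cpp_max_pairwise(as.matrix(m2))
    }, numeric(1)))
  }

  # largest-area axial slice
  per_slice <- apply(in_roi, 3L, sum)
  zbest <- which.max(per_slice)
  slc <- in_roi[, , zbest]
  area2d <- per_slice[zbest] * sp[1] * sp[2]
  perim <- slice_perimeter(slc, sp[1], sp[2])

  sphericity <- if (area > 0) pi^(1 / 3) * (6 * mvol)^(2 / 3) / area else NaN
  c(
    voxel_volume = n * voxvol,
    mesh_volume = mvol,
    surface_area = area,
    surface_to_volume_ratio = if (mvol > 0) area / mvol else NaN,
    sphericity = sphericity,
    compactness = if (area > 0) mvol / (sqrt(pi) * area^1.5) else NaN,
    equivalent_sphere_diameter = (6 * n * voxvol / pi)^(1 / 3),
    max_3d_diameter = max3d,
    major_axis_length = 4 * sqrt(lambda[1]),
    minor_axis_length = 4 * sqrt(lambda[2]),
    least_axis_length = 4 * sqrt(lambda[3]),
    elongation = if (lambda[1] > 0) sqrt(lambda[2] / lambda[1]) else NaN,
    flatness = if (lambda[1] > 0 && lambda[3] > 0) {
      sqrt(lambda[3] / lambda[1])
    } else NaN,
    slice_area = area2d,
    slice_perimeter = perim,
    perimeter_to_area = if (area2d > 0) perim / area2d else NaN,
    circularity = if (perim > 0) 4 * pi * area2d / perim^2 else NaN,
    max_2d_diameter_axial = max2d(3L),
    max_2d_diameter_coronal = max2d(2L),
    max_2d_diameter_sagittal = max2d(1L)
  )
}

# 6-connected erosion (used only to find boundary voxels)
erode6 <- function(x) {
  out <- x
  for (axis in 1:3) {
    out <- out & shift_fill(x, axis, 1L) & shift_fill(x, axis, -1L)
  }
  out
}

shift_fill <- function(x, axis, by) {
  out <- array(FALSE, dim(x))
  d <- dim(x)
  if (abs(by) >= d[axis]) return(out)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) {
    idx_dst[[axis]] <- seq(by + 1L, d[axis])
    idx_src[[axis]] <- seq(1L, d[axis] - by)
  } else {
    idx_dst[[axis]] <- seq(1L, d[axis] + by)
    idx_src[[axis]] <- seq(1L - by, d[axis])
  }
  if (length(idx_dst[[axis]]) == 0L) return(out)
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(x), idx_src)))))
}

# marching-squares perimeter of one binary slice at iso 0.5: each 2x2 pixel
# cell contributes the length of the midpoint contour segment(s) it holds
slice_perimeter <- function(slc, sx, sy) {
  nx <- nrow(slc)
  ny <- ncol(slc)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- slc
  a <- pad[1:(nx + 1L), 1:(ny + 1L)]       # (x,   y)
  b <- pad[2:(nx + 2L), 1:(ny + 1L)]       # (x+1, y)
  cc <- pad[1:(nx + 1L), 2:(ny + 2L)]      # (x,   y+1)
  d <- pad[2:(nx + 2L), 2:(ny + 2L)]       # (x+1, y+1)
  code <- a + 2L * b + 4L * cc + 8L * d
  diag_len <- sqrt((sx / 2)^2 + (sy / 2)^2)
  # segment length per marching-squares case (0 and 15 carry none; the two
  # saddle cases 6 and 9 carry two diagonal segments)
  seg <- c(0, diag_len, diag_len, sx, diag_len, sy, 2 * diag_len, diag_len,
           diag_len, 2 * diag_len, sy, diag_len, sx, diag_len, diag_len, 0)
  sum(seg[code + 1L])
}
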