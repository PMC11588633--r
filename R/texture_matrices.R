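#' Texture-matrix parameters
#'
#' The three swept radiomic parameters: the discretization bin count, the
#' kernel (the in-plane neighborhood radius, in voxels, around a voxel within
#' which spatial relationships are accumulated) and the set of in-plane
#' angles (the four quadrant directions). Co-occurrence offsets are generated
#' at distances `1..kernel` along each angle, one matrix per
#' (distance, angle) pair.
#'
#' @param bin_count discretization bin count (power of two, 2..256).
#' @param kernel neighborhood radius, integer 1..5.
#' @param angles subset of `c(0, 45, 90, 135)` (degrees, in-plane).
#' @param distance co-occurrence offset length, `1..kernel`.
#' @return An object of class `texture_params`.
#' @export
texture_params <- function(bin_count = 32L, kernel = 1L,
                           angles = c(0, 45, 90, 135), distance = 1L) {
  kernel <- as.integer(kernel)
  distance <- as.integer(distance)
  if (kernel < 1L || kernel > 5L) stop("kernel must be in 1..5", call. = FALSE)
  if (length(angles) == 0L || !all(angles %in% c(0, 45, 90, 135))) {
    stop("angles must be a non-empty subset of {0, 45, 90, 135}",
         call. = FALSE)
  }
  if (distance < 1L || distance > kernel) {
    stop("distance must be in 1..kernel", call. = FALSE)
  }
  structure(
    list(bin_count = discretization_config(bin_count)$bin_count,
         kernel = kernel, angles = as.numeric(angles), distance = distance),
    class = "texture_params"
  )
}

# in-plane unit offset for each quadrant angle
angle_offset <- function(angle) {
  switch(as.character(angle),
    "0" = c(1L, 0L),
    "45" = c(1L, 1L),
    "90" = c(0L, 1L),
    "135" = c(-1L, 1L),
    stop("angle must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

check_level_map <- function(levels) {
  if (!inherits(levels, "level_map")) {
    stop("`levels` must be a level_map from discretize()", call. = FALSE)
  }
}

#' Grey-level co-occurrence matrix at one offset
#'
#' Symmetric accumulation of co-occurring level pairs at the in-plane offset
#' `distance * angle_direction`, per axial slice, summed over slices, and
#' restricted to pairs with both voxels inside the ROI. The matrix total is
#' twice the number of valid ordered pairs.
#'
#' @param levels a `level_map` from [discretize()].
#' @param params a [texture_params()] (supplies the kernel bound).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param distance offset length in voxels, at most `params$kernel`.
#' @return Object of class `glc_matrix`: integer `counts` (B x B, symmetric),
#'   `degenerate` flag (TRUE when no valid pair exists).
#' @export
compute_glcm <- function(levels, params = texture_params(), angle = 0,
                         distance = 1L) {
  check_level_map(levels)
  if (!angle %in% params$angles) {
    stop("angle not in params$angles", call. = FALSE)
  }
  if (distance > params$kernel) {
    stop("distance exceeds kernel radius", call. = FALSE)
  }
  off <- angle_offset(angle) * as.integer(distance)
  counts <- cpp_glcm(as.vector(levels$levels), dim(levels$levels),
                     levels$bin_count, off[1], off[2])
  structure(
    list(counts = counts, symmetric = TRUE, angle = angle,
         distance = as.integer(distance), degenerate = sum(counts) == 0L),
    class = "glc_matrix"
  )
}

#' Grey-level run-length matrix along one direction
#'
#' Maximal runs of equal level along the angle direction, per axial slice;
#' out-of-ROI voxels break runs. Row i, column j counts runs of level i and
#' length j; the run lengths weighted by their counts sum to the ROI voxel
#' count.
#'
#' @inheritParams compute_glcm
#' @return Object of class `glrl_matrix` with integer `counts`
#'   (B x max run length).
#' @export
compute_glrlm <- function(levels, angle = 0) {
  check_level_map(levels)
  off <- angle_offset(angle)
  counts <- cpp_glrlm(as.vector(levels$levels), dim(levels$levels),
                      levels$bin_count, off[1], off[2])
  keep <- max(1L, max(which(colSums(counts) > 0L), 1L))
  structure(
    list(counts = counts[, seq_len(keep), drop = FALSE], angle = angle,
         n_roi = levels$n_roi),
    class = "glrl_matrix"
  )
}

#' Grey-level size-zone matrix
#'
#' Connected zones of equal level under 26-connectivity in 3D (the one
#' direction-free family, hence fully volumetric). Row i, column s counts
#' zones of level i and size s; zone sizes weighted by counts sum to the ROI
#' voxel count.
#'
#' @inheritParams compute_glcm
#' @return Object of class `glsz_matrix` with integer `counts`
#'   (B x max zone size).
#' @export
compute_glszm <- function(levels) {
  check_level_map(levels)
  counts <- cpp_glszm(as.vector(levels$levels), dim(levels$levels),
                      levels$bin_count)
  structure(list(counts = counts, n_roi = levels$n_roi),
            class = "glsz_matrix")
}

#' Grey-level dependence matrix
#'
#' For each ROI voxel, its dependence is the number of in-plane neighbors
#' within Chebyshev radius `kernel` whose level differs by at most `alpha`
#' (default 0: exact-level dependence). Row i, column k+1 counts voxels of
#' level i with dependence k; the matrix total equals the ROI voxel count.
#'
#' @inheritParams compute_glcm
#' @param alpha level-difference tolerance (default 0).
#' @return Object of class `gld_matrix` with integer `counts`
#'   (B x (max dependence + 1)); column k holds dependence k - 1.
#' @export
compute_gldm <- function(levels, params = texture_params(), alpha = 0L) {
  check_level_map(levels)
  counts <- cpp_gldm(as.vector(levels$levels), dim(levels$levels),
                     levels$bin_count, params$kernel, as.integer(alpha))
  nz <- which(colSums(counts) > 0L)
  keep <- if (length(nz)) max(nz) else 1L
  structure(
    list(counts = counts[, seq_len(keep), drop = FALSE],
         kernel = params$kernel, alpha = as.integer(alpha),
         n_roi = levels$n_roi),
    class = "gld_matrix"
  )
}

#' Neighbourhood grey-tone difference statistics
#'
#' For each grey level i: the number of ROI voxels of that level with at
#' least one in-kernel, in-plane neighbor (`n_i`), and the summed absolute
#' deviation `s_i` of those voxels from their neighborhood mean level. The
#' occurrence probabilities `p_i = n_i / sum(n)` sum to one over occurring
#' levels.
#'
#' @inheritParams compute_glcm
#' @return Object of class `ngtdm_row` with fields `n`, `s`, `p` (length-B
#'   vectors) and `n_valid`.
#' @export
compute_ngtdm <- function(levels, params = texture_params()) {
  check_level_map(levels)
  m <- cpp_ngtdm(as.vector(levels$levels), dim(levels$levels),
                 levels$bin_count, params$kernel)
  n <- m[, 1]
  total <- sum(n)
  structure(
    list(n = n, s = m[, 2], p = if (total > 0) n / total else n,
         n_valid = total, kernel = params$kernel),
    class = "ngtdm_row"
  )
}
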