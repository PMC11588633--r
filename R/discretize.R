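#' Discretization configuration
#'
#' Fixed-bin-count, equal-width discretization of the intensities inside an
#' ROI. Bin counts are the powers of two from 2 to 256, matching the swept
#' range of the texture parameter grid.
#'
#' @param bin_count one of 2, 4, 8, 16, 32, 64, 128, 256.
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(bin_count = 32L) {
  bin_count <- as.integer(bin_count)
  if (length(bin_count) != 1L || !bin_count %in% 2L^(1:8)) {
    stop("bin_count must be a power of two in 2..256", call. = FALSE)
  }
  structure(list(bin_count = bin_count), class = "discretization_config")
}

#' Discretize ROI intensities to integer grey levels
#'
#' Equal-width binning with a fixed number of bins over the min-max range of
#' the in-ROI intensities (per-tumor range, so texture reflects intra-tumor
#' contrast). Level `l = min(floor((v - min) / width) + 1, bin_count)`, so the
#' maximum maps to `bin_count`, not `bin_count + 1`. A constant ROI maps every
#' voxel to level 1. Out-of-ROI voxels carry the sentinel level 0.
#'
#' @param volume a [volume3d()] (normalized intensities).
#' @param roi a [mask3d()]; non-zero voxels form the ROI.
#' @param config a [discretization_config()] (or bare bin count).
#' @return An object of class `level_map`: integer `levels` array (0 outside
#'   the ROI), `bin_count`, `bin_edges`, `n_roi`.
#' @examples
#' v <- volume3d(array(c(0, 0.5, 1, 0), c(2, 2, 1)))
#' m <- mask3d(array(c(1L, 1L, 1L, 0L), c(2, 2, 1)))
#' discretize(v, m, discretization_config(2))$levels
#' @export
discretize <- function(volume, roi, config = discretization_config()) {
  stopifnot(inherits(volume, "volume3d"), inherits(roi, "mask3d"))
  if (is.numeric(config)) config <- discretization_config(config)
  check_same_grid(volume, roi, "volume", "roi")
  in_roi <- roi$labels != 0L
  n_roi <- sum(in_roi)
  if (n_roi == 0L) stop("ROI is empty", call. = FALSE)
  vals <- volume$voxels[in_roi]
  if (any(!is.finite(vals))) {
    stop("ROI contains non-finite intensities", call. = FALSE)
  }
  b <- config$bin_count
  rng <- range(vals)
  levels <- array(0L, dim = volume$shape)
  if (rng[2] > rng[1]) {
    width <- (rng[2] - rng[1]) / b
    lv <- pmin(floor((vals - rng[1]) / width) + 1, b)
    edges <- rng[1] + width * (0:b)
  } else {
    lv <- rep(1L, n_roi)
    edges <- c(rng[1], rng[1])
  }
  levels[in_roi] <- as.integer(lv)
  structure(
    list(levels = levels, bin_count = b, bin_edges = edges,
         spacing = volume$spacing, n_roi = n_roi),
    class = "level_map"
  )
}

#' @export
print.level_map <- function(x, ...) {
  cat(sprintf("<level_map> %s grid, %d ROI voxels, %d levels\n",
              paste(dim(x$levels), collapse = "x"), x$n_roi, x$bin_count))
  invisible(x)
}
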