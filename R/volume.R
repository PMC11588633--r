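#' 3D image volume with physical spacing
#'
#' A `volume3d` wraps a numeric 3D array of voxel values together with the
#' per-axis physical voxel size in millimetres. It is the in-memory form of a
#' CT volume after loading (and, typically, after [normalize_intensity()]).
#'
#' @param voxels numeric 3D array of voxel values.
#' @param spacing numeric length-3 vector, physical voxel size in mm per axis;
#'   all entries must be positive.
#' @param validate logical; check that all voxel values are finite.
#' @return An object of class `volume3d` with fields `voxels`, `spacing` and
#'   `shape` (axis lengths in voxels).
#' @examples
#' v <- volume3d(array(runif(64), c(4, 4, 4)), spacing = c(1, 1, 2))
#' v$shape
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), validate = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  storage.mode(voxels) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (validate && any(!is.finite(voxels))) {
    stop("volume contains non-finite voxel values", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, shape = dim(voxels)),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf(
    "<volume3d> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' Labeled 3D mask aligned to a volume
#'
#' A `mask3d` is an integer label grid on the same voxel lattice as a
#' [volume3d()]. Binary masks use code 1; subregion masks use the codes of
#' `label_map` (by default `c(head = 1, body = 2, tail = 3)` plus
#' `tumor = 1` / `pancreas = 1` for single-structure masks). Codes found in
#' the grid must be declared in `label_map` (0 is always background).
#'
#' @param labels integer 3D array (0 = background).
#' @param spacing numeric length-3 voxel size in mm.
#' @param label_map named integer vector mapping semantic names to codes.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(labels, spacing = c(1, 1, 1),
                   label_map = c(foreground = 1L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stop("mask labels must be finite integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  }
  label_map <- vapply(label_map, as.integer, integer(1))
  present <- setdiff(unique(as.vector(labels)), 0L)
  undeclared <- setdiff(present, label_map)
  if (length(undeclared) > 0) {
    stop(
      "mask contains codes not in label_map: ",
      paste(undeclared, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(labels = labels, spacing = spacing, shape = dim(labels),
         label_map = label_map),
    class = "mask3d"
  )
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf(
    "<mask3d> %s voxels, %d foreground, labels {%s}\n",
    paste(x$shape, collapse = "x"), sum(x$labels != 0L),
    paste(names(x$label_map), x$label_map, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

# shared geometry check used by case_record and the texture front-ends
check_same_grid <- function(a, b, what_a = "volume", what_b = "mask") {
  if (!identical(dim_of(a), dim_of(b))) {
    stop(sprintf(
      "geometry mismatch: %s grid is %s but %s grid is %s",
      what_a, paste(dim_of(a), collapse = "x"),
      what_b, paste(dim_of(b), collapse = "x")
    ), call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop(sprintf(
      "spacing mismatch between %s and %s", what_a, what_b
    ), call. = FALSE)
  }
  invisible(TRUE)
}

dim_of <- function(x) {
  if (inherits(x, "volume3d")) dim(x$voxels) else dim(x$labels)
}

#' Bundle one case: volume, tumor mask, pancreas mask, class label
#'
#' @param case_id character scalar identifier.
#' @param volume a [volume3d()].
#' @param tumor_mask,pancreas_mask [mask3d()] objects on the same grid as
#'   `volume`. The tumor mask must be non-empty.
#' @param region_label `"head"`, `"body_tail"`, or `NA` for unlabeled cases.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, volume, tumor_mask, pancreas_mask = NULL,
                        region_label = NA_character_) {
  stopifnot(inherits(volume, "volume3d"), inherits(tumor_mask, "mask3d"))
  check_same_grid(volume, tumor_mask, "volume", "tumor mask")
  if (!is.null(pancreas_mask)) {
    stopifnot(inherits(pancreas_mask, "mask3d"))
    check_same_grid(volume, pancreas_mask, "volume", "pancreas mask")
  }
  if (sum(tumor_mask$labels != 0L) == 0L) {
    stop("tumor mask is empty", call. = FALSE)
  }
  if (!is.na(region_label) &&
      !region_label %in% c("head", "body_tail")) {
    stop('region_label must be "head", "body_tail" or NA', call. = FALSE)
  }
  structure(
    list(case_id = as.character(case_id), volume = volume,
         tumor_mask = tumor_mask, pancreas_mask = pancreas_mask,
         region_label = region_label),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "<case_record> %s (%s): %s grid, tumor %d voxels\n",
    x$case_id, ifelse(is.na(x$region_label), "unlabeled", x$region_label),
    paste(x$volume$shape, collapse = "x"), sum(x$tumor_mask$labels != 0L)
  ))
  invisible(x)
}

#' Min-max normalize a volume to [0, 1]
#'
#' Rescales so the volume minimum maps to 0 and the maximum to 1, over the
#' whole volume (not an ROI). A constant volume maps to all zeros: a constant
#' carries no intensity signal and zero is the conventional fixed point. The
#' map is monotone, so voxel ordering is preserved, and it is idempotent.
#'
#' @param volume a [volume3d()] with finite voxels.
#' @return A [volume3d()] with voxels in `[0, 1]`.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "volume3d"))
  v <- volume$voxels
  if (any(!is.finite(v))) {
    stop("cannot normalize: volume contains non-finite voxels", call. = FALSE)
  }
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    v[] <- 0
  }
  volume3d(v, volume$spacing, validate = FALSE)
}
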