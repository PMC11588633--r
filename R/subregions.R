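#' Subregion voxel-fraction specification
#'
#' The pancreas head, body and tail occupy roughly 40%, 33% and 26% of the
#' organ; the default fractions are (0.40, 0.33, 0.27), with 0.27 absorbing
#' the rounding so the triple sums to one.
#'
#' @param fractions ordered numeric triple (head, body, tail); all positive,
#'   summing to 1 within 1e-9.
#' @return An object of class `subregion_spec`.
#' @export
subregion_spec <- function(fractions = c(head = 0.40, body = 0.33, tail = 0.27)) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(!is.finite(fractions)) ||
      any(fractions <= 0)) {
    stop("fractions must be three positive numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(list(fractions = setNames(fractions, c("head", "body", "tail"))),
            class = "subregion_spec")
}

#' Partition a pancreas mask into head / body / tail
#'
#' Proportional partition along the organ's own long axis: pancreas voxels
#' are ordered by their projection onto the first principal axis of the
#' voxel coordinates (in physical mm) and cut at cumulative voxel fractions
#' 0.40 and 0.73 (default spec), at the nearest boundary between projection
#' groups — voxels sharing a projection value (a grid-aligned slice) are
#' never split, so each realized fraction deviates from the spec by at most
#' one slab of the ordering axis. The head end is the end whose terminal 10% of slabs has the larger
#' mean cross-sectional voxel count (the head is the bulkiest part of the
#' organ, sitting in the duodenal curve); on an exact tie the end with the
#' smaller x-centroid is called head (patient-right convention). The
#' pancreatic neck is not distinguished: it is absorbed into the head.
#'
#' Because the rule follows the principal axis, not the array axes, the
#' partition is stable under rotation or translation of the whole grid.
#'
#' @param pancreas_mask a [mask3d()]; all non-zero voxels are pancreas.
#' @param spec a [subregion_spec()].
#' @return A [mask3d()] with codes `c(head = 1, body = 2, tail = 3)`.
#' @export
partition_pancreas <- function(pancreas_mask, spec = subregion_spec()) {
  stopifnot(inherits(pancreas_mask, "mask3d"), inherits(spec, "subregion_spec"))
  idx <- which(pancreas_mask$labels != 0L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("pancreas mask is empty", call. = FALSE)
  if (n < 2L) stop("pancreas mask is degenerate (single voxel)", call. = FALSE)
  coords <- sweep(idx, 2L, pancreas_mask$spacing, `*`)
  pc <- prcomp(coords, center = TRUE, scale. = FALSE)
  proj <- pc$x[, 1]
  if (max(proj) - min(proj) < .Machine$double.eps^0.5) {
    stop("pancreas mask has no principal axis extent", call. = FALSE)
  }

  # slab the projection at the finest in-plane pitch so "within one slab"
  # matches the axial-slice granularity of a grid-aligned organ
  pitch <- min(pancreas_mask$spacing)
  n_slabs <- max(2L, ceiling((max(proj) - min(proj)) / pitch + 1e-9))
  slab <- pmin(
    n_slabs,
    pmax(1L, ceiling((proj - min(proj)) / (max(proj) - min(proj)) * n_slabs))
  )
  slab[proj == min(proj)] <- 1L

  # head-end disambiguation: mean cross-section over the terminal 10% of slabs
  counts <- tabulate(slab, nbins = n_slabs)
  tip <- max(1L, ceiling(0.1 * n_slabs))
  occupied <- which(counts > 0)
  low_sl <- occupied[occupied <= min(occupied) + tip - 1L]
  high_sl <- occupied[occupied >= max(occupied) - tip + 1L]
  low_mean <- mean(counts[low_sl])
  high_mean <- mean(counts[high_sl])
  flip <- if (abs(low_mean - high_mean) > 1e-9) {
    high_mean > low_mean
  } else {
    # tie: head at the smaller x-centroid end
    x_low <- mean(coords[slab %in% low_sl, 1])
    x_high <- mean(coords[slab %in% high_sl, 1])
    x_high < x_low
  }
  if (flip) proj <- -proj

  # order voxels by projection and cut at the cumulative voxel fractions;
  # voxels sharing a projection value stay together (one grid-aligned slice
  # is never split), so realized fractions deviate by at most one slab
  o <- order(proj)
  gid <- cumsum(c(TRUE, diff(proj[o]) > 1e-9))
  cum <- cumsum(tabulate(gid)) / n
  f <- cumsum(spec$fractions)
  head_last <- which.min(abs(cum - f[1]))
  body_last <- max(head_last, which.min(abs(cum - f[2])))
  region <- integer(n)
  region[o] <- ifelse(gid <= head_last, 1L,
                      ifelse(gid <= body_last, 2L, 3L))

  labels <- array(0L, dim = pancreas_mask$shape)
  labels[idx] <- region
  mask3d(labels, pancreas_mask$spacing,
         label_map = c(head = 1L, body = 2L, tail = 3L))
}

#' Assign a tumor to the head or body/tail class
#'
#' Plurality vote over the subregion labels of the tumor's voxels; body and
#' tail are pooled into a single `body_tail` class. A tumor with no voxel on
#' a labeled subregion voxel is assigned from the subregion labels within
#' `tolerance_mm` (Chebyshev, in voxel steps of the coarsest axis) of its
#' voxels; if none are found it is unassignable. An exact 50/50 head vs
#' body/tail tie resolves to head (deterministic, documented).
#'
#' @param tumor_mask a [mask3d()] of the tumor.
#' @param subregion_labels a [mask3d()] from [partition_pancreas()].
#' @param tolerance_mm search margin around the tumor when it does not touch
#'   the labeled pancreas (default 10 mm).
#' @return `"head"` or `"body_tail"`.
#' @export
assign_tumor_region <- function(tumor_mask, subregion_labels,
                                tolerance_mm = 10) {
  stopifnot(inherits(tumor_mask, "mask3d"), inherits(subregion_labels, "mask3d"))
  check_same_grid(tumor_mask, subregion_labels, "tumor mask", "subregion labels")
  in_tumor <- tumor_mask$labels != 0L
  if (!any(in_tumor)) stop("tumor mask is empty", call. = FALSE)
  lab <- subregion_labels$labels[in_tumor]
  lab <- lab[lab != 0L]
  if (length(lab) == 0L) {
    # grow the tumor by the tolerance and re-test overlap
    steps <- pmax(1L, floor(tolerance_mm / tumor_mask$spacing))
    grown <- dilate_binary(in_tumor, steps)
    lab <- subregion_labels$labels[grown]
    lab <- lab[lab != 0L]
    if (length(lab) == 0L) {
      stop("tumor has no overlap with labeled pancreas within tolerance",
           call. = FALSE)
    }
  }
  n_head <- sum(lab == 1L)
  if (n_head >= length(lab) - n_head) "head" else "body_tail"
}

# Chebyshev dilation of a logical array by steps[axis] voxels per axis,
# via per-axis sweeps (separable for box structuring elements).
dilate_binary <- function(x, steps) {
  d <- dim(x)
  out <- x
  for (axis in 1:3) {
    if (steps[axis] < 1L) next
    acc <- out
    for (s in seq_len(steps[axis])) {
      lo <- shift_array(out, axis, s)
      hi <- shift_array(out, axis, -s)
      acc <- acc | lo | hi
    }
    out <- acc
  }
  out
}

shift_array <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  if (abs(by) >= d[axis]) return(out)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) {
    idx_dst[[axis]] <- seq(by + 1L, d[axis])
    idx_src[[axis]] <- seq(1L, d[axis] - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- seq(1L, d[axis] + by)
    idx_src[[axis]] <- seq(1L - by, d[axis])
  }
  if (length(idx_dst[[axis]]) == 0L) return(out)
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(x), idx_src)))))
}
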