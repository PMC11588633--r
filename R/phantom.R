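#' Phantom cohort specification
#'
#' Defines the generative conditions for synthetic labeled cohorts that carry
#' the class structure the analysis assumes: a 58/42 head vs body/tail split
#' per 100-case cohort, head tumors smaller (equivalent-sphere diameters
#' drawn uniformly from 2.4-3.1 cm) and brighter (+0.15 on the normalized
#' intensity scale), body/tail tumors larger (5.6-6.1 cm) with a coarser
#' planted texture (longer noise correlation length). Volumes are normalized
#' to [0, 1] after synthesis.
#'
#' @param n_head,n_bodytail cases per class (defaults 58 / 42).
#' @param head_diameter_cm,bodytail_diameter_cm equivalent-sphere diameter
#'   ranges in cm (uniformly sampled).
#' @param head_intensity_offset additive head-tumor contrast on the
#'   normalized scale (default +0.15).
#' @param head_corr_length,bodytail_corr_length Gaussian correlation length
#'   (voxels) of the planted intra-tumor texture noise per class.
#' @param texture_sd standard deviation of the planted texture field.
#' @param noise_sd global white-noise standard deviation.
#' @param grid_shape,spacing voxel grid and spacing (mm).
#' @param seed mandatory integer seed; generation is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_head = 58L, n_bodytail = 42L,
                         head_diameter_cm = c(2.4, 3.1),
                         bodytail_diameter_cm = c(5.6, 6.1),
                         head_intensity_offset = 0.15,
                         head_corr_length = 1.2,
                         bodytail_corr_length = 2.5,
                         texture_sd = 0.08,
                         noise_sd = 0.03,
                         grid_shape = c(88L, 56L, 32L),
                         spacing = c(2, 2, 3),
                         seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("phantom_spec requires an integer seed", call. = FALSE)
  }
  n_head <- as.integer(n_head)
  n_bodytail <- as.integer(n_bodytail)
  if (n_head < 2L || n_bodytail < 2L) {
    stop("need at least two cases per class", call. = FALSE)
  }
  chk_rng <- function(r, what) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop(what, " must be a positive ordered range", call. = FALSE)
    }
  }
  chk_rng(head_diameter_cm, "head_diameter_cm")
  chk_rng(bodytail_diameter_cm, "bodytail_diameter_cm")
  structure(
    list(n_head = n_head, n_bodytail = n_bodytail,
         head_diameter_cm = head_diameter_cm,
         bodytail_diameter_cm = bodytail_diameter_cm,
         head_intensity_offset = head_intensity_offset,
         head_corr_length = head_corr_length,
         bodytail_corr_length = bodytail_corr_length,
         texture_sd = texture_sd, noise_sd = noise_sd,
         grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# separable 3D Gaussian smoothing via per-axis kernel-matrix products;
# zero-padded convolution with a constant normalizer, so the operator is
# translation invariant (no edge renormalization)
smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  for (axis in 1:3) {
    n <- d[axis]
    k <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), `-`)), sd = sigma)
    k <- k / sum(stats::dnorm(seq(-n + 1, n - 1), sd = sigma))
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dim(xp) <- c(n, prod(d[-axis]))
    xp <- k %*% xp
    dim(xp) <- d[perm]
    x <- aperm(xp, order(perm))
  }
  x
}

# curved, head-heavy tubular pancreas mask; t = 0 is the head end
make_pancreas <- function(shape, spacing) {
  nx <- shape[1]
  ny <- shape[2]
  nz <- shape[3]
  length_mm <- runif(1, 120, 150)
  lx <- min(nx - 8L, round(length_mm / spacing[1]))
  x0 <- max(2L, round((nx - lx) / 2))
  xs <- x0:(x0 + lx - 1L)
  t <- (seq_along(xs) - 1) / (length(xs) - 1)
  amp <- runif(1, 4, 9)
  cy <- ny * 0.55 + amp * sin(pi * t) - amp / 2
  cz <- nz / 2 + runif(1, -1, 1)
  # anteroposterior radius tapers from the bulky head to the tail
  r_mm <- 6 + 9 * (1 - t)^1.3 + runif(1, -0.5, 0.5)
  labels <- array(0L, dim = shape)
  yy <- matrix(rep(seq_len(ny), nz), ny, nz)
  zz <- matrix(rep(seq_len(nz), each = ny), ny, nz)
  for (ii in seq_along(xs)) {
    ry <- r_mm[ii] / spacing[2]
    rz <- r_mm[ii] / spacing[3]
    sl <- ((yy - cy[ii]) / ry)^2 + ((zz - cz) / rz)^2 <= 1
    plane <- labels[xs[ii], , ]
    plane[sl] <- 1L
    labels[xs[ii], , ] <- plane
  }
  mask3d(labels, spacing, label_map = c(pancreas = 1L))
}

# ellipsoid with smooth boundary perturbation, centered inside the grid
make_tumor <- function(shape, spacing, center, radius_mm) {
  f1 <- runif(1, 0.9, 1.1)
  f2 <- runif(1, 0.9, 1.1)
  f <- c(f1, f2, 1 / (f1 * f2))
  pert <- smooth3d(array(rnorm(prod(shape)), shape), sigma = 2)
  pert <- pert / sd(pert)
  ax <- lapply(1:3, function(a) {
    (seq_len(shape[a]) - center[a]) * spacing[a] / (radius_mm * f[a])
  })
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  labels <- array(0L, dim = shape)
  labels[q <= (1 + 0.12 * pert)^2] <- 1L
  mask3d(labels, spacing, label_map = c(tumor = 1L))
}

generate_case <- function(spec, case_id, class, diameter_range, offset,
                          corr_length) {
  shape <- spec$grid_shape
  sp <- spec$spacing
  pancreas <- make_pancreas(shape, sp)
  regions <- partition_pancreas(pancreas)

  d_cm <- runif(1, diameter_range[1], diameter_range[2])
  r_mm <- d_cm * 10 / 2
  margin <- r_mm / sp + 2
  if (any(2 * margin >= shape)) {
    stop(sprintf(
      "tumor of diameter %.1f cm does not fit a %s grid at %s mm spacing; enlarge grid_shape",
      d_cm, paste(shape, collapse = "x"), paste(sp, collapse = "x")),
      call. = FALSE)
  }
  target_codes <- if (class == "head") 1L else c(2L, 3L)
  cand <- which(array(regions$labels %in% target_codes, dim = shape),
                arr.ind = TRUE)
  center <- cand[sample.int(nrow(cand), 1L), ]
  center <- pmin(pmax(center, ceiling(margin)), shape - ceiling(margin))
  tumor <- make_tumor(shape, sp, center, r_mm)

  raw <- array(0.40, dim = shape) + spec$noise_sd * rnorm(prod(shape))
  raw[pancreas$labels != 0L] <- raw[pancreas$labels != 0L] + 0.10
  in_tumor <- tumor$labels != 0L
  texture <- smooth3d(array(rnorm(prod(shape)), shape), corr_length)
  texture <- texture / sd(texture[in_tumor])
  raw[in_tumor] <- 0.45 + offset + spec$texture_sd * texture[in_tumor]
  volume <- normalize_intensity(volume3d(raw, sp, validate = FALSE))

  rec <- case_record(case_id, volume, tumor, pancreas, class)
  rec$subregion_mask <- regions
  rec
}

#' Generate a labeled phantom cohort
#'
#' For each case: an elongated, head-heavy tubular pancreas mask; a tumor
#' (perturbed ellipsoid) centered in the head or body/tail subregion of the
#' proportional partition; intensities built from tissue baselines plus
#' white noise, with intra-tumor texture drawn from class-specific
#' Gaussian-correlated noise and head tumors receiving the intensity offset;
#' the volume min-max normalized to [0, 1]. Head cases come first, then
#' body/tail. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return List of [case_record()]s (each also carries its `subregion_mask`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  cases <- vector("list", spec$n_head + spec$n_bodytail)
  for (ii in seq_len(spec$n_head)) {
    cases[[ii]] <- generate_case(
      spec, sprintf("phantom_%03d_head", ii), "head",
      spec$head_diameter_cm, spec$head_intensity_offset,
      spec$head_corr_length)
  }
  for (jj in seq_len(spec$n_bodytail)) {
    cases[[spec$n_head + jj]] <- generate_case(
      spec, sprintf("phantom_%03d_bodytail", jj), "body_tail",
      spec$bodytail_diameter_cm, 0, spec$bodytail_corr_length)
  }
  cases
}

#' Generate a null cohort (no class difference)
#'
#' Identical generative process for both classes — head diameter range,
#' zero intensity offset and a common texture correlation length (the mean
#' of the two class lengths) — with only the placement subregion and the
#' label differing. Used for type-I-error and chance-AUC calibration.
#'
#' @param spec a [phantom_spec()].
#' @return List of [case_record()]s.
#' @export
generate_null_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  corr <- mean(c(spec$head_corr_length, spec$bodytail_corr_length))
  cases <- vector("list", spec$n_head + spec$n_bodytail)
  for (ii in seq_len(spec$n_head)) {
    cases[[ii]] <- generate_case(
      spec, sprintf("null_%03d_head", ii), "head",
      spec$head_diameter_cm, 0, corr)
  }
  for (jj in seq_len(spec$n_bodytail)) {
    cases[[spec$n_head + jj]] <- generate_case(
      spec, sprintf("null_%03d_bodytail", jj), "body_tail",
      spec$head_diameter_cm, 0, corr)
  }
  cases
}

#' Generate one synthetic pancreas mask
#'
#' Convenience wrapper producing just the elongated pancreas mask of the
#' phantom generator (head end bulkier), for subregion-partition studies.
#'
#' @param spec a [phantom_spec()] (grid, spacing and seed are used).
#' @return A [mask3d()].
#' @export
generate_pancreas_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  make_pancreas(spec$grid_shape, spec$spacing)
}

#' Write a phantom cohort to disk
#'
#' Volumes and masks as NIfTI (or NRRD) plus a `labels.csv` label file.
#'
#' @param cases list of [case_record()]s.
#' @param dir output directory.
#' @param format `"nifti"` or `"nrrd"`.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cases, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cases) write_case(case, dir, format)
  write_labels(
    data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
               region_label = vapply(cases, `[[`, "", "region_label"),
               stringsAsFactors = FALSE),
    file.path(dir, "labels.csv")
  )
  invisible(dir)
}
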