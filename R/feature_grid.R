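#' Parameter-grid specification for the feature sweep
#'
#' The full default grid sweeps every texture family over the parameter axes
#' it genuinely depends on: co-occurrence over bins x offset distances (one
#' matrix per distance `1..kernel` per angle) x angles, run length over
#' bins x angles, size zone over bins only (direction-free), dependence and
#' grey-tone difference over bins x kernels. First-order statistics are
#' computed once (their entropy histogram uses a fixed bin count) and shape
#' features once (parameter-free). The default grid yields
#' `20*8*5*4 + 15*8*4 + 14*8 + 12*8*5 + 5*8*5 + 15 + 20 = 4507` descriptors.
#'
#' @param bin_counts subset of the powers of two 2..256.
#' @param kernels subset of 1..5 (co-occurrence distances and dependence /
#'   grey-tone kernel radii).
#' @param angles subset of `c(0, 45, 90, 135)`.
#' @param families subset of `c("firstorder", "shape", "glcm", "glrlm",
#'   "glszm", "gldm", "ngtdm")`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(bin_counts = 2L^(1:8), kernels = 1:5,
                      angles = c(0, 45, 90, 135),
                      families = c("firstorder", "shape", "glcm", "glrlm",
                                   "glszm", "gldm", "ngtdm")) {
  bin_counts <- sort(unique(as.integer(bin_counts)))
  kernels <- sort(unique(as.integer(kernels)))
  if (length(bin_counts) == 0L || !all(bin_counts %in% 2L^(1:8))) {
    stop("bin_counts must be a non-empty subset of 2,4,...,256", call. = FALSE)
  }
  if (length(kernels) == 0L || !all(kernels %in% 1:5)) {
    stop("kernels must be a non-empty subset of 1..5", call. = FALSE)
  }
  if (length(angles) == 0L || !all(angles %in% c(0, 45, 90, 135))) {
    stop("angles must be a non-empty subset of {0,45,90,135}", call. = FALSE)
  }
  allowed <- c("firstorder", "shape", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
  if (length(families) == 0L || !all(families %in% allowed)) {
    stop("unknown feature family", call. = FALSE)
  }
  structure(
    list(bin_counts = bin_counts, kernels = kernels,
         angles = sort(unique(as.numeric(angles))),
         families = allowed[allowed %in% families]),
    class = "grid_spec"
  )
}

family_feature_names <- function(family) {
  switch(family,
    firstorder = c("mean", "median", "minimum", "maximum", "range", "p10",
                   "p25", "p75", "p90", "variance", "skewness", "kurtosis",
                   "energy", "entropy", "mean_absolute_deviation"),
    shape = c("voxel_volume", "mesh_volume", "surface_area",
              "surface_to_volume_ratio", "sphericity", "compactness",
              "equivalent_sphere_diameter", "max_3d_diameter",
              "major_axis_length", "minor_axis_length", "least_axis_length",
              "elongation", "flatness", "slice_area", "slice_perimeter",
              "perimeter_to_area", "circularity", "max_2d_diameter_axial",
              "max_2d_diameter_coronal", "max_2d_diameter_sagittal"),
    glcm = names(glcm_features(structure(
      list(counts = matrix(0L, 1, 1)), class = "glc_matrix"))),
    glrlm = names(glrlm_features(structure(
      list(counts = matrix(0L, 1, 1), n_roi = 1L), class = "glrl_matrix"))),
    glszm = names(glszm_features(structure(
      list(counts = matrix(0L, 1, 1), n_roi = 1L), class = "glsz_matrix"))),
    gldm = names(gldm_features(structure(
      list(counts = matrix(0L, 1, 1)), class = "gld_matrix"))),
    ngtdm = c("coarseness", "contrast", "busyness", "complexity", "strength"),
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Enumerate the feature descriptors of a grid
#'
#' The descriptor table is a pure function of the [grid_spec()]: one row per
#' feature column, with the family, feature name and (bins, kernel, angle,
#' distance) provenance (0 / NA where an axis does not apply).
#'
#' @param grid a [grid_spec()].
#' @return data.frame with columns `id`, `family`, `name`, `bins`, `kernel`,
#'   `angle`, `distance`.
#' @export
grid_descriptors <- function(grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- list()
  add <- function(family, names, bins = 0L, kernel = 0L, angle = NA_real_,
                  distance = 0L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, name = names, bins = bins, kernel = kernel,
      angle = angle, distance = distance, stringsAsFactors = FALSE
    )
  }
  for (fam in grid$families) {
    fn <- family_feature_names(fam)
    if (fam == "firstorder" || fam == "shape") {
      add(fam, fn)
    } else if (fam == "glszm") {
      for (b in grid$bin_counts) add(fam, fn, bins = b)
    } else if (fam == "glrlm") {
      for (b in grid$bin_counts)
        for (a in grid$angles) add(fam, fn, bins = b, angle = a)
    } else if (fam == "glcm") {
      for (b in grid$bin_counts)
        for (k in grid$kernels)
          for (a in grid$angles)
            add(fam, fn, bins = b, kernel = k, angle = a, distance = k)
    } else {  # gldm, ngtdm
      for (b in grid$bin_counts)
        for (k in grid$kernels) add(fam, fn, bins = b, kernel = k)
    }
  }
  out <- do.call(rbind, rows)
  out$id <- descriptor_string(out)
  if (anyDuplicated(out$id)) stop("descriptor collision", call. = FALSE)
  out[, c("id", "family", "name", "bins", "kernel", "angle", "distance")]
}

descriptor_string <- function(d) {
  ang <- ifelse(is.na(d$angle), "none", format(d$angle, trim = TRUE))
  paste0(d$family, "__", d$name, "__b", d$bins, "_k", d$kernel,
         "_a", ang, "_d", d$distance)
}

parse_descriptors <- function(ids) {
  m <- regmatches(ids, regexec(
    "^([a-z]+)__(.+)__b([0-9]+)_k([0-9]+)_a([0-9.]+|none)_d([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 7L
  if (any(bad)) {
    stop("unparseable feature descriptor: ", ids[bad][1], call. = FALSE)
  }
  data.frame(
    id = ids,
    family = vapply(m, `[`, "", 2L),
    name = vapply(m, `[`, "", 3L),
    bins = as.integer(vapply(m, `[`, "", 4L)),
    kernel = as.integer(vapply(m, `[`, "", 5L)),
    angle = suppressWarnings(as.numeric(vapply(m, `[`, "", 6L))),
    distance = as.integer(vapply(m, `[`, "", 7L)),
    stringsAsFactors = FALSE
  )
}

#' Cases-by-features table with provenance-tagged descriptors
#'
#' @param values numeric matrix, one row per case; may contain `NaN`/`Inf`
#'   sentinels for unusable values.
#' @param case_ids character vector of row identifiers.
#' @param descriptors descriptor data.frame as from [grid_descriptors()].
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, case_ids, descriptors) {
  values <- as.matrix(values)
  if (nrow(values) != length(case_ids)) {
    stop("one row per case required", call. = FALSE)
  }
  if (ncol(values) != nrow(descriptors)) {
    stop("one column per descriptor required", call. = FALSE)
  }
  if (anyDuplicated(descriptors$id)) {
    stop("duplicate feature descriptors", call. = FALSE)
  }
  rownames(values) <- case_ids
  colnames(values) <- descriptors$id
  structure(list(values = values, case_ids = as.character(case_ids),
                 descriptors = descriptors),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cases x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$descriptors$family), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

subset_features <- function(table, keep) {
  feature_table(table$values[, keep, drop = FALSE], table$case_ids,
                table$descriptors[keep, , drop = FALSE])
}

subset_cases <- function(table, keep) {
  feature_table(table$values[keep, , drop = FALSE], table$case_ids[keep],
                table$descriptors)
}

#' Extract every grid feature for one case
#'
#' Runs the full parameter sweep of `grid` on the tumor ROI of `case`:
#' per bin count the ROI is discretized once and every requested texture
#' family reduced at each applicable (kernel, angle, distance) setting;
#' first-order and shape features are computed once. Extraction is
#' deterministic, and a failing family records `NaN` sentinels in its columns
#' rather than aborting the row.
#'
#' @param case a [case_record()].
#' @param grid a [grid_spec()].
#' @param alpha dependence-matrix level tolerance (default 0).
#' @return A one-row [feature_table()].
#' @export
extract_all <- function(case, grid = grid_spec(), alpha = 0L) {
  stopifnot(inherits(case, "case_record"))
  desc <- grid_descriptors(grid)
  vals <- setNames(rep(NaN, nrow(desc)), desc$id)
  put <- function(family, bins = 0L, kernel = 0L, angle = NA_real_,
                  distance = 0L, x) {
    sel <- desc$family == family & desc$bins == bins &
      desc$kernel == kernel & desc$distance == distance &
      (is.na(angle) & is.na(desc$angle) |
         (!is.na(angle) & !is.na(desc$angle) & desc$angle == angle))
    vals[desc$id[sel]] <<- x[desc$name[sel]]
  }
  safely <- function(expr) {
    tryCatch(expr, error = function(e) NULL)
  }

  if ("firstorder" %in% grid$families) {
    fo <- safely(firstorder_features(case$volume, case$tumor_mask))
    if (!is.null(fo)) put("firstorder", x = fo)
  }
  if ("shape" %in% grid$families) {
    sh <- safely(shape_features(case$tumor_mask))
    if (!is.null(sh)) put("shape", x = sh)
  }

  texture_fams <- intersect(grid$families,
                            c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  if (length(texture_fams) > 0) {
    kmax <- max(grid$kernels)
    for (b in grid$bin_counts) {
      lv <- safely(discretize(case$volume, case$tumor_mask,
                              discretization_config(b)))
      if (is.null(lv)) next
      if ("glszm" %in% texture_fams) {
        f <- safely(glszm_features(compute_glszm(lv)))
        if (!is.null(f)) put("glszm", bins = b, x = f)
      }
      if ("glrlm" %in% texture_fams) {
        for (a in grid$angles) {
          f <- safely(glrlm_features(compute_glrlm(lv, a)))
          if (!is.null(f)) put("glrlm", bins = b, angle = a, x = f)
        }
      }
      if ("glcm" %in% texture_fams) {
        tp <- texture_params(b, kernel = kmax, angles = grid$angles)
        for (k in grid$kernels) {
          for (a in grid$angles) {
            f <- safely(glcm_features(compute_glcm(lv, tp, a, k)))
            if (!is.null(f)) {
              put("glcm", bins = b, kernel = k, angle = a, distance = k, x = f)
            }
          }
        }
      }
      for (k in grid$kernels) {
        tp <- texture_params(b, kernel = k, angles = grid$angles)
        if ("gldm" %in% texture_fams) {
          f <- safely(gldm_features(compute_gldm(lv, tp, alpha)))
          if (!is.null(f)) put("gldm", bins = b, kernel = k, x = f)
        }
        if ("ngtdm" %in% texture_fams) {
          f <- safely(ngtdm_features(lv, tp))
          if (!is.null(f)) put("ngtdm", bins = b, kernel = k, x = f)
        }
      }
    }
  }
  feature_table(matrix(vals, nrow = 1), case$case_id, desc)
}

#' Extract features for a whole cohort
#'
#' @param cases list of [case_record()]s.
#' @param grid a [grid_spec()].
#' @param alpha dependence-matrix tolerance.
#' @param verbose print progress every 10 cases.
#' @return A [feature_table()] with one row per case, plus a `region_label`
#'   attribute holding the per-case class labels.
#' @export
extract_cohort <- function(cases, grid = grid_spec(), alpha = 0L,
                           verbose = FALSE) {
  rows <- vector("list", length(cases))
  for (ii in seq_along(cases)) {
    rows[[ii]] <- extract_all(cases[[ii]], grid, alpha)
    if (verbose && ii %% 10 == 0) {
      message("extracted ", ii, "/", length(cases), " cases")
    }
  }
  values <- do.call(rbind, lapply(rows, function(r) r$values))
  tab <- feature_table(values, vapply(cases, `[[`, "", "case_id"),
                       rows[[1]]$descriptors)
  attr(tab, "region_label") <- vapply(cases, `[[`, "", "region_label")
  tab
}

#' Write / read a feature table as CSV
#'
#' One row per case, one column per feature; the header encodes each
#' feature's family and (bins, kernel, angle, distance) provenance as
#' `family__name__b{bins}_k{kernel}_a{angle}_d{distance}`.
#'
#' @param table a non-empty [feature_table()].
#' @param path CSV file path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) == 0L || ncol(table$values) == 0L) {
    stop("feature table is empty", call. = FALSE)
  }
  df <- data.frame(case_id = table$case_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "case_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  feature_table(values, df$case_id, parse_descriptors(colnames(values)))
}
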