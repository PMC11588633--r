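#' @useDynLib pancradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx coef cor cov lm median na.omit p.adjust
#'   pnorm predict prcomp pt quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head tail
NULL

image_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  stop("unrecognized image format (expect .nii, .nii.gz or .nrrd): ", path,
       call. = FALSE)
}

read_image_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- image_format(path)
  if (fmt == "nifti") {
    img <- tryCatch(RNifti::readNifti(path), error = function(e) {
      stop("cannot read NIfTI file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
    arr <- as.array(img)
    d <- dim(arr)[1:3]
    arr <- array(as.numeric(arr), dim = d)  # strip niftiImage attributes
    sp <- RNifti::pixdim(img)[seq_len(3)]
    list(voxels = arr, spacing = as.numeric(sp))
  } else {
    read_nrrd(path)
  }
}

write_image_array <- function(voxels, spacing, path, integer = FALSE) {
  fmt <- image_format(path)
  if (fmt == "nifti") {
    if (integer) storage.mode(voxels) <- "integer"
    img <- RNifti::asNifti(voxels)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(voxels, spacing, path, integer = integer)
  }
  invisible(path)
}

# --- minimal NRRD codec -----------------------------------------------------
# Covers the detached-header-free NRRD dialect: 3D, raw or gzip encoding,
# little-endian, types double / float / int / short / uchar, spacing from
# either "spacings" or axis-aligned "space directions".

nrrd_types <- list(
  double = list(what = "double", size = 8L),
  float = list(what = "double", size = 4L),
  int = list(what = "integer", size = 4L),
  short = list(what = "integer", size = 2L),
  uchar = list(what = "integer", size = 1L)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) {
    stop("not an NRRD file: ", path, call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header: ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  type <- sub("^(unsigned char)$", "uchar", fields[["type"]])
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type, call. = FALSE)
  if (as.integer(fields[["dimension"]]) != 3L) {
    stop("only 3D NRRD supported", call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  endian <- if (grepl("big", fields[["endian"]] %||% "little")) "big" else "little"
  payload <- readBin(con, "raw", n = n * spec$size + 1024L)
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  values <- readBin(payload, spec$what, n = n, size = spec$size,
                    endian = endian, signed = spec$size > 1L)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(
      fields[["space directions"]],
      gregexpr("\\(([^)]*)\\)", fields[["space directions"]])
    )[[1]]
    mat <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    spacing <- sqrt(colSums(mat^2))
  }
  list(voxels = array(values, dim = sizes), spacing = spacing)
}

write_nrrd <- function(voxels, spacing, path, integer = FALSE) {
  type <- if (integer) "int" else "double"
  spec <- nrrd_types[[type]]
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(voxels), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 12), collapse = " ")),
    "endian: little",
    "encoding: gzip",
    ""
  )
  if (integer) storage.mode(voxels) <- "integer"
  raw_data <- writeBin(as.vector(voxels), raw(), size = spec$size,
                       endian = "little")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  writeBin(memCompress(raw_data, type = "gzip"), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- volumes, masks, cases --------------------------------------------------

#' Read / write a volume or mask image
#'
#' NIfTI-1 (`.nii`, `.nii.gz`) goes through \pkg{RNifti}; NRRD (`.nrrd`) uses
#' a built-in codec (raw/gzip encodings). Masks are stored as integer grids;
#' a sidecar `<path>.json` records the label map, and is read back when
#' present. No resampling is ever performed.
#'
#' @param path image file path.
#' @param volume,mask objects to write.
#' @param label_map label map to use when the sidecar is absent.
#' @return `read_volume()` a [volume3d()]; `read_mask()` a [mask3d()].
#' @export
read_volume <- function(path) {
  img <- read_image_array(path)
  volume3d(img$voxels, img$spacing)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  write_image_array(volume$voxels, volume$spacing, path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, label_map = NULL) {
  img <- read_image_array(path)
  sidecar <- paste0(path, ".json")
  if (is.null(label_map)) {
    if (file.exists(sidecar)) {
      lm <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      label_map <- setNames(as.integer(lm), names(lm))
    } else {
      present <- setdiff(unique(round(as.vector(img$voxels))), 0)
      label_map <- setNames(as.integer(present),
                            paste0("label", as.integer(present)))
      if (length(label_map) == 0L) label_map <- c(foreground = 1L)
    }
  }
  mask3d(round(img$voxels), img$spacing, label_map = label_map)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask3d"))
  write_image_array(mask$labels, mask$spacing, path, integer = TRUE)
  jsonlite::write_json(as.list(mask$label_map), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read one case from volume + mask files
#'
#' Validates that all grids share shape and spacing; a mismatch raises a
#' geometry error naming the offending file. No resampling is performed.
#'
#' @param volume_path,tumor_mask_path,pancreas_mask_path image file paths;
#'   `pancreas_mask_path` may be `NULL`.
#' @param case_id identifier; defaults to the volume file name.
#' @param region_label optional `"head"` / `"body_tail"` class label.
#' @return A [case_record()].
#' @export
read_case <- function(volume_path, tumor_mask_path, pancreas_mask_path = NULL,
                      case_id = NULL,
                      region_label = NA_character_) {
  volume <- read_volume(volume_path)
  tumor <- read_mask(tumor_mask_path, label_map = c(tumor = 1L))
  tryCatch(
    check_same_grid(volume, tumor, "volume", basename(tumor_mask_path)),
    error = function(e) stop(conditionMessage(e), call. = FALSE)
  )
  pancreas <- NULL
  if (!is.null(pancreas_mask_path)) {
    pancreas <- read_mask(pancreas_mask_path, label_map = c(pancreas = 1L))
    check_same_grid(volume, pancreas, "volume", basename(pancreas_mask_path))
  }
  if (is.null(case_id)) {
    case_id <- sub("\\.(nii(\\.gz)?|nrrd)$", "", basename(volume_path))
  }
  case_record(case_id, volume, tumor, pancreas, region_label)
}

#' Write one case to an output directory
#'
#' @param case a [case_record()].
#' @param dir output directory (created if needed).
#' @param format `"nifti"` or `"nrrd"`.
#' @return Named character vector of the files written.
#' @export
write_case <- function(case, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    volume = file.path(dir, paste0(case$case_id, "_volume", ext)),
    tumor = file.path(dir, paste0(case$case_id, "_tumor", ext))
  )
  write_volume(case$volume, paths[["volume"]])
  write_mask(case$tumor_mask, paths[["tumor"]])
  if (!is.null(case$pancreas_mask)) {
    paths[["pancreas"]] <- file.path(dir, paste0(case$case_id, "_pancreas", ext))
    write_mask(case$pancreas_mask, paths[["pancreas"]])
  }
  invisible(paths)
}

#' Read / write a case-label table
#'
#' Plain CSV with columns `case_id`, `region_label`.
#' @param labels data.frame with columns `case_id`, `region_label`.
#' @param path CSV path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("case_id", "region_label") %in% names(labels)))
  write.csv(labels[, c("case_id", "region_label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("case_id", "region_label") %in% names(df)))
  df
}
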