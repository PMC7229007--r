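#' @importFrom stats rnorm sd setNames quantile
#' @importFrom utils write.table read.table modifyList
NULL

#' Region label codes
#'
#' Integer coding of the anatomical regions used throughout the package:
#' `0 = OUTSIDE`, `1 = BONY`, `2 = SOFT`, `3 = MIXED`. The excluded region is
#' an independent boolean overlay, not a label, because it may intersect any
#' region.
#'
#' @format Named integer vector.
#' @export
REGION_CODES <- c(OUTSIDE = 0L, BONY = 1L, SOFT = 2L, MIXED = 3L)

VALID_MODALITIES <- c("MR1", "MR2", "CT", "PCT", "DOSE")

#' Construct an image volume
#'
#' A 3D scalar grid with voxel spacing in mm and a modality tag. This is the
#' basic container for MRI intensities (arbitrary units), CT numbers (HU) and
#' dose (Gy).
#'
#' @param data 3D numeric array.
#' @param spacing Numeric 3-vector of voxel edge lengths in mm, all > 0.
#' @param modality One of `"MR1"`, `"MR2"`, `"CT"`, `"PCT"`, `"DOSE"`.
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing`, `modality`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), spacing = c(0.81, 0.81, 5))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), modality = "CT") {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("'data' must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three positive finite values (mm)", call. = FALSE)
  }
  modality <- match.arg(modality, VALID_MODALITIES)
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a region label map
#'
#' Per-voxel categorical partition of the grid into `OUTSIDE` plus the three
#' body regions (`BONY`, `SOFT`, `MIXED`), together with an independent
#' `excluded` overlay marking voxels whose CT is anatomically mismatched with
#' the MRI (e.g. bladder/bowel). Excluded voxels are dropped from training and
#' evaluation but still receive a prediction.
#'
#' @param labels 3D integer array with values in [REGION_CODES].
#' @param excluded Optional 3D logical array of the same shape; default all
#'   `FALSE`.
#' @return An object of class `region_labels`.
#' @export
region_labels <- function(labels, excluded = NULL) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3L) {
    stop("'labels' must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(REGION_CODES))
  if (length(bad)) {
    stop("unknown region code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(excluded)) {
    excluded <- array(FALSE, dim(labels))
  }
  if (!identical(dim(excluded), dim(labels))) {
    stop("'excluded' must match the shape of 'labels'", call. = FALSE)
  }
  storage.mode(excluded) <- "logical"
  structure(list(labels = labels, excluded = excluded), class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = unname(REGION_CODES),
                      labels = names(REGION_CODES)))
  cat("<region_labels>", paste(dim(x$labels), collapse = "x"), "voxels\n")
  print(tab)
  cat("excluded voxels:", sum(x$excluded), "\n")
  invisible(x)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D scalar image.
#' @param modality Modality tag to attach (see [image_volume()]).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = "CT") {
  raw <- nifti_read(path)
  image_volume(raw$data, spacing = raw$spacing, modality = modality)
}

#' Write a volume to a NIfTI file
#'
#' Data are stored as float64, so `read_volume(write_volume(v))` reproduces
#' the voxel values exactly; spacing is carried in `pixdim`.
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  nifti_write(vol$data, vol$spacing, path)
}

#' Read a region label map from NIfTI
#'
#' @param path Integer-coded NIfTI label volume.
#' @param code_table Named integer vector mapping file codes to region names;
#'   defaults to [REGION_CODES]. Every code present in the file must appear in
#'   the table.
#' @param excluded_path Optional path of a 0/1 NIfTI volume with the excluded
#'   overlay; all-`FALSE` when omitted.
#' @return A [region_labels()] object (labels re-coded to the package's
#'   canonical codes).
#' @export
read_labelmap <- function(path, code_table = REGION_CODES, excluded_path = NULL) {
  raw <- nifti_read(path)
  vals <- as.integer(round(raw$data))
  known <- unname(code_table)
  bad <- setdiff(unique(vals), known)
  if (length(bad)) {
    stop("label code(s) not in code_table: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  }
  # re-code file values to canonical codes via the table's names
  canon <- REGION_CODES[names(code_table)]
  lut <- integer(max(known) + 1L)
  lut[known + 1L] <- canon
  labels <- array(lut[vals + 1L], dim = dim(raw$data))
  excluded <- NULL
  if (!is.null(excluded_path)) {
    exc <- nifti_read(excluded_path)
    if (!identical(dim(exc$data), dim(labels))) {
      stop("excluded overlay shape does not match labels", call. = FALSE)
    }
    excluded <- array(exc$data != 0, dim = dim(labels))
  }
  region_labels(labels, excluded)
}

#' Write a region label map to NIfTI
#'
#' Writes the categorical labels under `path` and, when any voxel is excluded,
#' the 0/1 overlay next to it (suffix `_excluded`).
#'
#' @param lab A [region_labels()] object.
#' @param path Output path for the label volume.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(lab, path) {
  stopifnot(inherits(lab, "region_labels"))
  nifti_write(lab$labels, c(1, 1, 1), path)
  if (any(lab$excluded)) {
    exc_path <- sub("(\\.nii(\\.gz)?)$", "_excluded\\1", path)
    nifti_write(lab$excluded + 0, c(1, 1, 1), exc_path)
  }
  invisible(path)
}
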