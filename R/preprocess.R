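#' Mask and margin parameters
#'
#' Parameters of body-mask construction and of the millimetre margins that
#' define the bony / soft / mixed partition. The bony region keeps ~1 mm
#' inside the cortical bone edge; the soft region stays 2.5 mm away from bone
#' (midpoint of the 2-3 mm convention); the shell in between is the mixed
#' region.
#'
#' @param body_threshold Intensity threshold separating the imaged subject
#'   from background air.
#' @param closing_radius_mm Radius of the morphological closing applied after
#'   thresholding, in mm.
#' @param bone_inner_margin_mm Erosion margin applied to the bone mask to get
#'   the bony region, mm (default 1).
#' @param soft_exclusion_margin_mm Dilation margin around bone excluded from
#'   the soft region, mm (default 2.5).
#' @return A list of class `mask_params`.
#' @export
mask_params <- function(body_threshold = 100, closing_radius_mm = 2,
                        bone_inner_margin_mm = 1, soft_exclusion_margin_mm = 2.5) {
  if (closing_radius_mm < 0 || bone_inner_margin_mm < 0 ||
      soft_exclusion_margin_mm < 0) {
    stop("margins must be >= 0", call. = FALSE)
  }
  structure(list(body_threshold = body_threshold,
                 closing_radius_mm = closing_radius_mm,
                 bone_inner_margin_mm = bone_inner_margin_mm,
                 soft_exclusion_margin_mm = soft_exclusion_margin_mm),
            class = "mask_params")
}

#' Fit a cohort intensity-normalization model
#'
#' For one MRI sequence, computes each patient's mean body-voxel intensity and
#' the unweighted cohort mean of those means. The per-patient multiplicative
#' correction factor is `cohort_mean / patient_mean`, so that after applying
#' the factors every patient's body mean equals the cohort mean.
#'
#' @param patient_volumes A list; each element a list with `id` (character),
#'   `volume` (an [image_volume()]) and `mask` (3D logical body mask).
#' @param sequence Tag recorded in the model (`"MR1"` or `"MR2"`).
#' @return A list of class `normalization_model` with `sequence`,
#'   `cohort_mean`, `patient_means` and `factors` (both named by patient id).
#' @export
fit_normalization <- function(patient_volumes, sequence = "MR1") {
  if (!length(patient_volumes)) stop("need at least one patient", call. = FALSE)
  ids <- vapply(patient_volumes, function(p) as.character(p$id), character(1))
  means <- vapply(patient_volumes, function(p) {
    if (!any(p$mask)) {
      stop("empty body mask for patient '", p$id, "'", call. = FALSE)
    }
    mean(p$volume$data[p$mask])
  }, numeric(1))
  bad <- means <= 0 | !is.finite(means)
  if (any(bad)) {
    stop("non-positive body mean for patient(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  cohort_mean <- mean(means)
  structure(list(sequence = sequence, cohort_mean = cohort_mean,
                 patient_means = setNames(means, ids),
                 factors = setNames(cohort_mean / means, ids)),
            class = "normalization_model")
}

#' Apply a multiplicative intensity correction
#'
#' @param vol An [image_volume()].
#' @param factor Positive scale factor, typically from [fit_normalization()].
#' @return The rescaled volume (same shape, spacing, modality).
#' @export
apply_normalization <- function(vol, factor) {
  stopifnot(inherits(vol, "image_volume"))
  if (!is.finite(factor) || factor <= 0) {
    stop("normalization factor must be positive", call. = FALSE)
  }
  vol$data <- vol$data * factor
  vol
}

#' Build a binary body mask from an MRI volume
#'
#' Thresholds the image, applies morphological closing (mm radius converted to
#' anisotropic voxel radii), fills interior cavities, and keeps the largest
#' 3D connected component. This replaces manual/edge-detection masking with a
#' deterministic, parameter-transparent procedure.
#'
#' @param vol An [image_volume()].
#' @param params A [mask_params()] object.
#' @return 3D logical array, `TRUE` on body voxels.
#' @export
make_body_mask <- function(vol, params = mask_params()) {
  stopifnot(inherits(vol, "image_volume"))
  if (any(!is.finite(vol$data))) stop("volume contains non-finite values", call. = FALSE)
  raw <- vol$data > params$body_threshold
  if (!any(raw)) {
    stop("no voxel above body_threshold = ", params$body_threshold, call. = FALSE)
  }
  r <- mm_to_voxel_radius(params$closing_radius_mm, vol$spacing)
  m <- binary_close(raw, r)
  m <- fill_holes(m)
  largest_component(m)
}

#' Partition the body into bony / soft / mixed regions
#'
#' Applies the margin rules around a given bone mask: the bony region is the
#' bone mask eroded by `bone_inner_margin_mm`; the soft region is the body
#' minus the bone mask dilated by `soft_exclusion_margin_mm`; remaining body
#' voxels form the mixed transition shell. Margins are ellipsoidal structuring
#' elements with per-axis voxel radii derived from `spacing`.
#'
#' @param bone_mask 3D logical bone mask (must lie inside `body_mask`).
#' @param body_mask 3D logical body mask.
#' @param spacing Voxel spacing, mm.
#' @param params A [mask_params()] object.
#' @return A [region_labels()] object (no voxels excluded).
#' @export
build_region_labels <- function(bone_mask, body_mask, spacing,
                                params = mask_params()) {
  if (!identical(dim(bone_mask), dim(body_mask))) {
    stop("bone and body masks must share a shape", call. = FALSE)
  }
  if (any(bone_mask & !body_mask)) {
    stop("bone mask extends outside the body mask", call. = FALSE)
  }
  r_in <- mm_to_voxel_radius(params$bone_inner_margin_mm, spacing)
  r_out <- mm_to_voxel_radius(params$soft_exclusion_margin_mm, spacing)
  bony <- binary_erode(bone_mask, r_in)
  soft <- body_mask & !binary_dilate(bone_mask, r_out)
  mixed <- body_mask & !bony & !soft
  labels <- array(REGION_CODES[["OUTSIDE"]], dim(body_mask))
  labels[soft] <- REGION_CODES[["SOFT"]]
  labels[mixed] <- REGION_CODES[["MIXED"]]
  labels[bony] <- REGION_CODES[["BONY"]]
  region_labels(labels)
}

#' Set air voxels to -1000 HU
#'
#' @param pct A CT-valued [image_volume()].
#' @param body_mask 3D logical array; voxels outside it are set to exactly
#'   -1000 HU, body voxels are untouched.
#' @return The modified volume.
#' @export
mark_air <- function(pct, body_mask) {
  stopifnot(inherits(pct, "image_volume"))
  if (!identical(dim(pct$data), dim(body_mask))) {
    stop("mask shape does not match the volume", call. = FALSE)
  }
  pct$data[!body_mask] <- -1000
  pct
}
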