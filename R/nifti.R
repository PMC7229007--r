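# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# Only what the pipeline needs: 3D scalar images, voxel spacing from pixdim,
# scl_slope/scl_inter honoured on read, float64 storage on write (lossless
# round trips). The world affine (srow_*) is written as a diagonal
# spacing matrix and otherwise ignored: all processing happens in
# voxel-index space on pre-registered, same-grid inputs.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Read header+data sequentially (gz connections cannot seek).
nifti_read <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE) {
    stop("'", path, "' is too short to be a NIfTI-1 file", call. = FALSE)
  }
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != NIFTI_HDR_SIZE) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != NIFTI_HDR_SIZE) {
      stop("'", path, "' does not look like NIfTI-1 (bad sizeof_hdr)", call. = FALSE)
    }
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  shape <- dims[seq_len(max(ndim, 0)) + 1]
  extra <- if (ndim > 3) shape[-(1:3)] else integer(0)
  if (ndim < 3 || any(extra != 1L)) {
    stop("expected 3D volume, got ", ndim, "D image with dim [",
         paste(shape, collapse = ", "), "] in '", path, "'", call. = FALSE)
  }
  shape <- shape[1:3]
  dtype <- rd(70L, "integer", 1L, 2L)
  spec <- nifti_dtypes[[as.character(dtype)]]
  if (is.null(spec)) {
    stop("unsupported (non-scalar) NIfTI datatype code ", dtype,
         " in '", path, "'", call. = FALSE)
  }
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                  signed = spec$signed)
  if (length(vals) < n) {
    stop("truncated NIfTI data in '", path, "'", call. = FALSE)
  }
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  list(data = array(vals, dim = shape), spacing = spacing)
}

nifti_write <- function(data, spacing, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write '", path, "': directory '", dir, "' does not exist",
         call. = FALSE)
  }
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  con <- tryCatch(nifti_open(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    if (length(b)) r[seq_len(min(len, length(b)))] <- b[seq_len(min(len, length(b)))]
    writeBin(r, con)
  }
  wi(NIFTI_HDR_SIZE, 4)                    # sizeof_hdr
  wc("", 10); wc("", 18)                   # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                 # intent_p1..3, intent_code
  wi(64, 2); wi(64, 2); wi(0, 2)           # datatype float64, bitpix, slice_start
  wf(c(1, spacing, 1, 1, 1, 1))            # pixdim[8] (qfac = 1)
  wf(NIFTI_VOX_OFFSET)                     # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc(rawToChar(as.raw(2L)), 1)  # slice_end, slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                           # glmax, glmin
  wc("pseudoCT", 80); wc("", 24)           # descrip, aux_file
  wi(0, 2); wi(1, 2)                       # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                  # quatern_b/c/d, qoffset_x/y/z
  wf(c(spacing[1], 0, 0, 0))               # srow_x
  wf(c(0, spacing[2], 0, 0))               # srow_y
  wf(c(0, 0, spacing[3], 0))               # srow_z
  wc("", 16); wc("n+1", 4)                 # intent_name, magic
  writeBin(raw(4), con)                    # extension flag
  writeBin(as.double(data), con, size = 8, endian = "little")
  invisible(path)
}
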