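#' Minimal NIfTI-1 input/output
#'
#' Reads and writes uncompressed single-file NIfTI-1 volumes (`.nii`). The
#' implementation covers what the pipeline needs — 3D/4D floating-point or
#' integer volumes, voxel spacing and an sform affine — and deliberately
#' nothing else (no `.nii.gz`, no extensions, no q-form quaternions). It
#' exists because no NIfTI reader is available in the target R library; the
#' test suite cross-checks files written here against an independent reader.
#'
#' @param path file path ending in `.nii`.
#' @return `read_nifti()` returns a list with `data` (numeric array),
#'   `spacing` (voxel sizes in mm for the first three dimensions) and
#'   `affine` (4x4 voxel-to-world sform matrix).
#' @name nifti_io
NULL

NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L
NIFTI_DT_INT16 <- 4L
NIFTI_DT_UINT8 <- 2L
NIFTI_DT_INT32 <- 8L

#' @rdname nifti_io
#' @param data numeric/logical array, 2 to 4 dimensions.
#' @param spacing voxel spacing in mm (recycled to the array rank).
#' @param affine optional 4x4 voxel-to-world matrix stored as the sform;
#'   defaults to diagonal `spacing`.
#' @param datatype on-disk type, `"float64"` (default), `"float32"`,
#'   `"int16"` or `"uint8"`.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = c("float64", "float32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
    if (missing(datatype)) datatype <- "uint8"
  }
  if (is.null(dim(data))) dim(data) <- length(data)
  nd <- length(dim(data))
  if (nd < 2L || nd > 4L)
    stop("write_nifti supports 2D-4D arrays", call. = FALSE)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (is.null(affine)) affine <- spacing_affine(spacing)

  dims <- integer(8); dims[1] <- nd; dims[2:(1 + nd)] <- dim(data)
  dims[dims == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- spacing
  if (nd == 4L) pixdim[5] <- 1

  dt <- switch(datatype,
               float64 = c(NIFTI_DT_FLOAT64, 64L),
               float32 = c(NIFTI_DT_FLOAT32, 32L),
               int16 = c(NIFTI_DT_INT16, 16L),
               uint8 = c(NIFTI_DT_UINT8, 8L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # data_type..dim_info
  writeBin(dims, con, size = 2)                      # dim[8]
  writeBin(numeric(3), con, size = 4)                # intent_p1..p3
  writeBin(c(0L, dt[1], dt[2], 0L), con, size = 2)   # intent_code, datatype,
                                                     # bitpix, slice_start
  writeBin(pixdim, con, size = 4)                    # pixdim[8]
  writeBin(352, con, size = 4)                       # vox_offset (float)
  writeBin(c(1, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                        # slice_end
  writeBin(as.raw(c(0L, 2L)), con)                   # slice_code, xyzt=mm
  writeBin(numeric(3), con, size = 4)                # cal_max/min, slice_dur
  writeBin(0, con, size = 4)                         # toffset
  writeBin(c(0L, 0L), con, size = 4)                 # glmax, glmin
  writeBin(raw(80 + 24), con)                        # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2)                 # qform=0, sform=1
  writeBin(numeric(6), con, size = 4)                # quatern b,c,d + offsets
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4)  # srow_x/y/z
  writeBin(raw(16), con)                             # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con) # magic
  writeBin(raw(4), con)                              # no header extension
  vals <- as.vector(data)
  if (datatype %in% c("int16", "uint8", "int32")) {
    writeBin(as.integer(round(vals)), con, size = dt[2] / 8)
  } else {
    writeBin(as.numeric(vals), con, size = dt[2] / 8)
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- .Platform$endian
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- if (endian == "little") "big" else "little"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  nd <- dims[1]
  if (nd < 1L || nd > 7L) stop("corrupt NIfTI dim field", call. = FALSE)
  shape <- dims[2:(1 + nd)]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl <- readBin(con, "numeric", 2, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1"))
    stop("missing NIfTI magic in ", path, call. = FALSE)
  seek(con, 280)
  srow <- readBin(con, "numeric", 12, size = 4, endian = endian)
  affine <- rbind(matrix(srow, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  if (all(affine[1:3, 1:3] == 0))
    affine <- spacing_affine(pixdim[2:4])

  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                              endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  dim(data) <- shape
  list(data = data, spacing = pixdim[2:4][seq_len(min(3L, nd))],
       affine = affine)
}
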