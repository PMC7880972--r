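#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, `.nii.gz`) with
#' axis-aligned geometry, which is all the pipeline needs to exchange SPGR
#' images, B1/T1 maps and masks. Supported on read: uint8, int16, int32,
#' uint16, float32, float64, either endianness, scl_slope/scl_inter
#' rescaling. Written files carry an sform with a diagonal direction matrix
#' (spacing on the diagonal, origin in the translation column). Oblique
#' orientations and NIfTI-2 are out of scope.
#'
#' @param vol a [volume_grid()].
#' @param path file path; a `.gz` suffix selects gzip compression.
#' @param datatype "float32" (default) or "uint8" (for masks).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   [volume_grid()].
#' @name nifti_io
NULL

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "uint8")) {
  stopifnot(is_volume_grid(vol))
  datatype <- match.arg(datatype)
  dt_code <- switch(datatype, float32 = 16L, uint8 = 2L)
  bitpix <- switch(datatype, float32 = 32L, uint8 = 8L)
  d <- dim(vol$values)
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wC <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wI(348L, 4)                               # sizeof_hdr
  wC("", 10); wC("", 18)                    # data_type, db_name
  wI(0L, 4); wI(0L, 2); wC("r", 1); wC("", 1)  # extents..dim_info
  wI(c(3L, d, 1L, 1L, 1L, 1L), 2)           # dim[8]
  wF(c(0, 0, 0)); wI(0L, 2)                 # intent_p*, intent_code
  wI(dt_code, 2); wI(bitpix, 2); wI(0L, 2)  # datatype, bitpix, slice_start
  wF(c(1, vol$spacing, 0, 0, 0, 0))         # pixdim[8] (qfac 1)
  wF(352); wF(1); wF(0)                     # vox_offset, scl_slope, scl_inter
  wI(0L, 2); wC("", 1); wC("", 1)           # slice_end, slice_code, xyzt_units
  wF(c(0, 0, 0, 0))                         # cal_max..toffset
  wI(c(0L, 0L), 4)                          # glmax, glmin
  wC("t1liver volume", 80); wC("", 24)      # descrip, aux_file
  wI(0L, 2); wI(1L, 2)                      # qform_code, sform_code
  wF(c(0, 0, 0)); wF(c(0, 0, 0))            # quatern, qoffset
  wF(c(vol$spacing[1], 0, 0, vol$origin[1]))      # srow_x
  wF(c(0, vol$spacing[2], 0, vol$origin[2]))      # srow_y
  wF(c(0, 0, vol$spacing[3], vol$origin[3]))      # srow_z
  wC("", 16); wC("n+1", 4)                  # intent_name, magic
  writeBin(raw(4), con)                     # extension flag
  if (datatype == "uint8") {
    writeBin(as.integer(round(vol$values)), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd <- function(raw, what, n, size, endian) {
    readBin(raw, what, n = n, size = size, endian = endian,
            signed = !(what == "integer" && size %in% c(1, 2) && FALSE))
  }
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L) stop(path, " is not a NIfTI-1 file")
  }
  at <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dim8 <- at(40, "integer", 8, 2)
  ndim <- dim8[1]
  if (ndim < 3) dim8[(ndim + 2):4] <- 1L
  d <- pmax(dim8[2:4], 1L)
  if (ndim > 3 && any(dim8[5:(ndim + 1)] > 1))
    stop("only 3D NIfTI volumes are supported (got ", ndim, "D)")
  datatype <- at(70, "integer", 1, 2)
  pixdim <- at(76, "double", 8, 4)
  vox_offset <- at(108, "double", 1, 4)
  scl_slope <- at(112, "double", 1, 4)
  scl_inter <- at(116, "double", 1, 4)
  sform_code <- at(254, "integer", 1, 2)
  srow <- matrix(at(280, "double", 12, 4), nrow = 3, byrow = TRUE)
  n <- prod(d)
  # skip to the data sequentially (seek() is unreliable on gz connections)
  if (vox_offset > 348) readBin(con, "raw", n = vox_offset - 348)
  vals <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n, 1, signed = FALSE,
                               endian = endian)),
    "4"   = as.numeric(readBin(con, "integer", n, 2, signed = TRUE,
                               endian = endian)),
    "512" = as.numeric(readBin(con, "integer", n, 2, signed = FALSE,
                               endian = endian)),
    "8"   = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
    "16"  = readBin(con, "double", n, 4, endian = endian),
    "64"  = readBin(con, "double", n, 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0) {
    spacing <- sqrt(colSums(srow[, 1:3]^2))
    origin <- srow[, 4]
  }
  spacing[spacing <= 0 | !is.finite(spacing)] <- 1
  volume_grid(array(vals, dim = d), spacing = spacing, origin = origin)
}
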