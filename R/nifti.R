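# Minimal NIfTI-1 reader/writer for the volumes this package exchanges:
# float32 fat-fraction maps and int16 ROI label maps, uncompressed .nii or
# gzipped .nii.gz, native (little-endian) byte order, sform = diag(pixdim).
# No R NIfTI package is available in the supported environment, so the
# 348-byte header is written directly.

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

#' Write a 3D volume as NIfTI-1
#'
#' Numeric data are stored as float32, integer data as int16.
#'
#' @param data 3D array.
#' @param path output `.nii` or `.nii.gz` path.
#' @param pixdim voxel size, mm per axis.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L)
  int_data <- is.integer(data) ||
    (is.numeric(data) && max(abs(data - round(data))) == 0 && max(abs(data)) < 32767)
  datatype <- if (int_data) 4L else 16L
  bitpix <- if (int_data) 16L else 32L
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_i32(348)
  writeBin(raw(28), con)                         # data_type, db_name
  w_i32(0); w_i16(0)                             # extents, session_error
  writeBin(c(charToRaw("r"), raw(1)), con)       # regular, dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))        # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)                    # intent
  w_i16(datatype); w_i16(bitpix); w_i16(0)
  w_f32(c(1, pixdim, 0, 0, 0, 0))                # pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)                 # vox_offset, scl_slope/inter
  w_i16(0); writeBin(raw(1), con)                # slice_end, slice_code
  writeBin(as.raw(2L), con)                      # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                           # cal_max/min, slice_dur, toffset
  w_i32(c(0, 0))                                 # glmax, glmin
  writeBin(pad_raw("unrolledmri", 80), con)      # descrip
  writeBin(raw(24), con)                         # aux_file
  w_i16(0); w_i16(1)                             # qform_code, sform_code
  w_f32(rep(0, 6))                               # quatern, qoffset
  w_f32(c(pixdim[1], 0, 0, 0))
  w_f32(c(0, pixdim[2], 0, 0))
  w_f32(c(0, 0, pixdim[3], 0))
  writeBin(raw(16), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)     # magic
  writeBin(raw(4), con)                          # extender
  if (int_data) w_i16(as.vector(data)) else w_f32(as.vector(data))
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the datatypes this package writes (int16, int32, float32,
#' float64), little-endian, single file `.nii` / `.nii.gz`.
#'
#' @param path input path.
#' @return list with `data` (array, scaled by `scl_slope`/`scl_inter` when
#'   set) and `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  r_i32 <- function(off) readBin(hdr[off + 1:4], "integer", size = 4, endian = "little")
  r_i16 <- function(off, n = 1) readBin(hdr[off + seq_len(2 * n)], "integer",
                                        size = 2, n = n, endian = "little")
  r_f32 <- function(off, n = 1) readBin(hdr[off + seq_len(4 * n)], "double",
                                        size = 4, n = n, endian = "little")
  if (r_i32(0) != 348) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  dims <- r_i16(40, 8)
  nd <- dims[1]
  shape <- dims[1 + seq_len(nd)]
  datatype <- r_i16(70)
  pixdim <- r_f32(76, 8)[2:4]
  vox_offset <- r_f32(108)
  scl_slope <- r_f32(112)
  scl_inter <- r_f32(116)
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(shape)
  data <- switch(as.character(datatype),
    "4" = readBin(con, "integer", n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n, size = 4, endian = "little"),
    "16" = readBin(con, "double", n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  if (scl_slope != 0 && (scl_slope != 1 || scl_inter != 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- shape
  list(data = data, pixdim = pixdim)
}
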