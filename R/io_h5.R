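# HDF5 k-space container. Layout:
#   /kspace     complex64 pairs {r,i}, dims (echo, kx, ky, kz)
#   /kspace_us  optional zero-filled undersampled k-space, same dims
#   /mask       uint8, dims (ky, kz)
# Root attributes carry the acquisition protocol and mask metadata.
# Dims are written in C order so that h5py sees the stated shapes.

# write an R array (any rank) as a dataset with C-order dims = dim(x)
h5_put_array <- function(path, name, x, dtype = "float32") {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  xt <- if (length(d) > 1L) aperm(x, rev(seq_along(d))) else x
  if (is.complex(x)) {
    .h5_write_cplx(path, name, Re(xt), Im(xt), as.integer(d))
  } else {
    .h5_write_num(path, name, as.numeric(xt), as.integer(d), dtype)
  }
  invisible(NULL)
}

h5_get_array <- function(path, name) {
  r <- .h5_read(path, name)
  d <- r$dims
  x <- if (r$kind == "complex") complex(real = r$re, imaginary = r$im) else r$data
  if (length(d) > 1L) {
    dim(x) <- rev(d)
    x <- aperm(x, rev(seq_along(d)))
  }
  x
}

#' Write a k-space dataset container
#'
#' @param path output `.h5` file.
#' @param kspace complex array `(echo, kx, ky, kz)`.
#' @param mask a sampling mask (object or `(ky, kz)` 0/1 matrix).
#' @param acq an [acquisition_spec()].
#' @param kspace_us optional zero-filled undersampled k-space, same dims.
#' @return `path`, invisibly.
#' @export
write_kspace_h5 <- function(path, kspace, mask, acq, kspace_us = NULL) {
  stopifnot(length(dim(kspace)) == 4L)
  .h5_create(path)
  h5_put_array(path, "kspace", kspace)
  if (!is.null(kspace_us)) h5_put_array(path, "kspace_us", kspace_us)
  plane <- mask_plane(mask)
  h5_put_array(path, "mask", plane, dtype = "uint8")
  .h5_attr_write_num(path, "TR", acq$TR)
  .h5_attr_write_num(path, "TE_list", acq$TE_list)
  .h5_attr_write_num(path, "flip_angle", acq$flip_angle)
  .h5_attr_write_num(path, "matrix", as.numeric(acq$matrix))
  .h5_attr_write_num(path, "resolution", acq$resolution)
  if (inherits(mask, "sampling_mask")) {
    .h5_attr_write_num(path, "accel_nominal", mask$accel_nominal)
    .h5_attr_write_num(path, "accel_empirical", mask$accel_empirical)
    .h5_attr_write_num(path, "center_fraction", mask$center_fraction)
    .h5_attr_write_num(path, "mask_seed", as.numeric(mask$seed))
  }
  invisible(path)
}

#' Read a k-space dataset container
#'
#' @param path `.h5` file written by [write_kspace_h5()].
#' @return list with `kspace`, `kspace_us` (or `NULL`), `mask`
#'   (a `sampling_mask` when metadata are present, else a matrix), and
#'   `acq` (an [acquisition_spec()]).
#' @export
read_kspace_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sets <- .h5_ls(path)
  kspace <- h5_get_array(path, "kspace")
  kus <- if ("kspace_us" %in% sets) h5_get_array(path, "kspace_us") else NULL
  plane <- h5_get_array(path, "mask")
  storage.mode(plane) <- "integer"
  attrs <- .h5_attr_list(path)
  mask <- if (all(c("accel_nominal", "center_fraction", "mask_seed") %in% attrs))
    new_sampling_mask(plane,
                      .h5_attr_read(path, "accel_nominal"),
                      .h5_attr_read(path, "accel_empirical"),
                      .h5_attr_read(path, "center_fraction"),
                      as.integer(.h5_attr_read(path, "mask_seed")))
  else plane
  acq <- acquisition_spec(TR = .h5_attr_read(path, "TR"),
                          TE_list = as.numeric(.h5_attr_read(path, "TE_list")),
                          flip_angle = .h5_attr_read(path, "flip_angle"),
                          matrix = as.integer(.h5_attr_read(path, "matrix")),
                          resolution = as.numeric(.h5_attr_read(path, "resolution")))
  list(kspace = kspace, kspace_us = kus, mask = mask, acq = acq)
}
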