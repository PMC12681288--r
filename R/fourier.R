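#' Centered orthonormal Fourier operators
#'
#' `fft3c()` maps a complex image volume to k-space with the DC component at
#' the array center (index `floor(n/2) + 1` along each axis) and orthonormal
#' (unitary) scaling, so that `ifft3c(fft3c(x))` recovers `x` exactly and the
#' L2 norm is preserved. Unitary scaling keeps data-consistency magnitudes
#' scale-free across matrix sizes.
#'
#' @param image complex (or numeric) 3D array.
#' @param k complex 3D k-space array with centered DC.
#' @return A complex 3D array of the same shape.
#' @examples
#' x <- array(complex(real = rnorm(64), imaginary = rnorm(64)), c(4, 4, 4))
#' max(Mod(ifft3c(fft3c(x)) - x)) < 1e-12
#' @export
fft3c <- function(image) {
  check_vol3(image)
  n <- length(image)
  fftshift(stats::fft(ifftshift(as_complex_array(image)))) / sqrt(n)
}

#' @rdname fft3c
#' @export
ifft3c <- function(k) {
  check_vol3(k)
  n <- length(k)
  fftshift(stats::fft(ifftshift(as_complex_array(k)), inverse = TRUE)) / sqrt(n)
}

as_complex_array <- function(x) {
  if (!is.complex(x)) {
    d <- dim(x)
    x <- as.complex(x)
    dim(x) <- d
  }
  x
}

check_vol3 <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected a 3D volume, got dimensions: ",
         paste(dim(x), collapse = "x"), call. = FALSE)
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(as_complex_array(x)))))
    stop("volume contains non-finite entries", call. = FALSE)
  invisible(TRUE)
}

# Circular shift moving index `floor(n/2)+1` to position 1 (ifftshift) or the
# inverse (fftshift); they differ for odd lengths.
shift_array <- function(x, shifts) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) {
    n <- d[a]
    ((seq_len(n) - 1L - shifts[a]) %% n) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftshift <- function(x) shift_array(x, dim(x) %/% 2L)

ifftshift <- function(x) shift_array(x, -(dim(x) %/% 2L))
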