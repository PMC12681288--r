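#' 3D gradient-echo Dixon acquisition specification
#'
#' Describes the multi-echo GRE protocol: repetition time, echo times, flip
#' angle, matrix size and voxel resolution. The default instance is the
#' 1.5 T thigh protocol used throughout the package: TR 22 ms, eight echoes
#' at TE = 2.38 to 19.06 ms in steps of 2.38 ms, flip angle 5 degrees,
#' matrix 128 x 128 x 36, resolution 1.72 x 1.72 x 5.00 mm.
#'
#' @param TR repetition time, ms.
#' @param TE_list echo times, ms; must be strictly increasing with a constant
#'   step.
#' @param flip_angle degrees.
#' @param matrix integer triplet `(Nx, Ny, Nz)`.
#' @param resolution voxel size, mm per axis.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(TR = 22,
                             TE_list = seq(2.38, by = 2.38, length.out = 8),
                             flip_angle = 5,
                             matrix = c(128L, 128L, 36L),
                             resolution = c(1.72, 1.72, 5.00)) {
  if (length(TE_list) < 2) stop("need at least two echoes", call. = FALSE)
  dte <- diff(TE_list)
  if (any(dte <= 0) || max(abs(dte - dte[1])) > 1e-6 * dte[1])
    stop("TE_list must be strictly increasing with a constant step",
         call. = FALSE)
  stopifnot(length(matrix) == 3, length(resolution) == 3)
  structure(list(TR = TR, TE_list = TE_list, flip_angle = flip_angle,
                 matrix = as.integer(matrix), resolution = resolution,
                 delta_TE = dte[1]),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("acquisition_spec: TR=%g ms, %d echoes TE=%g..%g (step %g) ms, flip=%g deg\n",
              x$TR, length(x$TE_list), min(x$TE_list), max(x$TE_list),
              x$delta_TE, x$flip_angle))
  cat(sprintf("  matrix %s, resolution %s mm\n",
              paste(x$matrix, collapse = "x"),
              paste(x$resolution, collapse = "x")))
  invisible(x)
}
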