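#' Variable-density Poisson-disc undersampling mask
#'
#' Generates a binary sampling mask on the (ky, kz) phase-encode plane of a
#' 3D Cartesian gradient-echo acquisition. The readout direction kx is always
#' fully sampled, so acceleration is defined on this plane and the mask is
#' broadcast along kx when applied. Points are drawn by dart throwing with a
#' local exclusion radius that grows linearly with the normalized elliptical
#' distance from the k-space center, `r(rho) = r0 * (1 + alpha * rho)`, giving
#' a variable-density Poisson-disc pattern. A central ellipse containing
#' `center_fraction` of the plane points is fully sampled. The base radius
#' `r0` is calibrated by bisection until the empirical acceleration
#' `ny * nz / sum(mask)` is within 5% of `accel`.
#'
#' @param ny,nz phase-encode plane dimensions.
#' @param accel nominal acceleration factor (>= 1).
#' @param center_fraction fraction of plane points in the fully sampled
#'   central ellipse, in (0, 1]. Default 0.04.
#' @param seed integer seed; the mask is deterministic for a fixed seed.
#' @param alpha density slope of the exclusion radius. Default 2.5.
#' @return An object of class `sampling_mask`: list with `plane` (ny x nz
#'   integer 0/1 matrix), `accel_nominal`, `accel_empirical`,
#'   `center_fraction`, `seed`.
#' @examples
#' m <- generate_vd_poisson_mask(64, 24, accel = 4, seed = 1)
#' m$accel_empirical
#' @export
generate_vd_poisson_mask <- function(ny, nz, accel, center_fraction = 0.04,
                                     seed = 0L, alpha = 2.5) {
  stopifnot(ny >= 4, nz >= 2)
  if (accel < 1) stop("accel must be >= 1", call. = FALSE)
  if (center_fraction <= 0 || center_fraction > 1)
    stop("center_fraction must be in (0, 1]", call. = FALSE)
  if (center_fraction > 1 / accel + 1e-12)
    stop("fully sampled center (", center_fraction,
         ") exceeds the sampling budget 1/accel = ", 1 / accel, call. = FALSE)

  n <- ny * nz
  # normalized coordinates in [-1, 1] per axis, center at the FFT center bin
  cy <- floor(ny / 2) + 1L
  cz <- floor(nz / 2) + 1L
  u <- (seq_len(ny) - cy) / (ny / 2)
  v <- (seq_len(nz) - cz) / (nz / 2)
  U <- matrix(u, ny, nz)
  V <- matrix(v, ny, nz, byrow = TRUE)
  rho <- sqrt(U^2 + V^2)

  # central ellipse with area center_fraction * (plane area 4 in (u,v) units)
  r_c <- 2 * sqrt(center_fraction / pi)
  center <- rho <= r_c

  if (accel <= 1 + 1e-12) {
    plane <- matrix(1L, ny, nz)
    return(new_sampling_mask(plane, accel, 1, center_fraction, seed))
  }

  target <- n / accel
  ord <- with_local_seed(seed, sample.int(n))
  outside <- which(!center)
  ord <- ord[!center[ord]]
  rho_norm <- pmin(rho / sqrt(2), 1)

  throw <- function(r0) {
    acc_u <- numeric(length(ord))
    acc_v <- numeric(length(ord))
    keep <- logical(n)
    m <- 0L
    for (p in ord) {
      r <- r0 * (1 + alpha * rho_norm[p])
      if (m > 0L) {
        du <- acc_u[seq_len(m)] - U[p]
        dv <- acc_v[seq_len(m)] - V[p]
        if (min(du * du + dv * dv) < r * r) next
      }
      m <- m + 1L
      acc_u[m] <- U[p]
      acc_v[m] <- V[p]
      keep[p] <- TRUE
    }
    keep
  }

  n_center <- sum(center)
  lo <- 1e-4
  hi <- 4
  best <- NULL
  for (it in 1:40) {
    mid <- sqrt(lo * hi)
    keep <- throw(mid)
    tot <- n_center + sum(keep)
    if (is.null(best) || abs(tot - target) < abs(best$tot - target))
      best <- list(keep = keep, tot = tot)
    if (abs(tot - target) / target < 0.01) break
    if (tot > target) lo <- mid else hi <- mid
  }
  plane <- matrix(0L, ny, nz)
  plane[center | best$keep] <- 1L
  new_sampling_mask(plane, accel, n / sum(plane), center_fraction, seed)
}

new_sampling_mask <- function(plane, accel, accel_emp, center_fraction, seed) {
  structure(list(plane = plane, accel_nominal = accel,
                 accel_empirical = accel_emp,
                 center_fraction = center_fraction, seed = seed),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("sampling_mask %dx%d: R_nominal=%.3g R_empirical=%.3g center=%.3g%% seed=%d\n",
              nrow(x$plane), ncol(x$plane), x$accel_nominal,
              x$accel_empirical, 100 * x$center_fraction, as.integer(x$seed)))
  invisible(x)
}

# run expr with a private RNG stream, leaving the global stream untouched
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

mask_plane <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$plane else mask
}

# broadcast the (ny, nz) plane along the fully sampled readout axis kx
broadcast_mask <- function(mask, dims) {
  plane <- mask_plane(mask)
  if (!all(dim(plane) == dims[2:3]))
    stop("mask plane ", paste(dim(plane), collapse = "x"),
         " does not match k-space phase-encode dims ",
         paste(dims[2:3], collapse = "x"), call. = FALSE)
  array(rep(as.numeric(plane), each = dims[1]), dim = dims)
}

#' Apply a sampling mask with zero filling
#'
#' Multiplies a k-space volume by the binary phase-encode plane mask,
#' broadcast along the readout axis: non-acquired points are set to zero.
#' The operation is idempotent.
#'
#' @param k complex 3D k-space array `(kx, ky, kz)`.
#' @param mask a [generate_vd_poisson_mask()] object or a 0/1 matrix of
#'   dimensions `(ky, kz)`.
#' @return Masked k-space volume, same shape as `k`.
#' @export
apply_mask_zero_fill <- function(k, mask) {
  check_vol3(k)
  k * broadcast_mask(mask, dim(k))
}

#' Data-consistency residual
#'
#' The gradient of the data-fidelity term on the mask support:
#' `mu * D * (k_it - k_us)`, zero wherever the mask is zero.
#'
#' @param k_it current k-space iterate.
#' @param k_us acquired (zero-filled) undersampled k-space.
#' @param mask sampling mask (see [apply_mask_zero_fill()]).
#' @param mu step-size scalar.
#' @return Complex 3D array.
#' @export
dc_residual <- function(k_it, k_us, mask, mu) {
  check_vol3(k_it)
  if (!all(dim(k_it) == dim(k_us)))
    stop("k_it and k_us dimensions differ", call. = FALSE)
  mu * broadcast_mask(mask, dim(k_it)) * (k_it - k_us)
}
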