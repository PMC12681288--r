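center_rho <- function(ny, nz) {
  cy <- floor(ny / 2) + 1
  cz <- floor(nz / 2) + 1
  u <- (seq_len(ny) - cy) / (ny / 2)
  v <- (seq_len(nz) - cz) / (nz / 2)
  sqrt(outer(u^2, rep(1, nz)) + outer(rep(1, ny), v^2))
}

test_that("acceleration 1 gives a full mask and invalid parameters error", {
  m <- generate_vd_poisson_mask(32, 8, accel = 1, seed = 0)
  expect_true(all(m$plane == 1L))
  expect_error(generate_vd_poisson_mask(32, 8, accel = 0.5, seed = 0), "accel")
  expect_error(generate_vd_poisson_mask(32, 8, accel = 8, center_fraction = 0.5,
                                        seed = 0), "budget")
  expect_error(generate_vd_poisson_mask(32, 8, accel = 4, center_fraction = 0,
                                        seed = 0), "center_fraction")
})

test_that("protocol-size mask at R=4 hits the sampling budget with a full center", {
  m <- generate_vd_poisson_mask(128, 36, accel = 4, center_fraction = 0.04,
                                seed = 0)
  expect_true(all(m$plane %in% c(0L, 1L)))
  expect_gte(mean(m$plane), 0.2375)
  expect_lte(mean(m$plane), 0.2625)
  rho <- center_rho(128, 36)
  expect_true(all(m$plane[rho <= 2 * sqrt(0.04 / pi)] == 1L))
})

test_that("masks are seed-reproducible and seed-sensitive", {
  a <- generate_vd_poisson_mask(64, 24, 4, seed = 5)
  b <- generate_vd_poisson_mask(64, 24, 4, seed = 5)
  c <- generate_vd_poisson_mask(64, 24, 4, seed = 6)
  expect_identical(a$plane, b$plane)
  expect_false(identical(a$plane, c$plane))
})

test_that("empirical acceleration is calibrated within 5% for R in 2,4,8", {
  for (R in c(2, 4, 8)) {
    for (s in 1:10) {
      m <- generate_vd_poisson_mask(96, 32, R, seed = s)
      expect_lte(abs(m$accel_empirical - R) / R, 0.05)
    }
  }
})

test_that("no two sampled points outside the center violate the local radius", {
  # O(n^2) pairwise oracle on the sampled coordinate list; the local
  # exclusion radius at each point is r0*(1 + alpha*rho) with unknown r0,
  # so verify the strongest r0 consistent with the accepted set: for every
  # pair, dist >= r(min rho) must hold with the r0 implied by the densest
  # admissible packing. We instead check the defining property directly by
  # regenerating with a known r0 through the exported interface: the
  # generator guarantees dist(p, q) >= r0*(1 + alpha*rho(p)) for the later-
  # placed point p. A necessary consequence checkable without r0: distances
  # between outside points grow with their distance from the center.
  m <- generate_vd_poisson_mask(64, 24, 4, seed = 3, alpha = 2.5)
  pts <- which(m$plane == 1L, arr.ind = TRUE)
  u <- (pts[, 1] - (floor(64 / 2) + 1)) / 32
  v <- (pts[, 2] - (floor(24 / 2) + 1)) / 12
  rho <- sqrt(u^2 + v^2)
  out <- rho > 2 * sqrt(0.04 / pi)
  pu <- u[out]; pv <- v[out]
  rn <- pmin(rho[out] / sqrt(2), 1)
  D <- as.matrix(stats::dist(cbind(pu, pv)))
  diag(D) <- Inf
  # r0 implied by the tightest pair relative to its radius factor
  fac <- outer(1 + 2.5 * rn, 1 + 2.5 * rn, pmin)
  r0_hat <- min(D / fac)
  expect_gt(r0_hat, 0)
  # every pair must satisfy the exclusion law at the shared r0
  expect_true(all(D >= r0_hat * fac - 1e-12))
  # inner points are packed more densely than outer points
  inner_d <- apply(D[rn < 0.4, rn < 0.4, drop = FALSE], 1, min)
  outer_d <- apply(D[rn > 0.7, rn > 0.7, drop = FALSE], 1, min)
  expect_lt(stats::median(inner_d), stats::median(outer_d))
})

test_that("apply_mask_zero_fill masks, broadcasts and is idempotent", {
  k <- rand_cvol(c(4, 6, 4), seed = 2)
  ones <- matrix(1L, 6, 4)
  expect_identical(apply_mask_zero_fill(k, ones), k)
  plane <- matrix(0L, 6, 4)
  plane[3, 2] <- 1L
  got <- apply_mask_zero_fill(k, plane)
  expect_equal(got[, 3, 2], k[, 3, 2])
  got[, 3, 2] <- 0
  expect_true(all(got == 0))
  m <- generate_vd_poisson_mask(6, 4, 2, center_fraction = 0.2, seed = 1)
  once <- apply_mask_zero_fill(k, m)
  expect_identical(apply_mask_zero_fill(once, m), once)
  expect_error(apply_mask_zero_fill(k, matrix(1L, 5, 4)), "match")
})

test_that("dc_residual matches the elementwise oracle and is linear", {
  k_it <- rand_cvol(c(4, 4, 2), seed = 7)
  k_us <- rand_cvol(c(4, 4, 2), seed = 8)
  set.seed(9)
  plane <- matrix(rbinom(8, 1, 0.5), 4, 2)
  mu <- 0.5
  oracle <- array(0i, dim(k_it))
  for (x in 1:4) for (y in 1:4) for (z in 1:2)
    oracle[x, y, z] <- mu * plane[y, z] * (k_it[x, y, z] - k_us[x, y, z])
  expect_equal(dc_residual(k_it, k_us, plane, mu), oracle)
  # zero on consistency, zero at mu = 0
  expect_true(all(dc_residual(k_us, k_us, plane, 1) == 0))
  expect_true(all(dc_residual(k_it, k_us, plane, 0) == 0))
  # homogeneity in mu, linearity in (k_it - k_us)
  expect_equal(dc_residual(k_it, k_us, plane, 2 * mu),
               2 * dc_residual(k_it, k_us, plane, mu))
  k2 <- rand_cvol(c(4, 4, 2), seed = 10)
  expect_equal(dc_residual(k_it + k2, k_us, plane, mu),
               dc_residual(k_it, k_us, plane, mu) +
                 dc_residual(k2, array(0i, dim(k2)), plane, mu))
})
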