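# Shared fixtures, all generated in code.

rand_cvol <- function(dims, seed = 1) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
}

rand_rvol <- function(dims, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(dims)), dims)
}

# tiny noiseless desk phantom + echoes, memoised per option set
desk_phantom <- local({
  cache <- list()
  function(noise_sd = 0, b0 = 50, seed = 1, matrix = c(32L, 32L, 8L)) {
    key <- paste(noise_sd, b0, seed, paste(matrix, collapse = "x"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- phantom_spec(matrix = matrix, noise_sd = noise_sd,
                         b0_amplitude = b0, seed = seed)
    ph <- make_thigh_phantom(spec)
    acq <- acquisition_spec(matrix = matrix)
    st <- simulate_dixon_echoes(ph$water, ph$fat, spec = spec, acq = acq)
    out <- list(spec = spec, ph = ph, acq = acq, stack = st)
    cache[[key]] <<- out
    out
  }
})

tiny_config <- function(variant = "halfvarnet", cascades = 2L, ch = 4L,
                        stages = 3L, dropout = 0) {
  network_config(variant, cascades = cascades, base_channels = ch,
                 stages = stages, dropout = dropout)
}

# direct (loop) 3D convolution oracle matching the package weight layout
conv3_oracle <- function(x, W, b, k) {
  d <- dim(x)
  C <- d[1]
  pad <- (k - 1) / 2
  out <- array(0, c(length(b), d[2:4]))
  for (co in seq_along(b)) for (xx in 1:d[2]) for (y in 1:d[3]) for (z in 1:d[4]) {
    s <- b[co]
    for (dz in 0:(k - 1)) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
      sx <- xx + dx - pad; sy <- y + dy - pad; sz <- z + dz - pad
      if (sx >= 1 && sx <= d[2] && sy >= 1 && sy <= d[3] && sz >= 1 && sz <= d[4]) {
        t <- dx + k * (dy + k * dz)
        for (c in 1:C) s <- s + W[co, c + C * t] * x[c, sx, sy, sz]
      }
    }
    out[co, xx, y, z] <- s
  }
  out
}
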