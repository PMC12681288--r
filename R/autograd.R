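# Minimal reverse-mode automatic differentiation engine.
#
# Nodes are environments holding `value` (a numeric/complex array), an
# accumulated `grad`, and a `bw` closure that pushes the node's gradient into
# its parents. Non-parameter nodes created while recording are appended to a
# tape; backward() walks the tape in reverse. Complex-valued nodes carry
# complex gradients under the real inner product: for y = A x with A
# complex-linear and unitary (the centered FFT), the pullback is A^H.
#
# Only the operations needed by the unrolled networks are implemented; each
# op computes its value eagerly and (while recording) caches what its
# backward pass needs.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

ag_recording <- function() .ag$recording

ag_tape_start <- function(capacity = 4096L) {
  .ag$recording <- TRUE
  .ag$tape <- vector("list", capacity)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(value, bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$param <- FALSE
  n$bw <- bw
  if (.ag$recording && !is.null(bw)) {
    .ag$n <- .ag$n + 1L
    if (.ag$n > length(.ag$tape))
      length(.ag$tape) <- 2L * length(.ag$tape)
    .ag$tape[[.ag$n]] <- n
  }
  n
}

ag_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$param <- TRUE
  n$bw <- NULL
  n
}

ag_const <- function(value) ag_node(value, bw = NULL)

ag_is_node <- function(x) is.environment(x) && !is.null(x$value)

add_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the current tape.
ag_backward <- function(loss) {
  if (!.ag$recording) stop("no active tape", call. = FALSE)
  loss$grad <- 1
  for (i in rev(seq_len(.ag$n))) {
    n <- .ag$tape[[i]]
    if (!is.null(n$grad) && !is.null(n$bw)) n$bw(n$grad)
  }
  invisible(NULL)
}

# ---- real tensor ops (layout (C, X, Y, Z)) --------------------------------

# 3D convolution, odd kernel k, stride 1, "same" zero padding.
# W: (Cout x Cin*k^3) matrix, rows of the column space ordered channel-fastest
# (c + Cin*tap); b: length Cout.
ag_conv3 <- function(x, W, b, k = 3L) {
  d <- dim(x$value)
  cols <- if (k == 1L) matrix(x$value, d[1], prod(d[2:4])) else .im2col3(x$value, k)
  out <- W$value %*% cols + b$value
  cout <- nrow(W$value)
  dim(out) <- c(cout, d[2], d[3], d[4])
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    gm <- matrix(g, cout, prod(d[2:4]))
    add_grad(W, tcrossprod(gm, cols))
    add_grad(b, rowSums(gm))
    dx <- crossprod(W$value, gm)
    if (k == 1L) dim(dx) <- d else dx <- .col2im3(dx, d, k)
    add_grad(x, dx)
  })
}

# Transpose convolution, kernel = stride = s (no overlap). For s = 2 the
# compiled fast path is used. W: (Cout*s^3 x Cin) matrix with row index
# cout + Cout*tap, tap = dx + s*(dy + s*dz); b: length Cout.
ag_tconv3 <- function(x, W, b, cout, s = 2L) {
  d <- dim(x$value)
  sp <- d[2:4]
  xm <- matrix(x$value, d[1], prod(sp))
  m <- W$value %*% xm
  out <- if (s == 2L) .block_expand2(m, cout, as.integer(sp))
         else block_expand_r(m, cout, sp, s)
  out <- out + b$value  # recycled along the channel-fastest axis
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    gm <- if (s == 2L) .block_collapse2(g, as.integer(sp))
          else block_collapse_r(g, cout, sp, s)
    add_grad(W, tcrossprod(gm, xm))
    add_grad(b, rowSums(matrix(g, cout, length(g) / cout)))
    dx <- crossprod(W$value, gm)
    dim(dx) <- d
    add_grad(x, dx)
  })
}

block_expand_r <- function(m, cout, sp, s) {
  # m: (cout*s^3) x prod(sp) with row index cout-fastest
  a <- array(m, c(cout, s, s, s, sp))
  a <- aperm(a, c(1, 2, 5, 3, 6, 4, 7))
  dim(a) <- c(cout, s * sp[1], s * sp[2], s * sp[3])
  a
}

block_collapse_r <- function(g, cout, sp, s) {
  a <- array(g, c(cout, s, sp[1], s, sp[2], s, sp[3]))
  a <- aperm(a, c(1, 2, 4, 6, 3, 5, 7))
  matrix(a, cout * s^3, prod(sp))
}

ag_maxpool3 <- function(x) {
  r <- .maxpool3_fw(x$value)
  if (!.ag$recording) return(ag_node(r$out))
  d <- dim(x$value)
  idx <- r$idx
  ag_node(r$out, bw = function(g) {
    add_grad(x, .maxpool3_bw(g, idx, as.integer(d)))
  })
}

# Instance normalization without learnable affine parameters: each channel is
# standardized over its spatial extent.
ag_instnorm3 <- function(x, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[1]
  xm <- matrix(x$value, C, prod(d[2:4]))
  mu <- rowMeans(xm)
  istd <- 1 / sqrt(rowMeans((xm - mu)^2) + eps)
  ym <- (xm - mu) * istd
  out <- ym
  dim(out) <- d
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    gm <- matrix(g, C, prod(d[2:4]))
    dx <- istd * (gm - rowMeans(gm) - ym * rowMeans(gm * ym))
    dim(dx) <- d
    add_grad(x, dx)
  })
}

ag_lrelu <- function(x, slope = 0.2) {
  v <- x$value
  neg <- v < 0
  v[neg] <- slope * v[neg]
  if (!.ag$recording) return(ag_node(v))
  ag_node(v, bw = function(g) {
    g[neg] <- slope * g[neg]
    add_grad(x, g)
  })
}

ag_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= p) / (1 - p)
  v <- x$value * keep
  dim(v) <- dim(x$value)
  if (!.ag$recording) return(ag_node(v))
  ag_node(v, bw = function(g) add_grad(x, g * keep))
}

ag_add <- function(x, y) {
  out <- x$value + y$value
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) { add_grad(x, g); add_grad(y, g) })
}

ag_add_list <- function(lst) {
  out <- lst[[1]]$value
  for (i in seq_along(lst)[-1]) out <- out + lst[[i]]$value
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) for (n in lst) add_grad(n, g))
}

# concatenate along the channel axis (dim 1)
ag_concat_c <- function(lst) {
  if (length(lst) == 1L) return(lst[[1]])
  dims <- lapply(lst, function(n) dim(n$value))
  cs <- vapply(dims, `[`, integer(1), 1L)
  sp <- dims[[1]][2:4]
  out <- array(0, c(sum(cs), sp))
  off <- 0L
  for (i in seq_along(lst)) {
    out[off + seq_len(cs[i]), , , ] <- lst[[i]]$value
    off <- off + cs[i]
  }
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    off <- 0L
    for (i in seq_along(lst)) {
      add_grad(lst[[i]], g[off + seq_len(cs[i]), , , , drop = FALSE])
      off <- off + cs[i]
    }
  })
}

# symmetric zero padding of the spatial axes up to target_sp; returns the
# node plus the crop record needed to invert it
ag_pad3 <- function(x, target_sp) {
  d <- dim(x$value)
  sp <- d[2:4]
  lo <- (target_sp - sp) %/% 2L
  if (all(lo == 0L) && all(target_sp == sp))
    return(list(node = x, crop = list(lo = lo, size = sp, padded = FALSE)))
  out <- array(0, c(d[1], target_sp))
  out[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]), lo[3] + seq_len(sp[3])] <- x$value
  crop <- list(lo = lo, size = sp, padded = TRUE)
  if (!.ag$recording) return(list(node = ag_node(out), crop = crop))
  node <- ag_node(out, bw = function(g) {
    add_grad(x, g[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]),
                  lo[3] + seq_len(sp[3]), drop = FALSE])
  })
  list(node = node, crop = crop)
}

ag_crop3 <- function(x, crop) {
  if (!crop$padded) return(x)
  lo <- crop$lo
  size <- crop$size
  d <- dim(x$value)
  out <- x$value[, lo[1] + seq_len(size[1]), lo[2] + seq_len(size[2]),
                 lo[3] + seq_len(size[3]), drop = FALSE]
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    dx <- array(0, d)
    dx[, lo[1] + seq_len(size[1]), lo[2] + seq_len(size[2]),
       lo[3] + seq_len(size[3])] <- g
    add_grad(x, dx)
  })
}

# y = a * x + b with constant scalars (used for normalization wrappers)
ag_affine <- function(x, a, b = 0) {
  out <- a * x$value + b
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) add_grad(x, a * g))
}

# Linear interpolation matrix mapping n points to f*n points, PyTorch
# align_corners = FALSE convention: output cell centers are sampled at
# (i + 0.5)/f - 0.5 in input index units, clamped at the edges.
interp_matrix <- function(n, f) {
  m <- f * n
  L <- matrix(0, m, n)
  src <- (seq_len(m) - 0.5) / f - 0.5        # 0-based source coordinate
  j0 <- pmax(0, pmin(n - 1, floor(src)))
  j1 <- pmax(0, pmin(n - 1, j0 + 1))
  w <- pmax(0, pmin(1, src - j0))
  for (i in seq_len(m)) {
    L[i, j0[i] + 1] <- L[i, j0[i] + 1] + (1 - w[i])
    L[i, j1[i] + 1] <- L[i, j1[i] + 1] + w[i]
  }
  L
}

apply_axis_mat <- function(v, L, axis) {
  # multiply array v (C, X, Y, Z) by L along spatial axis `axis` (1..3)
  d <- dim(v)
  perm <- c(axis + 1L, seq_along(d)[-(axis + 1L)])
  vp <- aperm(v, perm)
  dp <- dim(vp)
  m <- L %*% matrix(vp, dp[1], prod(dp[-1]))
  dim(m) <- c(nrow(L), dp[-1])
  aperm(m, order(perm))
}

# trilinear upsampling by an integer factor per axis
ag_upsample3 <- function(x, factors) {
  d <- dim(x$value)
  Ls <- lapply(1:3, function(a) if (factors[a] == 1) NULL
               else interp_matrix(d[a + 1], factors[a]))
  fwd <- function(v) {
    for (a in 1:3) if (!is.null(Ls[[a]])) v <- apply_axis_mat(v, Ls[[a]], a)
    v
  }
  out <- fwd(x$value)
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    for (a in 3:1) if (!is.null(Ls[[a]])) g <- apply_axis_mat(g, t(Ls[[a]]), a)
    add_grad(x, g)
  })
}

# ---- complex-domain ops ---------------------------------------------------

ag_fft3c <- function(x) {
  out <- fft3c(x$value)
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) add_grad(x, ifft3c(g)))
}

ag_ifft3c <- function(x) {
  out <- ifft3c(x$value)
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) add_grad(x, fft3c(g)))
}

ag_mask3 <- function(x, mask) {
  m <- broadcast_mask(mask, dim(x$value))
  out <- x$value * m
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) add_grad(x, g * m))
}

ag_csub <- function(x, y) {
  out <- x$value - y$value
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) { add_grad(x, g); add_grad(y, -g) })
}

ag_cadd <- function(x, y) ag_add(x, y)

# y = mu * x with a real scalar parameter mu and complex x
ag_cscale_param <- function(x, mu) {
  out <- mu$value * x$value
  if (!.ag$recording) return(ag_node(out))
  xv <- x$value
  ag_node(out, bw = function(g) {
    add_grad(mu, sum(Re(Conj(g) * xv)))
    add_grad(x, mu$value * g)
  })
}

# complex (X, Y, Z) -> two-channel real (2, X, Y, Z)
ag_c2ch <- function(x) {
  d <- dim(x$value)
  out <- array(0, c(2L, d))
  out[1, , , ] <- Re(x$value)
  out[2, , , ] <- Im(x$value)
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    gg <- g[1, , , ] + 1i * g[2, , , ]
    dim(gg) <- d
    add_grad(x, gg)
  })
}

# two-channel real (2, X, Y, Z) -> complex (X, Y, Z)
ag_ch2c <- function(x) {
  d <- dim(x$value)[2:4]
  out <- x$value[1, , , ] + 1i * x$value[2, , , ]
  dim(out) <- d
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) {
    gg <- array(0, c(2L, d))
    gg[1, , , ] <- Re(g)
    gg[2, , , ] <- Im(g)
    add_grad(x, gg)
  })
}

# mean squared error between a complex image node and a constant complex
# reference, on the two-channel real representation (2N real numbers)
ag_mse_cplx <- function(x, ref) {
  delta <- x$value - ref
  n2 <- 2 * length(delta)
  out <- sum(Re(delta)^2 + Im(delta)^2) / n2
  if (!.ag$recording) return(ag_node(out))
  ag_node(out, bw = function(g) add_grad(x, (2 * g / n2) * delta))
}
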