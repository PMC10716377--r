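# Differentiable layer operations on (channel, height, width) arrays.
# Convolution uses an im2col gather with cached index tables followed by a
# BLAS matmul; the backward pass scatters with rowsum(). All ops return
# nn_tensor nodes wired for nn_backward().

.im2col_cache <- new.env(parent = emptyenv())

# index table mapping (output pixel, cin*k*k) -> linear index into the
# zero-padded input array (C, H+2p, W+2p); columns ordered (cin, ki, kj)
# to match matrix(W, Cout, Cin*k*k)
im2col_index <- function(C, H, W, k, dilation) {
  key <- paste(C, H, W, k, dilation, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- dilation * (k - 1) / 2
  Hp <- H + 2 * p; Wp <- W + 2 * p
  off <- (seq_len(k) - 1 - (k - 1) / 2) * dilation
  # rows of Xcol: output pixels, h fastest then w (column-major of (H, W))
  hh <- rep(seq_len(H), times = W)
  ww <- rep(seq_len(W), each = H)
  ncol_x <- C * k * k
  idx <- matrix(0L, H * W, ncol_x)
  col <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) for (ci in seq_len(C)) {
    col <- col + 1L
    r <- hh + off[ki] + p
    cc <- ww + off[kj] + p
    idx[, col] <- ci + C * ((r - 1) + Hp * (cc - 1))
  }
  # reorder columns to (cin fastest, ki, kj): built above with ci fastest ✓
  out <- list(idx = idx, p = p, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

# 2D convolution, stride 1, "same" padding, odd kernel, optional dilation
op_conv2d <- function(x, w, b, dilation = 1) {
  dx <- dim(x$v); dw <- dim(w$v)
  C <- dx[1]; H <- dx[2]; W <- dx[3]
  Cout <- dw[1]; k <- dw[3]
  stopifnot(dw[2] == C, dw[4] == k, k %% 2 == 1)
  ii <- im2col_index(C, H, W, k, dilation)
  xpad <- array(0, dim = c(C, ii$Hp, ii$Wp))
  xpad[, ii$p + seq_len(H), ii$p + seq_len(W)] <- x$v
  Xcol <- matrix(xpad[ii$idx], nrow = H * W)
  Wmat <- matrix(w$v, nrow = Cout)
  out_mat <- Xcol %*% t(Wmat)
  out_mat <- sweep(out_mat, 2, b$v, "+")
  out <- aperm(array(out_mat, dim = c(H, W, Cout)), c(3, 1, 2))
  nn_tensor(out, parents = list(x, w, b), backward = function(g) {
    dmat <- t(matrix(g, nrow = Cout))                 # (HW, Cout)
    dW <- array(t(dmat) %*% Xcol, dim = dw)
    db <- colSums(dmat)
    # input gradient as a convolution of g with the flipped, transposed
    # kernel (gather + matmul instead of a scatter-add)
    jj <- im2col_index(Cout, H, W, k, dilation)
    gpad <- array(0, dim = c(Cout, jj$Hp, jj$Wp))
    gpad[, jj$p + seq_len(H), jj$p + seq_len(W)] <- g
    Gcol <- matrix(gpad[jj$idx], nrow = H * W)
    wt <- matrix(aperm(w$v[, , k:1, k:1, drop = FALSE], c(2, 1, 3, 4)),
                 nrow = C)                            # (Cin, Cout k^2)
    dXmat <- Gcol %*% t(wt)
    dx_arr <- aperm(array(dXmat, dim = c(H, W, C)), c(3, 1, 2))
    list(dx_arr, dW, db)
  })
}

op_dense <- function(x, w, b) {
  out <- as.numeric(w$v %*% x$v + b$v)
  nn_tensor(out, parents = list(x, w, b), backward = function(g) {
    list(as.numeric(t(w$v) %*% g), outer(g, x$v), g)
  })
}

op_add <- function(a, b) {
  nn_tensor(a$v + b$v, parents = list(a, b),
            backward = function(g) list(g, g))
}

op_leaky_relu <- function(x, slope = 0.1) {
  fac <- (x$v > 0) + slope * (x$v <= 0)
  nn_tensor(x$v * fac, parents = list(x),
            backward = function(g) list(g * fac))
}

op_relu <- function(x) {
  pos <- x$v > 0
  nn_tensor(x$v * pos, parents = list(x),
            backward = function(g) list(g * pos))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  nn_tensor(s, parents = list(x),
            backward = function(g) list(g * s * (1 - s)))
}

# instance normalisation: per-channel standardisation over (H, W) with
# learnable per-channel gamma/beta
op_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$v)
  C <- d[1]; n <- d[2] * d[3]
  xm <- matrix(x$v, C, n)
  mu <- rowMeans(xm)
  va <- rowMeans(xm^2) - mu^2
  sd_inv <- 1 / sqrt(va + eps)
  xh <- (xm - mu) * sd_inv
  y <- xh * gamma$v + beta$v
  nn_tensor(array(y, d), parents = list(x, gamma, beta), backward = function(g) {
    gm <- matrix(g, C, n)
    dgamma <- rowSums(gm * xh)
    dbeta <- rowSums(gm)
    dxh <- gm * gamma$v
    dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) * sd_inv
    list(array(dx, d), dgamma, dbeta)
  })
}

# global average pool over (H, W) -> channel vector
op_gap <- function(x) {
  d <- dim(x$v)
  C <- d[1]; n <- d[2] * d[3]
  out <- rowMeans(matrix(x$v, C, n))
  nn_tensor(out, parents = list(x), backward = function(g) {
    list(array(rep(g / n, n), dim = d))
  })
}

# multiply each channel by a scalar from vector node s (gating)
op_scale_channels <- function(x, s) {
  d <- dim(x$v)
  C <- d[1]; n <- d[2] * d[3]
  xm <- matrix(x$v, C, n)
  nn_tensor(array(xm * s$v, d), parents = list(x, s), backward = function(g) {
    gm <- matrix(g, C, n)
    list(array(gm * s$v, d), rowSums(gm * xm))
  })
}

op_concat_channels <- function(tensors) {
  cs <- vapply(tensors, function(t) dim(t$v)[1], numeric(1))
  d1 <- dim(tensors[[1]]$v)
  out <- array(0, dim = c(sum(cs), d1[2], d1[3]))
  at <- 0
  for (t in tensors) {
    out[at + seq_len(dim(t$v)[1]), , ] <- t$v
    at <- at + dim(t$v)[1]
  }
  nn_tensor(out, parents = tensors, backward = function(g) {
    res <- vector("list", length(tensors))
    at <- 0
    for (i in seq_along(tensors)) {
      ci <- dim(tensors[[i]]$v)[1]
      res[[i]] <- g[at + seq_len(ci), , , drop = FALSE]
      at <- at + ci
    }
    res
  })
}

op_avgpool2 <- function(x) {
  d <- dim(x$v)
  stopifnot(d[2] %% 2 == 0, d[3] %% 2 == 0)
  a <- array(x$v, dim = c(d[1], 2, d[2] / 2, 2, d[3] / 2))
  out <- (a[, 1, , 1, ] + a[, 2, , 1, ] + a[, 1, , 2, ] + a[, 2, , 2, ]) / 4
  dim(out) <- c(d[1], d[2] / 2, d[3] / 2)
  nn_tensor(out, parents = list(x), backward = function(g) {
    gb <- array(0, dim = c(d[1], 2, d[2] / 2, 2, d[3] / 2))
    for (i in 1:2) for (j in 1:2) gb[, i, , j, ] <- g / 4
    list(array(gb, dim = d))
  })
}

op_upsample2 <- function(x) {
  d <- dim(x$v)
  ri <- rep(seq_len(d[2]), each = 2)
  ci <- rep(seq_len(d[3]), each = 2)
  out <- x$v[, ri, ci, drop = FALSE]
  nn_tensor(out, parents = list(x), backward = function(g) {
    ga <- array(g, dim = c(d[1], 2, d[2], 2, d[3]))
    list(ga[, 1, , 1, ] + ga[, 2, , 1, ] + ga[, 1, , 2, ] + ga[, 2, , 2, ])
  })
}

# sub-pixel (pixel shuffle) upscale: (C r^2, H, W) -> (C, rH, rW)
op_pixel_shuffle <- function(x, r) {
  d <- dim(x$v)
  C <- d[1] / r^2
  stopifnot(C == round(C))
  H <- d[2]; W <- d[3]
  a <- array(x$v, dim = c(C, r, r, H, W))          # cin = c + C*(i-1 + r*(j-1))
  out <- array(0, dim = c(C, r * H, r * W))
  for (i in seq_len(r)) for (j in seq_len(r))
    out[, (seq_len(H) - 1) * r + i, (seq_len(W) - 1) * r + j] <- a[, i, j, , ]
  nn_tensor(out, parents = list(x), backward = function(g) {
    ga <- array(0, dim = c(C, r, r, H, W))
    for (i in seq_len(r)) for (j in seq_len(r))
      ga[, i, j, , ] <- g[, (seq_len(H) - 1) * r + i, (seq_len(W) - 1) * r + j]
    list(array(ga, dim = d))
  })
}

# elementwise difference with a constant target
op_sub_const <- function(x, target) {
  nn_tensor(x$v - target, parents = list(x), backward = function(g) list(g))
}

op_mean_sq <- function(x) {
  n <- length(x$v)
  nn_tensor(mean(x$v^2), parents = list(x),
            backward = function(g) list(g * 2 * x$v / n))
}

op_mean_abs <- function(x) {
  n <- length(x$v)
  nn_tensor(mean(abs(x$v)), parents = list(x),
            backward = function(g) list(g * sign(x$v) / n))
}

op_sum_sq <- function(x) {
  nn_tensor(sum(x$v^2), parents = list(x),
            backward = function(g) list(g * 2 * x$v))
}

# finite difference along one axis of a 3D array
op_axis_diff <- function(x, axis) {
  d <- dim(x$v)
  n <- d[axis]
  stopifnot(n >= 2)
  out <- switch(axis,
    x$v[2:n, , , drop = FALSE] - x$v[1:(n - 1), , , drop = FALSE],
    x$v[, 2:n, , drop = FALSE] - x$v[, 1:(n - 1), , drop = FALSE],
    x$v[, , 2:n, drop = FALSE] - x$v[, , 1:(n - 1), drop = FALSE])
  nn_tensor(out, parents = list(x), backward = function(g) {
    dx <- array(0, dim = d)
    if (axis == 1) {
      dx[2:n, , ] <- dx[2:n, , ] + g
      dx[1:(n - 1), , ] <- dx[1:(n - 1), , ] - g
    } else if (axis == 2) {
      dx[, 2:n, ] <- dx[, 2:n, ] + g
      dx[, 1:(n - 1), ] <- dx[, 1:(n - 1), ] - g
    } else {
      dx[, , 2:n] <- dx[, , 2:n] + g
      dx[, , 1:(n - 1)] <- dx[, , 1:(n - 1)] - g
    }
    list(dx)
  })
}

# weighted sum of scalar nodes: sum_i w_i s_i
op_scalar_comb <- function(scalars, weights) {
  val <- sum(vapply(seq_along(scalars), function(i)
    weights[i] * scalars[[i]]$v, numeric(1)))
  nn_tensor(val, parents = scalars, backward = function(g) {
    lapply(weights, function(w) g * w)
  })
}
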