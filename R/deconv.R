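#' Richardson-Lucy deconvolution settings
#'
#' @param iterations multiplicative updates to run (default 30).
#' @param epsilon small positive ratio guard added to denominators.
#' @param background constant background subtracted from the views (then
#'   clipped at zero) before iterating.
#' @return an `flfm_deconv_config`.
#' @export
deconv_config <- function(iterations = 30, epsilon = 1e-9, background = 0) {
  stopifnot(iterations >= 1, epsilon > 0, background >= 0)
  structure(list(iterations = as.integer(iterations), epsilon = epsilon,
                 background = background),
            class = "flfm_deconv_config")
}

# FFT machinery for the multi-view forward operator A x = sum_z x_z (*) k_zv.
# Builds padded kernel transforms once; forward crops the full convolution
# with the kernel-centre offset, the adjoint zero-embeds at the same offset
# and multiplies by the conjugate transforms (exact adjoint pair).
make_lf_operator <- function(kernels, h, w) {
  d <- dim(kernels)  # (depth, view, kh, kw)
  nd <- d[1]; nv <- d[2]; kh <- d[3]; kw <- d[4]
  P <- next_pow2(max(h + kh - 1, w + kw - 1))
  Kf <- array(0 + 0i, dim = c(nd, nv, P, P))
  for (iz in seq_len(nd)) for (iv in seq_len(nv)) {
    K <- matrix(0, P, P)
    K[seq_len(kh), seq_len(kw)] <- kernels[iz, iv, , ]
    Kf[iz, iv, , ] <- fft(K)
  }
  r0 <- floor(kh / 2); c0 <- floor(kw / 2)
  forward <- function(x) {  # x: (depth, h, w) -> (view, h, w)
    Xf <- array(0 + 0i, dim = c(nd, P, P))
    for (iz in seq_len(nd)) {
      A <- matrix(0, P, P); A[seq_len(h), seq_len(w)] <- x[iz, , ]
      Xf[iz, , ] <- fft(A)
    }
    out <- array(0, dim = c(nv, h, w))
    for (iv in seq_len(nv)) {
      acc <- matrix(0 + 0i, P, P)
      for (iz in seq_len(nd)) acc <- acc + Xf[iz, , ] * Kf[iz, iv, , ]
      full <- Re(fft(acc, inverse = TRUE)) / (P * P)
      out[iv, , ] <- full[r0 + seq_len(h), c0 + seq_len(w)]
    }
    out
  }
  adjoint <- function(r) {  # r: (view, h, w) -> (depth, h, w)
    Rf <- array(0 + 0i, dim = c(nv, P, P))
    for (iv in seq_len(nv)) {
      A <- matrix(0, P, P)
      A[r0 + seq_len(h), c0 + seq_len(w)] <- r[iv, , ]
      Rf[iv, , ] <- fft(A)
    }
    out <- array(0, dim = c(nd, h, w))
    for (iz in seq_len(nd)) {
      acc <- matrix(0 + 0i, P, P)
      for (iv in seq_len(nv)) acc <- acc + Rf[iv, , ] * Conj(Kf[iz, iv, , ])
      full <- Re(fft(acc, inverse = TRUE)) / (P * P)
      out[iz, , ] <- full[seq_len(h), seq_len(w)]
    }
    out
  }
  list(forward = forward, adjoint = adjoint, n_depth = nd, n_view = nv)
}

# Poisson log-likelihood of views y under model intensities mu (up to the
# x-independent log-factorial term)
poisson_loglik <- function(y, mu, epsilon = 1e-9) {
  sum(y * log(mu + epsilon) - mu)
}

#' Multi-view Richardson-Lucy deconvolution
#'
#' Reconstructs a nonnegative volume from the three sub-aperture views by
#' the multiplicative expectation-maximisation update
#' `x <- x * A^T( y / (A x + eps) ) / A^T 1`, where `A` is depthwise
#' convolution with the per-view kernels summed over depth. Nonnegativity is
#' preserved by construction and the Poisson log-likelihood is
#' non-decreasing every iteration.
#'
#' @param views an `flfm_views` or `(3, h, w)` array (background-subtracted
#'   measurements; `cfg$background` is subtracted here if nonzero).
#' @param kernels per-view kernel bank `(depth, view, kh, kw)` from
#'   [psf_views()].
#' @param cfg an `flfm_deconv_config`.
#' @param track_likelihood record the Poisson log-likelihood per iteration.
#' @param voxel_size_nm voxel size metadata for the returned volume.
#' @return an `flfm_volume` on the kernel depth grid, with attributes
#'   `loglik` (if tracked) and `iterations`.
#' @export
richardson_lucy <- function(views, kernels, cfg = deconv_config(),
                            track_likelihood = FALSE,
                            voxel_size_nm = c(NA, NA, NA)) {
  y <- if (inherits(views, "flfm_views")) views$data else views
  if (any(!is.finite(y))) stop("views contain non-finite values")
  if (any(!is.finite(kernels))) stop("kernels contain non-finite values")
  if (dim(y)[1] != dim(kernels)[2])
    stop("view count mismatch between views and kernel bank")
  y <- pmax(y - cfg$background, 0)
  h <- dim(y)[2]; w <- dim(y)[3]
  nd <- dim(kernels)[1]
  if (sum(y) == 0) {
    warning("all-zero views; returning a zero volume")
    out <- volume(array(0, dim = c(nd, h, w)), voxel_size_nm)
    attr(out, "iterations") <- 0L
    return(out)
  }
  op <- make_lf_operator(kernels, h, w)
  at1 <- op$adjoint(array(1, dim = dim(y)))
  at1 <- pmax(at1, cfg$epsilon)
  x <- array(mean(y) / nd, dim = c(nd, h, w))
  ll <- numeric(0)
  for (it in seq_len(cfg$iterations)) {
    ax <- pmax(op$forward(x), 0)
    if (track_likelihood) ll <- c(ll, poisson_loglik(y, ax, cfg$epsilon))
    ratio <- y / (ax + cfg$epsilon)
    x <- x * op$adjoint(ratio) / at1
    x[x < 0] <- 0
  }
  if (track_likelihood)
    ll <- c(ll, poisson_loglik(y, pmax(op$forward(x), 0), cfg$epsilon))
  out <- volume(x, voxel_size_nm)
  if (track_likelihood) attr(out, "loglik") <- ll
  attr(out, "iterations") <- cfg$iterations
  out
}

#' Reconstruct a raw light field by view extraction + Richardson-Lucy
#'
#' Composition of [extract_views()] and [richardson_lucy()] with kernels
#' cropped from the PSF by the same calibration; deterministic.
#'
#' @param lf an `flfm_lf`.
#' @param cal an `flfm_calibration`.
#' @param psf an `flfm_psf`.
#' @param cfg an `flfm_deconv_config`.
#' @param ... passed on to [richardson_lucy()].
#' @return an `flfm_volume`.
#' @export
reconstruct_lf <- function(lf, cal, psf, cfg = deconv_config(), ...) {
  views <- extract_views(lf, cal)
  kernels <- psf_views(psf, cal)
  vx <- c(diff(psf$depth_values)[1] * 1000, rep(lateral_sampling_nm(psf$config), 2))
  richardson_lucy(views, kernels, cfg, voxel_size_nm = vx, ...)
}
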