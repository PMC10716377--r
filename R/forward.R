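#' Clean light-field synthesis: y = sum_z x_z (*) H_z
#'
#' Depthwise linear, shift-invariant forward projection of a volume through
#' the FLFM measurement operator: each depth slice is convolved (zero-padded,
#' non-circular) with the full-sensor PSF of its plane and the results are
#' summed on the sensor. The volume's lateral grid must use the instrument's
#' sensor-referred sampling; a volume smaller than the sensor is embedded
#' centred.
#'
#' @param vol an `flfm_volume` (or 3D array) with depth planes matching the
#'   PSF depth grid.
#' @param psf an `flfm_psf` from [compute_psf()].
#' @return an `flfm_lf` (clean: no noise, no background).
#' @export
forward_project <- function(vol, psf) {
  x <- if (inherits(vol, "flfm_volume")) vol$data else vol
  stopifnot(inherits(psf, "flfm_psf"))
  nd <- dim(psf$full)[1]
  n <- dim(psf$full)[2]
  if (dim(x)[1] != nd)
    stop(sprintf("volume has %d depth planes but the PSF grid has %d (z axis mismatch)",
                 dim(x)[1], nd))
  if (dim(x)[2] > n || dim(x)[3] > n)
    stop("volume lateral extent exceeds the sensor (y/x axis mismatch)")
  if (inherits(vol, "flfm_volume")) {
    dx_nm <- lateral_sampling_nm(psf$config)
    if (any(abs(vol$voxel_size_nm[2:3] - dx_nm) > 1e-6 * dx_nm))
      stop("lateral voxel size does not match the sensor-referred sampling (y/x axis mismatch)")
  }
  s <- max(dim(x)[2], dim(x)[3])
  P <- next_pow2(n + s - 1)
  acc <- matrix(0 + 0i, P, P)
  for (iz in seq_len(nd)) {
    sl <- x[iz, , ]
    if (all(sl == 0)) next
    A <- matrix(0, P, P)
    A[seq_len(dim(x)[2]), seq_len(dim(x)[3])] <- sl
    K <- matrix(0, P, P)
    K[seq_len(n), seq_len(n)] <- psf$full[iz, , ]
    acc <- acc + fft(A) * fft(K)
  }
  full <- Re(fft(acc, inverse = TRUE)) / (P * P)
  # slice indices so that a centred impulse reproduces the centred PSF:
  # impulse at volume centre ci_s lands the kernel centre ci_n at
  # row (ci_s - 1) + ci_n of the full convolution
  r0 <- centre_index(dim(x)[2]) - 1
  c0 <- centre_index(dim(x)[3]) - 1
  y <- full[r0 + seq_len(n), c0 + seq_len(n)]
  y[y < 0 & y > -1e-12 * max(abs(y))] <- 0  # FFT round-off
  lf_image(pmax(y, 0), pixel_pitch_um = psf$pixel_pitch_um)
}

#' Noise and background parameters for sensor corruption
#'
#' @param poisson_gain photons per intensity unit (>= 0; 0 disables the
#'   Poisson branch).
#' @param gaussian_sigma read-noise standard deviation, intensity units.
#' @param background constant background offset `b`, intensity units.
#' @param seed integer RNG seed making corruption reproducible.
#' @return an `flfm_noise_params`.
#' @export
noise_params <- function(poisson_gain = 0, gaussian_sigma = 0,
                         background = 0, seed = 1L) {
  stopifnot(poisson_gain >= 0, gaussian_sigma >= 0, background >= 0)
  structure(list(poisson_gain = poisson_gain,
                 gaussian_sigma = gaussian_sigma,
                 background = background,
                 seed = as.integer(seed)),
            class = "flfm_noise_params")
}

#' Corrupt a clean light field with shot noise, read noise and background
#'
#' Applies, in physical order, Poisson shot noise on the clean intensities
#' (`Poisson(gain * clean) / gain`), additive Gaussian read noise
#' `N(0, sigma)`, and a constant background `b`, then clips at zero
#' (sensor outputs are nonnegative after offset subtraction). Deterministic
#' under the seed in `params`.
#'
#' @param clean an `flfm_lf` or nonnegative matrix/array.
#' @param params an `flfm_noise_params`.
#' @return object of the same shape/class as `clean`.
#' @export
corrupt_lf <- function(clean, params) {
  stopifnot(inherits(params, "flfm_noise_params"))
  x <- if (inherits(clean, "flfm_lf")) clean$data else clean
  if (any(x < 0)) stop("clean input must be nonnegative")
  d <- dim(x)
  out <- with_seed(params$seed, {
    v <- as.numeric(x)
    if (params$poisson_gain > 0) {
      lam <- params$poisson_gain * v
      big <- lam > 1e8  # beyond integer-safe rpois; moment-matched Gaussian
      v[!big] <- rpois(sum(!big), lam[!big]) / params$poisson_gain
      if (any(big))
        v[big] <- (lam[big] + sqrt(lam[big]) * rnorm(sum(big))) / params$poisson_gain
    }
    if (params$gaussian_sigma > 0)
      v <- v + rnorm(length(v), 0, params$gaussian_sigma)
    v + params$background
  })
  out <- pmax(out, 0)
  dim(out) <- d
  if (inherits(clean, "flfm_lf")) lf_image(out, clean$pixel_pitch_um) else out
}

#' Signal-to-background ratio of a clean light field
#'
#' Foreground pixels are those above the Otsu threshold of the clean image;
#' SBR is `mean(foreground) / mean(background)` evaluated after adding the
#' constant background `b` to both.
#'
#' @param clean clean `flfm_lf` or matrix.
#' @param background constant background to include.
#' @return SBR (ratio).
#' @export
measure_sbr <- function(clean, background = 0) {
  x <- if (inherits(clean, "flfm_lf")) clean$data else clean
  th <- otsu_threshold(x)
  fg <- x > th
  if (!any(fg) || all(fg)) stop("cannot separate foreground from background")
  (mean(x[fg]) + background) / (mean(x[!fg]) + background)
}

#' Fit noise parameters to a target SNR and SBR
#'
#' Chooses `(gain, sigma, b)` so that the corruption of `clean` realises a
#' requested SNR (measured by [measure_snr()] with reference `clean + b`)
#' and signal-to-background ratio. The background is solved in closed form
#' from the SBR definition; the Poisson gain is set so shot noise carries
#' half of the noise power budget `S / 10^(SNR/10)`; sigma is initialised
#' from the remaining budget and then refined by bisection against the
#' seeded Monte-Carlo mean of the realised SNR (which absorbs the
#' zero-clipping bias).
#'
#' @param clean clean `flfm_lf` or matrix with nonzero signal.
#' @param target_snr_db target SNR in dB (e.g. -1.62 for the low-light
#'   regime of interest).
#' @param target_sbr target signal-to-background ratio (> 1).
#' @param seed RNG seed for the fit and the returned parameters.
#' @param n_draws Monte-Carlo draws per SNR estimate during refinement.
#' @param tol_db accepted deviation from the target, dB (default 0.1).
#' @return an `flfm_noise_params`.
#' @export
fit_noise_to_target <- function(clean, target_snr_db, target_sbr = 3,
                                seed = 1L, n_draws = 6, tol_db = 0.1) {
  x <- if (inherits(clean, "flfm_lf")) clean$data else clean
  if (!is.finite(target_snr_db)) stop("target SNR must be finite")
  if (target_sbr <= 1) stop("target SBR must exceed 1")
  if (max(x) <= 0 || stats::sd(x) == 0) stop("clean input has no signal")
  th <- otsu_threshold(x)
  fg_mean <- mean(x[x > th])
  bg_mean <- mean(x[x <= th])
  b <- (fg_mean - target_sbr * bg_mean) / (target_sbr - 1)
  if (b < 0)
    stop(sprintf("target SBR %.2f is above the noiseless limit %.2f of this image",
                 target_sbr, fg_mean / max(bg_mean, .Machine$double.eps)))
  f <- x + b
  s_pow <- sum((f - mean(f))^2)
  n_pow <- s_pow / 10^(target_snr_db / 10)
  gain <- 2 * sum(x) / n_pow           # Poisson carries half the budget
  sigma0 <- sqrt(n_pow / (2 * length(x)))
  realised <- function(sigma, k = n_draws) {
    snrs <- vapply(seq_len(k), function(i) {
      p <- noise_params(gain, sigma, b, seed = seed * 1000L + i)
      measure_snr(f, corrupt_lf(x, p))
    }, numeric(1))
    mean(snrs)
  }
  # bracket: realised SNR decreases in sigma
  lo <- 0; hi <- sigma0
  while (realised(hi) > target_snr_db && hi < sigma0 * 64) hi <- hi * 2
  if (realised(hi) > target_snr_db)
    stop("target SNR unreachable: Poisson floor already below target noise")
  for (i in seq_len(40)) {
    mid <- (lo + hi) / 2
    r <- realised(mid)
    if (abs(r - target_snr_db) < tol_db) { lo <- hi <- mid; break }
    if (r > target_snr_db) lo <- mid else hi <- mid
  }
  noise_params(gain, (lo + hi) / 2, b, seed = seed)
}
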