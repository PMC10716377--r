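test_that("forward projection is the depthwise convolution y = sum_z x_z * H_z", {
  psf <- fx_psf()
  D <- dim(psf$full)[1]
  # zero volume -> zero light field
  z0 <- forward_project(array(0, dim = c(D, 17, 17)), psf)
  expect_true(all(z0$data == 0))
  # centred impulse reproduces the PSF page exactly (machine precision)
  x <- array(0, dim = c(D, 33, 33)); x[5, 17, 17] <- 2.5
  lf <- forward_project(x, psf)
  expect_lt(max(abs(lf$data - 2.5 * psf$full[5, , ])), 1e-12)
  # depth-grid mismatch names the axis
  expect_error(forward_project(array(1, dim = c(D + 2, 9, 9)), psf), "z axis")
})

test_that("forward projection matches a direct convolution oracle and is linear", {
  psf <- fx_psf()
  D <- dim(psf$full)[1]
  set.seed(31)
  x1 <- array(runif(D * 9 * 9), dim = c(D, 9, 9)) *
    array(rbinom(D * 9 * 9, 1, 0.1), dim = c(D, 9, 9))  # sparse keeps oracle fast
  x2 <- array(runif(D * 9 * 9), dim = c(D, 9, 9)) *
    array(rbinom(D * 9 * 9, 1, 0.1), dim = c(D, 9, 9))
  y1 <- forward_project(x1, psf)$data
  o1 <- oracle_forward(x1, psf)
  expect_lt(max(abs(y1 - o1)) / max(o1), 1e-6)
  y2 <- forward_project(x2, psf)$data
  y12 <- forward_project(x1 + x2, psf)$data
  expect_lt(max(abs(y12 - (y1 + y2))) / max(y12), 1e-6)
})

test_that("corruption handles the degenerate noise-free case and is seeded", {
  clean <- matrix(runif(64, 0, 3), 8, 8)
  p0 <- noise_params(poisson_gain = 0, gaussian_sigma = 0, background = 5)
  expect_equal(corrupt_lf(clean, p0), clean + 5)
  p <- noise_params(poisson_gain = 3, gaussian_sigma = 0.2, background = 1, seed = 9)
  a <- corrupt_lf(clean, p)
  b <- corrupt_lf(clean, p)
  expect_identical(a, b)
  expect_false(identical(a, corrupt_lf(clean, noise_params(3, 0.2, 1, seed = 10))))
  expect_error(corrupt_lf(clean - 10, p), "nonnegative")
})

test_that("corruption has the physical first and second moments", {
  clean <- matrix(4, 64, 64)
  gain <- 5; sigma <- 0.3; b <- 2
  n_draws <- 10000
  s1 <- 0; s2 <- 0
  for (i in seq_len(n_draws)) {
    y <- corrupt_lf(clean, noise_params(gain, sigma, b, seed = i))
    s1 <- s1 + sum(y); s2 <- s2 + sum(y^2)
  }
  n_tot <- n_draws * length(clean)
  mu <- s1 / n_tot
  va <- s2 / n_tot - mu^2
  va_true <- 4 / gain + sigma^2
  se <- sqrt(va_true / n_tot)
  expect_lt(abs(mu - (4 + b)), 3 * se)
  expect_lt(abs(va - va_true) / va_true, 0.10)
})

test_that("noise fitting realises a requested SNR and SBR", {
  psf <- fx_psf()
  cal <- calibration_from_config(fx_cfg(), view_size = 65)
  lf <- forward_project(fx_bead_phantom(), psf)
  v <- extract_views(lf, cal)$data
  np <- fit_noise_to_target(v, -1.62, target_sbr = 3, seed = 3)
  # realised SNR (fresh seeds, not those used in the fit)
  snrs <- vapply(1:4, function(i) {
    y <- corrupt_lf(v, noise_params(np$poisson_gain, np$gaussian_sigma,
                                    np$background, seed = 5000 + i))
    measure_snr(v + np$background, y)
  }, numeric(1))
  expect_lt(abs(mean(snrs) - (-1.62)), 0.5)
  sbr <- measure_sbr(v, np$background)
  expect_lt(abs(sbr - 3) / 3, 0.05)
})

test_that("noise fitting limits and monotonicity", {
  psf <- fx_psf()
  cal <- calibration_from_config(fx_cfg(), view_size = 65)
  v <- extract_views(forward_project(fx_bead_phantom(), psf), cal)$data
  # very high target SNR -> vanishing sigma, large gain
  np_hi <- fit_noise_to_target(v, 40, target_sbr = 3, seed = 2)
  np_lo <- fit_noise_to_target(v, -1.62, target_sbr = 3, seed = 2)
  expect_gt(np_hi$poisson_gain, np_lo$poisson_gain)
  expect_lt(np_hi$gaussian_sigma, np_lo$gaussian_sigma / 10)
  # realised SNR decreases monotonically in sigma at fixed gain
  snr_at <- function(s) {
    y <- corrupt_lf(v, noise_params(np_lo$poisson_gain, s, np_lo$background, seed = 77))
    measure_snr(v + np_lo$background, y)
  }
  s_grid <- np_lo$gaussian_sigma * c(0.25, 1, 4)
  snrs <- vapply(s_grid, snr_at, numeric(1))
  expect_true(all(diff(snrs) < 0))
  expect_error(fit_noise_to_target(v, Inf, 3), "finite")
  expect_error(fit_noise_to_target(v * 0, 0, 3), "signal")
})
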