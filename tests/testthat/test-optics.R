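test_that("optical configuration invariants are enforced", {
  cfg <- optical_config()
  expect_equal(cfg$lenslet_focal / cfg$lenslet_pitch, 36.92, tolerance = 1e-3)
  expect_equal(lateral_sampling_nm(cfg), 162.5)
  expect_equal(sum(depth_values_um(cfg) == 0), 1)
  expect_error(optical_config(numerical_aperture = 1.6), "immersion")
  expect_error(optical_config(depth_planes = 40), "odd")
  expect_error(optical_config(f_number = 30), "f_number")
  # overlapping lenslets: centres closer than the pitch
  expect_error(optical_config(
    lenslet_centers = rbind(c(0, 1), c(0, -1), c(2, 0))), "overlap")
  # aperture pushed outside the pupil
  expect_error(optical_config(
    lenslet_centers = rbind(c(0, 3.5), c(0, -3.5), c(3.5, 0))), "pupil")
})

test_that("DOE phase is a wrapped thin-lens profile per lenslet", {
  cfg <- fx_cfg()
  doe <- doe_phase(cfg)
  lam <- cfg$emission_wavelength * 1e-9
  f_ml <- cfg$lenslet_focal * 1e-3
  n <- cfg$sensor_grid[1]
  du <- doe$sample_spacing_m
  u <- (seq_len(n) - (floor(n / 2) + 1)) * du
  ux <- matrix(u, n, n, byrow = TRUE); uy <- matrix(u, n, n)
  for (j in seq_len(3)) {
    cx <- cfg$lenslet_centers[j, 1] * 1e-3
    cy <- cfg$lenslet_centers[j, 2] * 1e-3
    r2 <- (ux - cx)^2 + (uy - cy)^2
    inside <- r2 <= (cfg$lenslet_pitch / 2 * 1e-3)^2
    # vertex: phase at the grid sample nearest the lenslet centre is zero
    # up to the sub-sample quadratic term pi*(du^2/2)/(lambda f_ML)
    i_ctr <- which(r2 == min(r2), arr.ind = TRUE)[1, ]
    ph0 <- doe$phase[i_ctr[1], i_ctr[2]] %% (2 * pi)
    vertex_bound <- 2 * pi * (du^2 / 2) / (lam * f_ml)
    expect_lt(min(ph0, 2 * pi - ph0), vertex_bound)
    # unwrapped radial profile matches -pi r^2 / (lambda f_ML)
    expected <- (-pi * r2[inside] / (lam * f_ml)) %% (2 * pi)
    err <- abs(doe$phase[inside] - expected)
    err <- pmin(err, 2 * pi - err)
    expect_lt(max(err) / max(abs(-pi * r2[inside] / (lam * f_ml))), 1e-6)
  }
  expect_true(all(doe$phase >= 0 & doe$phase < 2 * pi))
})

test_that("DOE phase is invariant under the 120-degree arrangement symmetry", {
  cfg <- fx_cfg()
  doe <- doe_phase(cfg)
  n <- cfg$sensor_grid[1]
  du <- doe$sample_spacing_m
  u <- (seq_len(n) - (floor(n / 2) + 1)) * du
  ux <- matrix(u, n, n, byrow = TRUE); uy <- matrix(u, n, n)
  # radial phase histogram about each lenslet centre must coincide
  profiles <- lapply(seq_len(3), function(j) {
    cx <- cfg$lenslet_centers[j, 1] * 1e-3
    cy <- cfg$lenslet_centers[j, 2] * 1e-3
    r <- sqrt((ux - cx)^2 + (uy - cy)^2)
    inside <- r <= (cfg$lenslet_pitch / 2 * 1e-3)
    bins <- cut(r[inside], breaks = seq(0, cfg$lenslet_pitch / 2 * 1e-3,
                                        length.out = 24))
    tapply(doe$phase[inside], bins, mean)
  })
  expect_equal(profiles[[1]], profiles[[2]], tolerance = 1e-2)
  expect_equal(profiles[[1]], profiles[[3]], tolerance = 1e-2)
})

test_that("simulated PSF shows three sub-PSFs at the geometric positions", {
  psf <- fx_psf()
  cfg <- fx_cfg()
  iz0 <- which.min(abs(psf$depth_values))
  pred <- psf_spot_centers(cfg, 0)
  half <- (psf$view_size - 1) / 2
  ctr <- attr(psf$views, "centers_px")
  pos <- t(vapply(seq_len(3), function(j) {
    v <- psf$views[iz0, j, , ]
    idx <- which(v == max(v), arr.ind = TRUE)[1, ]
    c(ctr[j, 1] - half - 1 + idx[1], ctr[j, 2] - half - 1 + idx[2])
  }, numeric(2)))
  expect_lt(max(abs(pos - pred)), 1)
  # pairwise spot distances equal for the equilateral arrangement
  d <- as.matrix(dist(pos))
  pw <- d[upper.tri(d)]
  expect_lt(max(pw) - min(pw), 1)
})

test_that("per-depth PSF energy is conserved across the depth range", {
  psf <- fx_psf()
  e <- apply(psf$full, 1, sum)
  expect_lt((max(e) - min(e)) / mean(e), 0.05)
  expect_true(all(psf$full >= 0))
})

test_that("per-view centroid shifts linearly with depth at the geometric parallax rate", {
  psf <- fx_psf()
  cfg <- fx_cfg()
  slopes_pred <- parallax_slope_px_per_um(cfg)
  z <- psf$depth_values
  slopes_sim <- matrix(0, 3, 2)
  for (j in seq_len(3)) {
    cr <- vapply(seq_along(z), function(iz) {
      v <- psf$views[iz, j, , ]
      w <- v / sum(v)
      c(sum(row(v) * w), sum(col(v) * w))
    }, numeric(2))
    fit_r <- lm(cr[1, ] ~ z); fit_c <- lm(cr[2, ] ~ z)
    slopes_sim[j, ] <- c(coef(fit_r)[2], coef(fit_c)[2])
    # linearity: R^2 > 0.99 on any axis with non-trivial motion
    if (abs(slopes_pred[j, 1]) > 0.2)
      expect_gt(summary(fit_r)$r.squared, 0.99)
    if (abs(slopes_pred[j, 2]) > 0.2)
      expect_gt(summary(fit_c)$r.squared, 0.99)
  }
  # magnitude within 10% of the geometric prediction
  mag_sim <- sqrt(rowSums(slopes_sim^2))
  mag_pred <- sqrt(rowSums(slopes_pred^2))
  expect_lt(max(abs(mag_sim - mag_pred) / mag_pred), 0.10)
  # opposite slope sign for lenslets on opposite sides of the axis
  expect_lt(sum(slopes_sim[1, ] * slopes_sim[2, ]), 0)
  expect_lt(sum(slopes_sim[1, ] * slopes_sim[3, ]), 0)
})

test_that("sampling violations at extreme defocus raise an error naming the depth", {
  cfg <- mini_optical_config(depth_planes = 5, depth_range = 60)
  expect_error(compute_psf(cfg, view_size = 33), "um")
})

test_that("the PSF is converged with respect to the simulation window", {
  # doubling the sensor grid both refines the pupil sampling and pushes
  # the periodic window twice as far away; the per-view kernels (identical
  # physical windows) must be stable under it, bounding wrap-around and
  # discretisation error together
  cfg <- mini_optical_config(depth_planes = 3, depth_range = 3.5)
  cfg2 <- mini_optical_config(depth_planes = 3, depth_range = 3.5,
                              sensor_grid = c(640, 640))
  p1 <- compute_psf(cfg, view_size = 49)
  p2 <- compute_psf(cfg2, view_size = 49)
  rel <- max(abs(p1$views - p2$views)) / max(p1$views)
  expect_lt(rel, 0.01)
})

test_that("per-view kernels reassemble onto the sensor and partition energy", {
  psf <- fx_psf()
  cal <- calibration_from_config(fx_cfg(), view_size = 119)
  kern <- psf_views(psf, cal)
  expect_true(all(kern >= 0))
  back <- assemble_psf_views(kern)
  # exact reproduction inside the view windows
  ctr <- attr(kern, "centers_px")
  half <- (dim(kern)[3] - 1) / 2
  for (j in seq_len(3)) {
    rows <- (ctr[j, 1] - half):(ctr[j, 1] + half)
    cols <- (ctr[j, 2] - half):(ctr[j, 2] + half)
    expect_identical(back[, rows, cols], psf$full[, rows, cols])
  }
  # view energies account for (nearly) all sensor energy per depth
  e_views <- apply(kern, 1, sum)
  e_full <- apply(psf$full, 1, sum)
  expect_true(all(e_views / e_full > 0.95))
  expect_true(all(e_views <= e_full + 1e-12))
  # crop window beyond the sensor errors
  cal_bad <- cal; cal_bad$view_size <- 401
  expect_error(psf_views(psf, cal_bad), "sensor")
})

test_that("the three on-axis view kernels are congruent up to the arrangement symmetry", {
  psf <- fx_psf()
  iz0 <- which.min(abs(psf$depth_values))
  # for the circular sub-apertures the on-axis kernels are translated
  # copies; the Fourier modulus is translation-invariant, so congruence
  # shows as identical |FFT| up to the sub-pixel sampling offsets
  fmod <- lapply(seq_len(3), function(j)
    Mod(stats::fft(psf$views[iz0, j, , ])))
  rms <- function(a, b) sqrt(mean((a - b)^2))
  peak <- max(fmod[[1]])
  expect_lt(rms(fmod[[1]], fmod[[2]]) / peak, 0.01)
  expect_lt(rms(fmod[[1]], fmod[[3]]) / peak, 0.01)
})
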