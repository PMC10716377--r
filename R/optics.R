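#' Optical configuration of an FLFM instrument
#'
#' Collects every optical/system constant of the Fourier light-field
#' microscope: objective, Fourier lens, the three-lenslet diffractive Fourier
#' microlens (DOE), sensor and reconstruction depth grid. Defaults describe a
#' 100x/1.4 NA oil-immersion system with a 300 mm Fourier lens and a DOE with
#' lenslet pitch 3.25 mm, lenslet focal length 120 mm (f-number ~37), imaging
#' 41 depth planes across a ~7 um axial range.
#'
#' The Fourier pupil radius at the DOE plane is
#' `fourier_lens_focal * NA / magnification` and the sensor-referred lateral
#' sampling is `sensor_pixel_pitch / (magnification * lenslet_focal /
#' fourier_lens_focal)` (162.5 nm for the defaults). Lenslet centres default
#' to an equilateral triangle at the radius where the lenslet apertures
#' inscribe the pupil.
#'
#' @param objective_magnification dimensionless magnification (default 100).
#' @param numerical_aperture objective NA (default 1.4).
#' @param immersion_index refractive index of the immersion medium (1.518).
#' @param emission_wavelength emission wavelength in nm (default 510, EGFP).
#' @param fourier_lens_focal Fourier lens focal length, mm (default 300).
#' @param lenslet_pitch lenslet pitch (= aperture diameter), mm (default 3.25).
#' @param lenslet_focal lenslet focal length, mm (default 120).
#' @param lenslet_count number of lenslets/views (default 3).
#' @param f_number nominal lenslet f-number (default 37); checked against
#'   `lenslet_focal / lenslet_pitch` within 1%.
#' @param lenslet_centers `lenslet_count x 2` matrix of (x, y) positions in
#'   the Fourier plane, mm; `NULL` for the default equilateral arrangement
#'   (first centre at 90 degrees from the +x axis; y along increasing rows).
#' @param sensor_pixel_pitch sensor pixel pitch, um (default 6.5).
#' @param sensor_grid sensor size in pixels, `(height, width)`; must be
#'   square for the single-FFT propagator.
#' @param depth_planes odd number of depth planes (default 41).
#' @param depth_range half-range of the symmetric depth grid, um (default
#'   3.5, i.e. ~7 um total).
#' @param iris_diameter_at_nip optional field-iris diameter at the native
#'   image plane, mm (informational; view overlap is prevented by the
#'   aperture-disjointness check instead).
#' @param view_size side length of per-view crops in pixels; `NULL` derives
#'   the largest odd window that stays inside the sensor and keeps views
#'   disjoint.
#' @return an object of class `flfm_optical_config`.
#' @export
optical_config <- function(objective_magnification = 100,
                           numerical_aperture = 1.4,
                           immersion_index = 1.518,
                           emission_wavelength = 510,
                           fourier_lens_focal = 300,
                           lenslet_pitch = 3.25,
                           lenslet_focal = 120,
                           lenslet_count = 3,
                           f_number = 37,
                           lenslet_centers = NULL,
                           sensor_pixel_pitch = 6.5,
                           sensor_grid = c(1024, 1024),
                           depth_planes = 41,
                           depth_range = 3.5,
                           iris_diameter_at_nip = NULL,
                           view_size = NULL) {
  cfg <- list(
    objective_magnification = objective_magnification,
    numerical_aperture = numerical_aperture,
    immersion_index = immersion_index,
    emission_wavelength = emission_wavelength,
    fourier_lens_focal = fourier_lens_focal,
    lenslet_pitch = lenslet_pitch,
    lenslet_focal = lenslet_focal,
    lenslet_count = lenslet_count,
    f_number = f_number,
    lenslet_centers = lenslet_centers,
    sensor_pixel_pitch = sensor_pixel_pitch,
    sensor_grid = sensor_grid,
    depth_planes = depth_planes,
    depth_range = depth_range,
    iris_diameter_at_nip = iris_diameter_at_nip,
    view_size = view_size
  )
  class(cfg) <- "flfm_optical_config"
  if (is.null(cfg$lenslet_centers))
    cfg$lenslet_centers <- default_lenslet_centers(cfg)
  validate_optical_config(cfg)
  cfg
}

#' Desk-scale FLFM configuration
#'
#' A physically consistent miniature of the default instrument (shorter
#' Fourier lens and lenslet focal lengths, smaller pitch) whose PSF fits a
#' 320 x 320 sensor grid, for examples and fast simulation studies. Same
#' objective, wavelength and lateral sampling (162.5 nm) as the full system.
#'
#' @param ... overrides passed to [optical_config()].
#' @return an `flfm_optical_config`.
#' @export
mini_optical_config <- function(...) {
  args <- modifyList(list(fourier_lens_focal = 75,
                          lenslet_pitch = 0.8,
                          lenslet_focal = 30,
                          f_number = 37.5,
                          sensor_grid = c(320, 320),
                          depth_planes = 21),
                     list(...))
  do.call(optical_config, args)
}

# pupil radius at the DOE plane, mm
pupil_radius_mm <- function(cfg)
  cfg$fourier_lens_focal * cfg$numerical_aperture / cfg$objective_magnification

#' Sensor-referred lateral sampling of the instrument, nm
#' @param cfg an `flfm_optical_config`.
#' @return lateral sample spacing in object space, nm.
#' @export
lateral_sampling_nm <- function(cfg) {
  m_total <- cfg$objective_magnification * cfg$lenslet_focal / cfg$fourier_lens_focal
  cfg$sensor_pixel_pitch / m_total * 1e3
}

#' Depth grid of the configuration, um
#' @param cfg an `flfm_optical_config`.
#' @return numeric vector of `depth_planes` symmetric depths.
#' @export
depth_values_um <- function(cfg)
  seq(-cfg$depth_range, cfg$depth_range, length.out = cfg$depth_planes)

default_lenslet_centers <- function(cfg) {
  r <- pupil_radius_mm(cfg) - cfg$lenslet_pitch / 2
  ang <- (90 + 120 * (seq_len(cfg$lenslet_count) - 1)) * pi / 180
  cbind(x = r * cos(ang), y = r * sin(ang))
}

# DOE-plane sample spacing in metres (single-FFT conjugate-plane sampling):
# the FFT maps an N-sample DOE plane with spacing du onto the sensor with
# spacing dx = lambda * f_ML / (N * du).
mla_sample_spacing_m <- function(cfg) {
  lam <- cfg$emission_wavelength * 1e-9
  f_ml <- cfg$lenslet_focal * 1e-3
  dx <- cfg$sensor_pixel_pitch * 1e-6
  lam * f_ml / (cfg$sensor_grid[1] * dx)
}

#' Validate an optical configuration
#'
#' Checks NA < immersion index, the lenslet f-number (focal/pitch within 1%
#' of the nominal value), oddness and symmetry of the depth grid, and that
#' the lenslet apertures are pairwise disjoint, lie inside the Fourier pupil
#' and inside the sampled DOE window.
#'
#' @param cfg an `flfm_optical_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_optical_config <- function(cfg) {
  stopifnot(inherits(cfg, "flfm_optical_config"))
  if (cfg$numerical_aperture >= cfg$immersion_index)
    stop("numerical_aperture must be smaller than immersion_index")
  if (!is.null(cfg$f_number)) {
    fn <- cfg$lenslet_focal / cfg$lenslet_pitch
    if (abs(fn - cfg$f_number) / cfg$f_number > 0.01)
      stop(sprintf("lenslet_focal/lenslet_pitch = %.2f deviates from f_number %.2f by > 1%%",
                   fn, cfg$f_number))
  }
  if (cfg$depth_planes %% 2 != 1 || cfg$depth_planes < 1)
    stop("depth_planes must be odd so a z = 0 plane exists")
  if (cfg$sensor_grid[1] != cfg$sensor_grid[2])
    stop("sensor_grid must be square")
  cen <- cfg$lenslet_centers
  if (nrow(cen) != cfg$lenslet_count)
    stop("lenslet_centers must have lenslet_count rows")
  r_pupil <- pupil_radius_mm(cfg)
  radii <- sqrt(rowSums(cen^2))
  if (any(radii + cfg$lenslet_pitch / 2 > r_pupil * (1 + 1e-9)))
    stop("lenslet apertures must lie inside the Fourier pupil")
  if (cfg$lenslet_count > 1) {
    dmin <- min(stats::dist(cen))
    if (dmin < cfg$lenslet_pitch)
      stop("lenslet apertures overlap: minimum centre distance ",
           sprintf("%.3f mm < pitch %.3f mm", dmin, cfg$lenslet_pitch))
  }
  half_window_mm <- cfg$sensor_grid[1] / 2 * mla_sample_spacing_m(cfg) * 1e3
  if (max(radii) + cfg$lenslet_pitch / 2 > half_window_mm)
    stop("sampled DOE window does not cover the lenslet apertures; ",
         "decrease sensor_pixel_pitch or the lenslet radius")
  invisible(cfg)
}

# lenslet centres on the sensor, px (row, col), 1-based, exact (not rounded)
lenslet_centers_px <- function(cfg) {
  dx_mm <- cfg$sensor_pixel_pitch * 1e-3
  ci <- centre_index(cfg$sensor_grid[1])
  cbind(row = ci + cfg$lenslet_centers[, 2] / dx_mm,
        col = ci + cfg$lenslet_centers[, 1] / dx_mm)
}

#' Fourier-plane phase of the DOE
#'
#' The phase plate equivalent to the three-lenslet Fourier microlens: inside
#' each lenslet aperture a thin-lens quadratic phase `-pi r^2 / (lambda f_ML)`
#' about the lenslet centre, wrapped to `[0, 2pi)`; the amplitude mask is zero
#' outside the apertures.
#'
#' @param cfg an `flfm_optical_config`.
#' @return list with `phase` (N x N matrix, radians in `[0, 2pi)`), `mask`
#'   (0/1 matrix), `sample_spacing_m`, and `centers_px`.
#' @export
doe_phase <- function(cfg) {
  validate_optical_config(cfg)
  n <- cfg$sensor_grid[1]
  du <- mla_sample_spacing_m(cfg)
  lam <- cfg$emission_wavelength * 1e-9
  f_ml <- cfg$lenslet_focal * 1e-3
  u <- (seq_len(n) - centre_index(n)) * du
  ux <- matrix(u, n, n, byrow = TRUE)   # x along columns
  uy <- matrix(u, n, n)                 # y along rows
  phase <- matrix(0, n, n)
  mask <- matrix(0, n, n)
  ap_r <- cfg$lenslet_pitch / 2 * 1e-3
  for (j in seq_len(cfg$lenslet_count)) {
    cx <- cfg$lenslet_centers[j, 1] * 1e-3
    cy <- cfg$lenslet_centers[j, 2] * 1e-3
    r2 <- (ux - cx)^2 + (uy - cy)^2
    inside <- r2 <= ap_r^2
    if (any(mask[inside] > 0)) stop("lenslet apertures overlap on the sample grid")
    phase[inside] <- (-pi * r2[inside] / (lam * f_ml)) %% (2 * pi)
    mask[inside] <- 1
  }
  list(phase = phase, mask = mask, sample_spacing_m = du,
       centers_px = lenslet_centers_px(cfg))
}

# high-NA defocus phase (radians) of a point emitter at axial position z_m
# on the DOE grid; zero outside the pupil. rho = radial pupil coordinate.
defocus_phase <- function(cfg, z_m, n_grid, du) {
  lam <- cfg$emission_wavelength * 1e-9
  na <- cfg$numerical_aperture
  ri <- cfg$immersion_index
  r_pupil <- pupil_radius_mm(cfg) * 1e-3
  u <- (seq_len(n_grid) - centre_index(n_grid)) * du
  ux <- matrix(u, n_grid, n_grid, byrow = TRUE)
  uy <- matrix(u, n_grid, n_grid)
  rho2 <- (ux^2 + uy^2) / r_pupil^2
  arg <- pmax(ri^2 - na^2 * rho2, 0)
  (2 * pi / lam) * z_m * sqrt(arg)
}

# worst-case phase gradient (rad/m) of the total DOE-plane phase at depth z_m
max_phase_gradient <- function(cfg, z_m) {
  lam <- cfg$emission_wavelength * 1e-9
  na <- cfg$numerical_aperture
  ri <- cfg$immersion_index
  r_pupil <- pupil_radius_mm(cfg) * 1e-3
  f_ml <- cfg$lenslet_focal * 1e-3
  radii <- sqrt(rowSums(cfg$lenslet_centers^2)) * 1e-3
  u_max <- min(max(radii) + cfg$lenslet_pitch / 2 * 1e-3, r_pupil * 0.999)
  # within a lenslet the lens + Fresnel quadratic phases combine to a linear
  # ramp with gradient 2 pi |c| / (lambda f_ML)
  g_ramp <- 2 * pi * max(radii) / (lam * f_ml)
  rho <- u_max / r_pupil
  g_def <- (2 * pi / lam) * abs(z_m) * na^2 * rho / r_pupil /
    sqrt(ri^2 - na^2 * rho^2)
  g_ramp + g_def
}

#' Predicted sub-PSF spot centres on the sensor
#'
#' Geometric prediction of each view's intensity centroid for an on-axis
#' emitter at depth `z_um`: the lenslet centre mapped 1:1 onto the sensor,
#' displaced by the parallax shift `-z NA^2 c f_ML / (R^2 sqrt(n^2 -
#' NA^2 (|c|/R)^2))` obtained by linearising the defocus phase about the
#' lenslet centre.
#'
#' @param cfg an `flfm_optical_config`.
#' @param z_um emitter depth, um.
#' @return `lenslet_count x 2` matrix of (row, col) sensor positions, px.
#' @export
psf_spot_centers <- function(cfg, z_um = 0) {
  base <- lenslet_centers_px(cfg)
  base + z_um * parallax_slope_px_per_um(cfg)
}

#' Parallax slope of each view, px per um of depth
#'
#' Geometric-optics prediction of the per-view centroid shift rate: the ray
#' parallax `-NA^2 u f_ML / (R^2 sqrt(n^2 - NA^2 (|u|/R)^2))` averaged over
#' the (uniformly filled) lenslet aperture. The average is taken over the
#' aperture rather than at its centre because the sub-PSF centroid weights
#' every pupil position equally.
#'
#' @param cfg an `flfm_optical_config`.
#' @param n_quad quadrature samples per axis over the aperture (default 61).
#' @return `lenslet_count x 2` matrix `d(row, col)/dz`.
#' @export
parallax_slope_px_per_um <- function(cfg, n_quad = 61) {
  na <- cfg$numerical_aperture
  ri <- cfg$immersion_index
  r_pupil <- pupil_radius_mm(cfg) * 1e-3
  f_ml <- cfg$lenslet_focal * 1e-3
  dx <- cfg$sensor_pixel_pitch * 1e-6
  ap_r <- cfg$lenslet_pitch / 2 * 1e-3
  cen <- cfg$lenslet_centers * 1e-3
  t <- seq(-ap_r, ap_r, length.out = n_quad)
  g <- expand.grid(x = t, y = t)
  g <- g[g$x^2 + g$y^2 <= ap_r^2, ]
  out <- matrix(0, nrow(cen), 2)
  for (j in seq_len(nrow(cen))) {
    ux <- cen[j, 1] + g$x
    uy <- cen[j, 2] + g$y
    rho2 <- (ux^2 + uy^2) / r_pupil^2
    denom <- sqrt(ri^2 - na^2 * rho2)
    scale <- -na^2 * f_ml / (r_pupil^2 * denom)  # sensor shift per unit depth
    out[j, ] <- c(mean(uy * scale), mean(ux * scale))  # (row, col)
  }
  out * 1e-6 / dx  # px per um
}

#' Simulate the FLFM point-spread function
#'
#' For each depth plane, propagates an on-axis point emitter through the
#' objective pupil (high-NA defocus phase), across the Fourier lens to the
#' DOE plane, applies the DOE amplitude and phase, and focuses to the sensor
#' with a single-FFT Fresnel transform over the lenslet focal distance. The
#' recorded intensity stack is normalised so the z = 0 plane sums to 1.
#' Because the pupil field has unit modulus inside the apertures, per-depth
#' energy on the full FFT grid is conserved exactly (Parseval); any loss is
#' view-window cropping only.
#'
#' @param cfg an `flfm_optical_config`.
#' @param view_size optional per-view crop size override (odd integer, px).
#' @return an object of class `flfm_psf` with elements `full` (depth, Y, X),
#'   `views` (depth, view, y, x), `depth_values` (um), `pixel_pitch_um`,
#'   `centers_px`, `view_size` and `config`.
#' @export
compute_psf <- function(cfg, view_size = NULL) {
  validate_optical_config(cfg)
  n <- cfg$sensor_grid[1]
  du <- mla_sample_spacing_m(cfg)
  zs <- depth_values_um(cfg)
  doe <- doe_phase(cfg)
  lam <- cfg$emission_wavelength * 1e-9
  f_ml <- cfg$lenslet_focal * 1e-3
  u <- (seq_len(n) - centre_index(n)) * du
  ux <- matrix(u, n, n, byrow = TRUE)
  uy <- matrix(u, n, n)
  fresnel <- pi * (ux^2 + uy^2) / (lam * f_ml)
  static_phase <- doe$phase + fresnel
  full <- array(0, dim = c(length(zs), n, n))
  for (iz in seq_along(zs)) {
    z_m <- zs[iz] * 1e-6
    if (max_phase_gradient(cfg, z_m) * du >= pi)
      stop(sprintf("DOE-plane sampling violates the band limit at depth %+.3f um", zs[iz]))
    field <- doe$mask * exp(1i * (defocus_phase(cfg, z_m, n, du) + static_phase))
    amp <- fftshift2(fft(ifftshift2(field)))
    full[iz, , ] <- Re(amp * Conj(amp))
  }
  iz0 <- which.min(abs(zs))
  full <- full / sum(full[iz0, , ])
  cal <- list(rotation_degrees = 0,
              view_centers = doe$centers_px,
              view_size = view_size %||% cfg$view_size %||% derive_view_size(doe$centers_px, n))
  class(cal) <- "flfm_calibration"
  psf <- list(full = full,
              views = NULL,
              depth_values = zs,
              pixel_pitch_um = cfg$sensor_pixel_pitch,
              centers_px = doe$centers_px,
              view_size = cal$view_size,
              config = cfg)
  class(psf) <- "flfm_psf"
  psf$views <- psf_views(psf, cal)
  psf
}

# largest odd per-view window keeping crops inside the sensor and disjoint
derive_view_size <- function(centers_px, n) {
  ctr <- round(centers_px)
  border <- min(pmin(ctr - 1, n - ctr))
  v <- 2 * border + 1
  if (nrow(ctr) > 1) {
    cheb <- Inf
    for (i in seq_len(nrow(ctr) - 1))
      for (j in seq.int(i + 1, nrow(ctr)))
        cheb <- min(cheb, max(abs(ctr[i, ] - ctr[j, ])))
    v <- min(v, cheb)
  }
  v <- as.integer(v)
  if (v %% 2 == 0) v <- v - 1L
  if (v < 3) stop("sensor too small to derive a per-view window")
  v
}

#' Per-view kernel bank from a full-sensor PSF
#'
#' Crops the full-sensor PSF into centre-aligned per-view kernels, one per
#' lenslet per depth, using the view centres (rounded to integer pixels) of a
#' calibration. These kernels drive per-view forward projection and
#' Richardson-Lucy deconvolution.
#'
#' @param psf an `flfm_psf`.
#' @param cal an `flfm_calibration` (e.g. [calibration_from_config()]);
#'   pixel pitch must match the PSF.
#' @return array `(depth, view, y, x)` with attributes `centers_px` and
#'   `sensor_dim`.
#' @export
psf_views <- function(psf, cal) {
  stopifnot(inherits(psf, "flfm_psf"))
  v <- cal$view_size
  half <- (v - 1) / 2
  nd <- dim(psf$full)[1]
  n <- dim(psf$full)[2]
  ctr <- round(cal$view_centers)
  nv <- nrow(ctr)
  if (any(ctr - half < 1) || any(ctr + half > n))
    stop("view crop window exceeds the sensor")
  out <- array(0, dim = c(nd, nv, v, v))
  for (j in seq_len(nv)) {
    rows <- (ctr[j, 1] - half):(ctr[j, 1] + half)
    cols <- (ctr[j, 2] - half):(ctr[j, 2] + half)
    out[, j, , ] <- psf$full[, rows, cols, drop = FALSE]
  }
  if (any(out < 0)) stop("negative PSF intensities")
  attr(out, "centers_px") <- ctr
  attr(out, "sensor_dim") <- c(n, n)
  out
}

#' Reassemble per-view kernels onto the sensor grid
#'
#' Inverse of [psf_views()]: places each per-view kernel back at its view
#' centre on a zero canvas. Pixels inside the view windows reproduce the
#' full PSF exactly; pixels outside all windows are zero.
#'
#' @param kernels array from [psf_views()].
#' @return array `(depth, Y, X)`.
#' @export
assemble_psf_views <- function(kernels) {
  ctr <- attr(kernels, "centers_px")
  nn <- attr(kernels, "sensor_dim")
  d <- dim(kernels)
  half <- (d[3] - 1) / 2
  out <- array(0, dim = c(d[1], nn[1], nn[2]))
  for (j in seq_len(d[2])) {
    rows <- (ctr[j, 1] - half):(ctr[j, 1] + half)
    cols <- (ctr[j, 2] - half):(ctr[j, 2] + half)
    out[, rows, cols] <- out[, rows, cols] + kernels[, j, , ]
  }
  out
}
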