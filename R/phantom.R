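#' Specification of a synthetic fluorescence phantom
#'
#' Seeded generators for the three ground-truth families used to train and
#' test the reconstruction: diffraction-scale beads, hollow tubes emulating
#' outer mitochondrial membranes (bright wall, dark lumen), and branching
#' filament networks emulating the endoplasmic reticulum. These stand in for
#' high-resolution confocal/Airyscan ground-truth acquisitions.
#'
#' @param kind `"beads"`, `"hollow_tubes"` or `"filament_network"`.
#' @param shape volume shape `(z, y, x)` in voxels.
#' @param voxel_size_nm `(dz, dy, dx)`, nm.
#' @param count objects to draw (beads or tubes; filaments for the network).
#' @param intensity_range per-object peak intensity range.
#' @param seed RNG seed (same seed, same volume).
#' @param margin_vox lateral margin kept free of structure, voxels.
#' @param bead_diameter_nm bead FWHM diameter (beads), nm.
#' @param min_separation_nm minimum pairwise bead separation (3D and
#'   lateral), nm; default 2.5 diameters.
#' @param outer_diameter_nm tube outer diameter range (hollow tubes), nm;
#'   default 400-1000 so the membrane walls are unresolvable in single
#'   views but resolvable at the ~180 nm reconstruction scale.
#' @param wall_nm tube wall thickness range, nm (default 80-150).
#' @param filament_sigma_nm filament Gaussian radius, nm.
#' @param persistence direction inertia of the random-walk centrelines in
#'   `[0, 1)`; higher is straighter.
#' @return an `flfm_phantom_spec`.
#' @export
phantom_spec <- function(kind = c("beads", "hollow_tubes", "filament_network"),
                         shape = c(21, 64, 64),
                         voxel_size_nm = c(350, 162.5, 162.5),
                         count = 3,
                         intensity_range = c(0.8, 1),
                         seed = 1L,
                         margin_vox = 8,
                         bead_diameter_nm = 300,
                         min_separation_nm = NULL,
                         outer_diameter_nm = c(400, 1000),
                         wall_nm = c(80, 150),
                         filament_sigma_nm = 100,
                         persistence = 0.85) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, shape = as.integer(shape),
               voxel_size_nm = voxel_size_nm, count = count,
               intensity_range = intensity_range, seed = as.integer(seed),
               margin_vox = margin_vox,
               bead_diameter_nm = bead_diameter_nm,
               min_separation_nm = min_separation_nm,
               outer_diameter_nm = outer_diameter_nm,
               wall_nm = wall_nm,
               filament_sigma_nm = filament_sigma_nm,
               persistence = persistence)
  class(spec) <- "flfm_phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$shape) == 3, all(spec$shape >= 4),
            all(spec$voxel_size_nm > 0), spec$count >= 1)
  if (spec$kind == "hollow_tubes") {
    r_min <- min(spec$outer_diameter_nm) / 2
    if (any(spec$wall_nm <= 0) || max(spec$wall_nm) >= r_min)
      stop("wall thickness must be positive and smaller than the tube radius")
    # the shell must be representable: outer radius at least one voxel
    if (r_min < max(spec$voxel_size_nm[2:3]))
      stop("tube radius below the lateral voxel size; geometry infeasible")
  }
  if (spec$kind == "beads" && spec$bead_diameter_nm <= 0)
    stop("bead diameter must be positive")
  invisible(spec)
}

#' Generate a synthetic ground-truth volume
#'
#' @param spec an `flfm_phantom_spec`.
#' @return an `flfm_volume`; nonnegative, deterministic in `spec$seed`.
#'   Hollow tubes have a strict intensity minimum along the tube axis
#'   (dark lumen) relative to the wall.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  data <- with_seed(spec$seed, switch(spec$kind,
    beads = draw_beads(spec),
    hollow_tubes = draw_tubes(spec),
    filament_network = draw_filaments(spec)
  ))
  volume(data, spec$voxel_size_nm)
}

draw_beads <- function(spec) {
  d <- spec$shape
  vol <- array(0, dim = d)
  sigma <- spec$bead_diameter_nm / 2.355  # FWHM -> sigma, nm
  min_sep <- spec$min_separation_nm %||% (2.5 * spec$bead_diameter_nm)
  centres <- matrix(0, 0, 3)
  tries <- 0
  m <- spec$margin_vox
  while (nrow(centres) < spec$count && tries < 5000) {
    tries <- tries + 1
    p <- c(runif(1, 2, d[1] - 1),
           runif(1, m, d[2] - m + 1),
           runif(1, m, d[3] - m + 1))
    p_nm <- p * spec$voxel_size_nm
    ok <- TRUE
    if (nrow(centres) > 0) {
      prev_nm <- sweep(centres, 2, spec$voxel_size_nm, "*")
      d3 <- sqrt(rowSums(sweep(prev_nm, 2, p_nm)^2))
      d2 <- sqrt(rowSums(sweep(prev_nm[, 2:3, drop = FALSE], 2, p_nm[2:3])^2))
      ok <- all(d3 > min_sep) && all(d2 > min_sep)
    }
    if (ok) centres <- rbind(centres, p)
  }
  if (nrow(centres) < spec$count)
    stop("could not place the requested beads with the required separation")
  amps <- runif(spec$count, spec$intensity_range[1], spec$intensity_range[2])
  for (i in seq_len(spec$count))
    vol <- add_gaussian_blob(vol, centres[i, ], sigma, amps[i], spec$voxel_size_nm)
  vol
}

add_gaussian_blob <- function(vol, centre_vox, sigma_nm, amp, voxel_nm) {
  d <- dim(vol)
  half <- ceiling(3 * sigma_nm / voxel_nm)
  rng <- lapply(1:3, function(a)
    max(1, floor(centre_vox[a] - half[a])):min(d[a], ceiling(centre_vox[a] + half[a])))
  g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
  dz <- (g$z - centre_vox[1]) * voxel_nm[1]
  dy <- (g$y - centre_vox[2]) * voxel_nm[2]
  dxv <- (g$x - centre_vox[3]) * voxel_nm[3]
  val <- amp * exp(-(dz^2 + dy^2 + dxv^2) / (2 * sigma_nm^2))
  idx <- cbind(g$z, g$y, g$x)
  vol[idx] <- pmax(vol[idx], val)
  vol
}

# random smooth centreline through the volume interior, voxel coordinates
random_centreline <- function(shape, margin, persistence, step_vox = 0.5,
                              n_steps = NULL) {
  lo <- c(1.5, margin, margin)
  hi <- c(shape[1] - 0.5, shape[2] - margin + 1, shape[3] - margin + 1)
  n_steps <- n_steps %||% round(2.5 * max(shape[2:3]))
  p <- runif(3, lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
  dir <- rnorm(3); dir[1] <- dir[1] * 0.25  # mostly in-plane
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(0, n_steps, 3)
  for (i in seq_len(n_steps)) {
    pts[i, ] <- p
    kick <- rnorm(3); kick[1] <- kick[1] * 0.25
    dir <- persistence * dir + (1 - persistence) * kick
    dir <- dir / sqrt(sum(dir^2))
    p_new <- p + step_vox * dir
    for (a in 1:3) {  # reflect at the walls
      if (p_new[a] < lo[a] || p_new[a] > hi[a]) {
        dir[a] <- -dir[a]
        p_new[a] <- p[a] + step_vox * dir[a]
      }
    }
    p <- p_new
  }
  pts
}

# minimum distance (nm) from voxel centres to a sampled curve, local
# neighbourhoods only; reach_nm bounds the useful distance
curve_distance_nm <- function(shape, voxel_nm, pts, reach_nm) {
  dist <- array(Inf, dim = shape)
  half <- ceiling(reach_nm / voxel_nm)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    rng <- lapply(1:3, function(a)
      max(1, floor(p[a] - half[a])):min(shape[a], ceiling(p[a] + half[a])))
    g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
    dz <- (g$z - p[1]) * voxel_nm[1]
    dy <- (g$y - p[2]) * voxel_nm[2]
    dxv <- (g$x - p[3]) * voxel_nm[3]
    dd <- sqrt(dz^2 + dy^2 + dxv^2)
    idx <- cbind(g$z, g$y, g$x)
    dist[idx] <- pmin(dist[idx], dd)
  }
  dist
}

draw_tubes <- function(spec) {
  vol <- array(0, dim = spec$shape)
  for (i in seq_len(spec$count)) {
    r_out <- runif(1, spec$outer_diameter_nm[1], spec$outer_diameter_nm[2]) / 2
    wall <- runif(1, spec$wall_nm[1], spec$wall_nm[2])
    r_mid <- r_out - wall / 2
    sigma_w <- wall / 2.355
    amp <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
    pts <- random_centreline(spec$shape, spec$margin_vox, spec$persistence)
    dist <- curve_distance_nm(spec$shape, spec$voxel_size_nm, pts,
                              r_out + 3 * sigma_w)
    shell <- amp * exp(-(dist - r_mid)^2 / (2 * sigma_w^2))
    shell[!is.finite(dist)] <- 0
    vol <- pmax(vol, shell)
  }
  vol
}

draw_filaments <- function(spec) {
  vol <- array(0, dim = spec$shape)
  sigma <- spec$filament_sigma_nm
  for (i in seq_len(spec$count)) {
    amp <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
    pts <- random_centreline(spec$shape, spec$margin_vox, spec$persistence)
    dist <- curve_distance_nm(spec$shape, spec$voxel_size_nm, pts, 3 * sigma)
    fil <- amp * exp(-dist^2 / (2 * sigma^2))
    fil[!is.finite(dist)] <- 0
    vol <- pmax(vol, fil)
  }
  vol
}

#' Resample a volume onto the FLFM reconstruction grid
#'
#' Trilinear resampling onto the instrument's depth grid (`depth_planes`
#' planes over `2 * depth_range`) and sensor-referred lateral sampling,
#' both grids centre-aligned. The result is renormalised to preserve total
#' flux. Resampling onto an identical grid returns the input unchanged.
#'
#' @param vol an `flfm_volume` with known voxel size.
#' @param cfg an `flfm_optical_config`.
#' @param lateral_size output lateral size in voxels (default: keep the
#'   physical extent of the input).
#' @param crop_z allow silently cropping an input whose axial extent
#'   exceeds the depth range (default `FALSE`: error).
#' @return an `flfm_volume` on the FLFM grid.
#' @export
resample_to_flfm <- function(vol, cfg, lateral_size = NULL, crop_z = FALSE) {
  stopifnot(inherits(vol, "flfm_volume"))
  dz_t <- 2 * cfg$depth_range * 1000 / (cfg$depth_planes - 1)
  dx_t <- lateral_sampling_nm(cfg)
  src <- vol$data
  d <- dim(src)
  lateral_size <- lateral_size %||%
    round(d[2] * vol$voxel_size_nm[2] / dx_t)
  tgt_dim <- c(cfg$depth_planes, lateral_size, lateral_size)
  tgt_vox <- c(dz_t, dx_t, dx_t)
  if (all(tgt_dim == d) && all(abs(tgt_vox - vol$voxel_size_nm) < 1e-9))
    return(vol)
  src_extent_z <- (d[1] - 1) * vol$voxel_size_nm[1]
  tgt_extent_z <- (tgt_dim[1] - 1) * dz_t
  if (src_extent_z > tgt_extent_z + dz_t && !crop_z)
    stop("source axial extent exceeds the instrument depth range; set crop_z = TRUE to crop")
  coords <- lapply(1:3, function(a) {
    (seq_len(tgt_dim[a]) - centre_index(tgt_dim[a])) * tgt_vox[a] /
      vol$voxel_size_nm[a] + centre_index(d[a])
  })
  g <- expand.grid(z = coords[[1]], y = coords[[2]], x = coords[[3]])
  out <- trilinear_sample(src, g$z, g$y, g$x)
  out <- array(out, dim = tgt_dim)
  if (sum(out) > 0) out <- out * sum(src) / sum(out)
  volume(pmax(out, 0), tgt_vox)
}

trilinear_sample <- function(arr, z, y, x) {
  d <- dim(arr)
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  val <- function(zi, yi, xi) {
    ok <- zi >= 1 & zi <= d[1] & yi >= 1 & yi <= d[2] & xi >= 1 & xi <= d[3]
    v <- numeric(length(zi))
    v[ok] <- arr[cbind(zi[ok], yi[ok], xi[ok])]
    v
  }
  (1 - fz) * ((1 - fy) * ((1 - fx) * val(z0, y0, x0) + fx * val(z0, y0, x0 + 1)) +
              fy * ((1 - fx) * val(z0, y0 + 1, x0) + fx * val(z0, y0 + 1, x0 + 1))) +
  fz * ((1 - fy) * ((1 - fx) * val(z0 + 1, y0, x0) + fx * val(z0 + 1, y0, x0 + 1)) +
        fy * ((1 - fx) * val(z0 + 1, y0 + 1, x0) + fx * val(z0 + 1, y0 + 1, x0 + 1)))
}

#' Build a training dataset of (noisy views, clean views, HR stack) triplets
#'
#' For each triplet: generates a seeded phantom on the FLFM grid, forward
#' projects it through the PSF, extracts the clean three-view stack, fits
#' noise parameters to an SNR drawn uniformly from `snr_range` (and the
#' given SBR), and corrupts the clean views. With augmentation enabled,
#' additional copies with an in-plane flip/rotation applied identically to
#' all three members are appended and marked `augmented` (flips do not
#' commute with the three-view parallax geometry, so augmented triplets are
#' excluded from physics-consistency checks).
#'
#' @param specs a `flfm_phantom_spec` or list thereof, cycled over triplets.
#'   Their `shape`/`voxel_size_nm` are overridden to the FLFM grid with
#'   lateral size `view_size`.
#' @param cfg an `flfm_optical_config`.
#' @param psf optional precomputed `flfm_psf` for `cfg`.
#' @param n_triplets number of (non-augmented) triplets.
#' @param snr_range SNR range, dB.
#' @param sbr target signal-to-background ratio.
#' @param view_size lateral size of views and HR stacks, px.
#' @param seed master seed; per-triplet seeds are derived as
#'   `seed + 7919 * i`.
#' @param augment append flipped/rotated copies.
#' @return list of class `flfm_dataset`; each element has `hr_stack`,
#'   `clean_views`, `noisy_views`, `noise`, `target_snr_db`, `augmented`,
#'   `checksum`.
#' @export
build_dataset <- function(specs, cfg, psf = NULL, n_triplets = 8,
                          snr_range = c(-2, 6), sbr = 3,
                          view_size = 64, seed = 1L, augment = FALSE) {
  if (inherits(specs, "flfm_phantom_spec")) specs <- list(specs)
  psf <- psf %||% compute_psf(cfg)
  cal <- calibration_from_config(cfg, view_size = view_size)
  dz_nm <- 2 * cfg$depth_range * 1000 / (cfg$depth_planes - 1)
  vox <- c(dz_nm, lateral_sampling_nm(cfg), lateral_sampling_nm(cfg))
  # lateral margin so parallax does not push structure out of the views
  shift <- max(abs(parallax_slope_px_per_um(cfg))) * cfg$depth_range
  margin <- ceiling(shift) + 6
  out <- list()
  snrs <- with_seed(seed, runif(n_triplets, snr_range[1], snr_range[2]))
  for (i in seq_len(n_triplets)) {
    si <- seed + 7919L * i
    sp <- specs[[(i - 1) %% length(specs) + 1]]
    sp$shape <- c(cfg$depth_planes, view_size, view_size)
    sp$voxel_size_nm <- vox
    sp$margin_vox <- max(sp$margin_vox, margin)
    sp$seed <- si
    validate_phantom_spec(sp)
    hr <- make_phantom(sp)
    clean_lf <- forward_project(hr, psf)
    clean_views <- extract_views(clean_lf, cal, provenance = "synthetic")
    np <- fit_noise_to_target(clean_views$data, snrs[i], target_sbr = sbr,
                              seed = si)
    noisy <- corrupt_lf(clean_views$data, np)
    trip <- list(hr_stack = hr,
                 clean_views = clean_views,
                 noisy_views = view_stack(noisy, provenance = "synthetic"),
                 noise = np, target_snr_db = snrs[i], augmented = FALSE)
    trip$checksum <- object_checksum(trip[c("hr_stack", "clean_views", "noisy_views")])
    out[[length(out) + 1]] <- trip
    if (augment) {
      aug <- augment_triplet(trip, choice = (i %% 3) + 1)
      aug$checksum <- object_checksum(aug[c("hr_stack", "clean_views", "noisy_views")])
      out[[length(out) + 1]] <- aug
    }
  }
  class(out) <- c("flfm_dataset", "list")
  out
}

# identical in-plane transform on all members of a triplet
augment_triplet <- function(trip, choice = 1) {
  f2 <- switch(choice,
    function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],  # vertical flip
    function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],  # horizontal flip
    function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE])  # 90 deg
  ap3 <- function(a) {
    out <- array(0, dim = dim(a))
    for (i in seq_len(dim(a)[1])) out[i, , ] <- f2(a[i, , ])
    out
  }
  trip$hr_stack$data <- ap3(trip$hr_stack$data)
  trip$clean_views$data <- ap3(trip$clean_views$data)
  trip$noisy_views$data <- ap3(trip$noisy_views$data)
  trip$augmented <- TRUE
  trip
}
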