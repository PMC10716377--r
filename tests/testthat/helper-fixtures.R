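# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code from seeded generators; no stored data.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# miniature instrument, 21 depth planes over +-3.5 um
fx_cfg <- function() fx_cached("cfg", function() mini_optical_config())

# PSF with 65-px view windows (unit tests)
fx_psf <- function() fx_cached("psf", function() compute_psf(fx_cfg(), view_size = 65))

# shallower instrument used by the learning tests: 13 planes over +-1.75 um
fx_cfg13 <- function() fx_cached("cfg13", function()
  mini_optical_config(depth_planes = 13, depth_range = 1.75))

fx_psf13 <- function() fx_cached("psf13", function()
  compute_psf(fx_cfg13(), view_size = 65))

# well-separated 3-bead phantom matched to the 65-px views of fx_psf()
fx_bead_phantom <- function() fx_cached("beads", function() {
  make_phantom(phantom_spec("beads",
    shape = c(fx_cfg()$depth_planes, 65, 65),
    voxel_size_nm = c(350, 162.5, 162.5),
    count = 3, seed = 5, margin_vox = 18, min_separation_nm = 2000))
})

# brute-force forward projection oracle: direct spatial-domain convolution
# of every voxel against the full-sensor PSF, independent of the FFT path
oracle_forward <- function(vol, psf) {
  n <- dim(psf$full)[2]
  d <- dim(vol)
  out <- matrix(0, n, n)
  ci_n <- floor(n / 2) + 1
  r_off <- ci_n - (floor(d[2] / 2) + 1)
  c_off <- ci_n - (floor(d[3] / 2) + 1)
  for (iz in seq_len(d[1])) {
    h <- psf$full[iz, , ]
    for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
      v <- vol[iz, iy, ix]
      if (v == 0) next
      # impulse at sensor position (r0, c0) shifts the (centred) kernel
      r0 <- r_off + iy - ci_n
      c0 <- c_off + ix - ci_n
      rs <- max(1, 1 + r0):min(n, n + r0)
      cs <- max(1, 1 + c0):min(n, n + c0)
      out[rs, cs] <- out[rs, cs] + v * h[rs - r0, cs - c0]
    }
  }
  out
}

# weighted centroid of an array restricted to a window around a point
local_centroid <- function(arr, centre, win = 4) {
  rng <- lapply(seq_along(dim(arr)), function(a)
    max(1, round(centre[a]) - win):min(dim(arr)[a], round(centre[a]) + win))
  sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  idx <- which(sub >= 0, arr.ind = TRUE)
  w <- as.numeric(sub)
  colSums(idx * w) / sum(w) + vapply(rng, min, numeric(1)) - 1
}

# ground-truth bead centroids of a bead phantom (kmeans on bright voxels)
bead_centroids <- function(vol, n_beads = 3) {
  m <- vol > 0.3 * max(vol)
  idx <- which(m, arr.ind = TRUE)
  km <- suppressWarnings(stats::kmeans(idx, centers = n_beads, nstart = 5))
  t(vapply(seq_len(n_beads), function(k) {
    sel <- idx[km$cluster == k, , drop = FALSE]
    colSums(sel * vol[sel]) / sum(vol[sel])
  }, numeric(3)))
}

# full-width at half maximum of a 1D profile, linear interpolation
profile_fwhm <- function(p) {
  i0 <- which.max(p)
  half <- p[i0] / 2
  left <- i0; while (left > 1 && p[left] > half) left <- left - 1
  right <- i0; while (right < length(p) && p[right] > half) right <- right + 1
  lf <- left + (half - p[left]) / (p[left + 1] - p[left])
  rf <- right - (half - p[right]) / (p[right - 1] - p[right])
  rf - lf
}
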