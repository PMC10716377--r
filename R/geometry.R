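#' Calibration derived directly from an optical configuration
#'
#' For synthetic light fields the view geometry is known exactly: rotation 0
#' and view centres at the lenslet centres mapped onto the sensor.
#'
#' @param cfg an `flfm_optical_config`.
#' @param view_size optional odd view window size, px.
#' @return an `flfm_calibration` with `rotation_degrees`, `view_centers`
#'   (3 x 2, (row, col), 1-based) and `view_size`.
#' @export
calibration_from_config <- function(cfg, view_size = NULL) {
  ctr <- lenslet_centers_px(cfg)
  vs <- view_size %||% cfg$view_size %||%
    derive_view_size(ctr, cfg$sensor_grid[1])
  if (vs %% 2 == 0)
    stop("view_size must be odd (crops are centred on a pixel)")
  cal <- list(rotation_degrees = 0,
              view_centers = canonical_view_order(ctr, cfg$sensor_grid[1]),
              view_size = vs)
  class(cal) <- "flfm_calibration"
  cal
}

# order view centres canonically: ascending angle from the +x (column) axis,
# measured about the sensor centre; ties broken by distance from the centre
canonical_view_order <- function(centers, n, rotation = 0) {
  ci <- centre_index(n)
  dy <- centers[, 1] - ci
  dxc <- centers[, 2] - ci
  ang <- (atan2(dy, dxc) * 180 / pi - rotation) %% 360
  r <- sqrt(dy^2 + dxc^2)
  centers[order(ang, r), , drop = FALSE]
}

#' Calibrate view geometry from a reference light field
#'
#' Expects a reference exposure with the three sub-apertures illuminated
#' (e.g. a uniform fluorescent slide). Thresholds at the Otsu level, labels
#' connected components, and returns the three component centroids as view
#' centres plus the in-plane rotation of the arrangement relative to the
#' canonical orientation (first lenslet at 90 degrees from the +x axis).
#' The rotation is defined modulo the 120-degree symmetry of the triple and
#' reported in (-60, 60]. Deterministic.
#'
#' @param reference_lf an `flfm_lf` or matrix.
#' @param view_size optional view window size; derived if `NULL`.
#' @return an `flfm_calibration`.
#' @export
calibrate_lf <- function(reference_lf, view_size = NULL) {
  img <- if (inherits(reference_lf, "flfm_lf")) reference_lf$data else reference_lf
  n <- nrow(img)
  th <- otsu_threshold(img)
  lab <- EBImage::bwlabel(EBImage::Image(img > th))
  k <- max(lab)
  if (k != 3)
    stop(sprintf("calibration expects 3 illuminated sub-apertures, found %d components", k))
  lab <- as.matrix(EBImage::imageData(lab))
  centers <- t(vapply(seq_len(3), function(j) {
    idx <- which(lab == j, arr.ind = TRUE)
    w <- img[idx]
    c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  }, numeric(2)))
  colnames(centers) <- c("row", "col")
  ci <- centre_index(n)
  ang <- atan2(centers[, 1] - ci, centers[, 2] - ci) * 180 / pi
  canonical <- c(90, 210, 330)
  # offset of each measured angle to the nearest canonical one, mod 120
  offs <- vapply(ang, function(a) {
    d <- (a - 90) %% 120
    if (d > 60) d - 120 else d
  }, numeric(1))
  rotation <- mean(offs)
  centers <- canonical_view_order(centers, n, rotation)
  cal <- list(rotation_degrees = rotation,
              view_centers = centers,
              view_size = view_size %||% derive_view_size(centers, n))
  class(cal) <- "flfm_calibration"
  cal
}

#' Synthetic calibration reference light field
#'
#' Draws three uniformly filled discs at the (optionally rotated) view
#' centres of a configuration — the ideal image of a constant-intensity
#' sample. Used to exercise and test [calibrate_lf()] against known ground
#' truth.
#'
#' @param cfg an `flfm_optical_config`.
#' @param rotation_degrees arrangement rotation to synthesise.
#' @param disc_radius_px disc radius; defaults to 40% of the view window.
#' @return an `flfm_lf`.
#' @export
make_reference_lf <- function(cfg, rotation_degrees = 0, disc_radius_px = NULL) {
  cal <- calibration_from_config(cfg)
  n <- cfg$sensor_grid[1]
  ci <- centre_index(n)
  th <- rotation_degrees * pi / 180
  img <- matrix(0, n, n)
  r <- disc_radius_px %||% (0.4 * cal$view_size)
  for (j in seq_len(nrow(cal$view_centers))) {
    d <- cal$view_centers[j, ] - ci
    rc <- c(cos(th) * d[1] + sin(th) * d[2],
            -sin(th) * d[1] + cos(th) * d[2]) + ci
    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    img[(rows - rc[1])^2 + (cols - rc[2])^2 <= r^2] <- 1
  }
  lf_image(img, pixel_pitch_um = cfg$sensor_pixel_pitch)
}

# view centres after removing the calibration rotation (positions on the
# derotated sensor), rounded to integer pixels for cropping
derotated_centers <- function(cal, n) {
  ci <- centre_index(n)
  th <- -cal$rotation_degrees * pi / 180
  d <- sweep(cal$view_centers, 2, c(ci, ci))
  rot <- cbind(cos(th) * d[, 1] + sin(th) * d[, 2],
               -sin(th) * d[, 1] + cos(th) * d[, 2])
  round(sweep(rot, 2, c(ci, ci), "+"))
}

#' Extract the three sub-aperture views from a light field
#'
#' Rotates the sensor image by minus the calibration rotation (bilinear,
#' zero boundary; skipped exactly at rotation 0) and crops the
#' `view_size`-square window centred on each derotated view centre.
#'
#' @param lf an `flfm_lf` or matrix.
#' @param cal an `flfm_calibration`.
#' @param provenance provenance tag for the result.
#' @return an `flfm_views` of shape `(3, view_size, view_size)`.
#' @export
extract_views <- function(lf, cal, provenance = "raw") {
  img <- if (inherits(lf, "flfm_lf")) lf$data else lf
  n <- nrow(img)
  img <- rotate_image(img, -cal$rotation_degrees)
  ctr <- derotated_centers(cal, n)
  half <- (cal$view_size - 1) / 2
  if (any(ctr - half < 1) || any(ctr[, 1] + half > nrow(img)) ||
      any(ctr[, 2] + half > ncol(img)))
    stop("view crop window out of sensor bounds")
  out <- array(0, dim = c(3, cal$view_size, cal$view_size))
  for (j in seq_len(3)) {
    out[j, , ] <- img[(ctr[j, 1] - half):(ctr[j, 1] + half),
                      (ctr[j, 2] - half):(ctr[j, 2] + half)]
  }
  view_stack(pmax(out, 0), provenance = provenance)
}

#' Place views back onto a sensor canvas
#'
#' Inverse of [extract_views()]: writes each view into its window on a zero
#' canvas (pixels outside the apertures are 0), then restores the
#' calibration rotation. Exact inverse at rotation 0.
#'
#' @param views an `flfm_views` or `(3, h, w)` array.
#' @param cal an `flfm_calibration`.
#' @param sensor_dim sensor size `(rows, cols)`.
#' @return an `flfm_lf`.
#' @export
assemble_lf <- function(views, cal, sensor_dim) {
  v <- if (inherits(views, "flfm_views")) views$data else views
  if (dim(v)[2] != cal$view_size || dim(v)[3] != cal$view_size)
    stop("view shape does not match calibration view_size")
  n <- sensor_dim[1]
  ctr <- derotated_centers(cal, n)
  half <- (cal$view_size - 1) / 2
  img <- matrix(0, n, sensor_dim[2])
  for (j in seq_len(3)) {
    img[(ctr[j, 1] - half):(ctr[j, 1] + half),
        (ctr[j, 2] - half):(ctr[j, 2] + half)] <- v[j, , ]
  }
  img <- rotate_image(img, cal$rotation_degrees)
  lf_image(pmax(img, 0))
}
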