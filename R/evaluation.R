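#' Signal-to-noise ratio of a noisy image against its reference
#'
#' `SNR = 10 * log10( sum (f - fbar)^2 / sum (fhat - f)^2 )` where `f` is
#' the reference signal, `fbar` its mean over the grid, and `fhat` the noisy
#' image. Scale-invariant: scaling both images by the same factor leaves the
#' value unchanged.
#'
#' @param reference reference image/array `f` (not constant).
#' @param noisy noisy image/array `fhat`, same shape.
#' @return SNR in dB; `Inf` if `noisy` equals `reference` exactly.
#' @export
measure_snr <- function(reference, noisy) {
  f <- if (inherits(reference, "flfm_lf")) reference$data else reference
  g <- if (inherits(noisy, "flfm_lf")) noisy$data else noisy
  if (!identical(dim(f), dim(g))) stop("shape mismatch")
  sig <- sum((f - mean(f))^2)
  if (sig == 0) stop("reference is constant; SNR undefined")
  noise <- sum((g - f)^2)
  if (noise == 0) return(Inf)
  10 * log10(sig / noise)
}

# uniform mean filter over a k-cube window, "valid" region only, for 2D or
# 3D arrays; returns the filtered array of reduced size
uniform_filter_valid <- function(x, k) {
  d <- dim(x)
  if (length(d) == 2) {
    s <- matrix(0, d[1] + 1, d[2] + 1)
    s[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
    nr <- d[1] - k + 1; nc <- d[2] - k + 1
    hi_r <- (k + 1):(d[1] + 1); hi_c <- (k + 1):(d[2] + 1)
    out <- s[hi_r, hi_c] - s[1:nr, hi_c] - s[hi_r, 1:nc] + s[1:nr, 1:nc]
    out / (k * k)
  } else {
    # 3D summed-area table via cumsum along each axis in turn
    cs <- x
    cs <- aperm(apply(cs, c(2, 3), cumsum), c(1, 2, 3))
    cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))
    cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1))
    s <- array(0, d + 1)
    s[-1, -1, -1] <- cs
    H <- lapply(d, function(n) (k + 1):(n + 1))
    L <- lapply(d, function(n) 1:(n - k + 1))
    pick <- function(i1, i2, i3) s[i1[[1]], i2[[2]], i3[[3]], drop = FALSE]
    out <- pick(H, H, H) - pick(L, H, H) - pick(H, L, H) - pick(H, H, L) +
      pick(L, L, H) + pick(L, H, L) + pick(H, L, L) - pick(L, L, L)
    out / k^3
  }
}

#' Structural similarity index
#'
#' Mean SSIM with a uniform square (2D) or cubic (3D) window, the standard
#' constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `K1 = 0.01`, `K2 = 0.03`,
#' sample (n-1) covariance normalisation, and averaging over the valid
#' (fully overlapping) window positions — the common reference formulation,
#' matched bit-for-bit against scikit-image's `structural_similarity`.
#'
#' @param a,b images or volumes of equal shape (2D matrices or 3D arrays).
#' @param data_range dynamic range `L`; default `max(a,b) - min(a,b)`.
#' @param win_size odd window side (default 7).
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = NULL, win_size = 7) {
  if (is.null(dim(a))) a <- as.matrix(a)
  if (is.null(dim(b))) b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (any(dim(a) < win_size)) stop("image smaller than the SSIM window")
  L <- data_range %||% (max(a, b) - min(a, b))
  k <- win_size
  np <- k^length(dim(a))
  cov_norm <- np / (np - 1)
  ux <- uniform_filter_valid(a, k)
  uy <- uniform_filter_valid(b, k)
  uxx <- uniform_filter_valid(a * a, k)
  uyy <- uniform_filter_valid(b * b, k)
  uxy <- uniform_filter_valid(a * b, k)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Normalised root-mean-square error
#'
#' RMSE between `pred` and the reference, normalised by the reference's
#' dynamic range (`max(ref) - min(ref)`), matching scikit-image's
#' `normalized_root_mse` with `normalization = "min-max"`.
#'
#' @param ref reference image/volume.
#' @param pred prediction, same shape.
#' @return NRMSE (>= 0).
#' @export
nrmse <- function(ref, pred) {
  if (!identical(dim(ref), dim(pred))) stop("shape mismatch")
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("reference has zero dynamic range")
  sqrt(mean((ref - pred)^2)) / rng
}

#' Resolution estimate from the radially averaged power spectrum
#'
#' Computes the 2D power spectrum, radially averages it over integer
#' frequency bins, estimates the noise floor as the median power in the
#' highest-frequency decile of bins, and reports the first frequency at
#' which the spectrum falls to within `floor_factor` times that floor.
#' Resolution is the reciprocal cutoff frequency in nm. If the spectrum
#' never reaches the floor the sampling limit (`2 * pixel_size_nm`) is
#' returned with `limited = TRUE`.
#'
#' @param image 2D matrix.
#' @param pixel_size_nm pixel size, nm.
#' @param floor_factor multiple of the noise floor treated as "reached the
#'   floor" (default 2).
#' @return list with `resolution_nm`, `cutoff_cycles_per_nm`, `limited`,
#'   and the radial `spectrum` (data frame of frequency and power).
#' @export
resolution_from_spectrum <- function(image, pixel_size_nm, floor_factor = 2) {
  stopifnot(is.matrix(image), nrow(image) >= 16)
  n <- nrow(image); m <- ncol(image)
  w <- image - mean(image)
  P <- Mod(fftshift2(fft(w)))^2
  ci <- centre_index(n); cj <- centre_index(m)
  fr <- (row(P) - ci) / n
  fc <- (col(P) - cj) / m
  rad <- sqrt(fr^2 + fc^2)          # cycles per pixel
  nb <- floor(min(n, m) / 2)
  bins <- pmin(floor(rad * min(n, m)) + 1, nb + 1)
  pw <- vapply(seq_len(nb), function(k) mean(P[bins == k]), numeric(1))
  freq <- (seq_len(nb) - 0.5) / (min(n, m) * pixel_size_nm)  # cycles/nm
  hi <- seq.int(max(1, floor(0.9 * nb)), nb)
  floor_p <- median(pw[hi])
  signal_p <- mean(pw[3:min(8, nb)])
  spectrum <- data.frame(freq_cycles_per_nm = freq, power = pw)
  # a flat spectrum (no low-frequency excess over the floor) carries no
  # resolvable structure: report the sampling limit
  if (!(signal_p > 4 * floor_p)) {
    return(list(resolution_nm = 2 * pixel_size_nm,
                cutoff_cycles_per_nm = 1 / (2 * pixel_size_nm),
                limited = TRUE, spectrum = spectrum))
  }
  # crossing threshold: a multiple of the noise floor, but never below a
  # 1e-4 fraction of the low-frequency signal power (guards against an
  # effectively zero floor in noise-free synthetic images)
  threshold <- max(floor_factor * floor_p, signal_p * 1e-4)
  below <- which(pw <= threshold)
  below <- below[below > 2]  # ignore the DC-adjacent bins
  if (length(below) == 0) {
    return(list(resolution_nm = 2 * pixel_size_nm,
                cutoff_cycles_per_nm = 1 / (2 * pixel_size_nm),
                limited = TRUE, spectrum = spectrum))
  }
  kc <- freq[min(below)]
  list(resolution_nm = 1 / kc, cutoff_cycles_per_nm = kc,
       limited = FALSE, spectrum = spectrum)
}

#' Per-voxel absolute error map
#'
#' Both inputs are normalised to `[0, 1]` using the ground truth's intensity
#' range (min subtracted, divided by the range), then the voxelwise absolute
#' difference is returned. With a shared normalisation range the map is
#' symmetric in its arguments.
#'
#' @param gt ground-truth volume/image (sets the normalisation range).
#' @param pred prediction, same shape.
#' @return array of `|gt - pred|` on the normalised scale.
#' @export
error_map <- function(gt, pred) {
  g <- if (inherits(gt, "flfm_volume")) gt$data else gt
  p <- if (inherits(pred, "flfm_volume")) pred$data else pred
  if (!identical(dim(g), dim(p))) stop("shape mismatch")
  rng <- max(g) - min(g)
  if (rng == 0) stop("ground truth has zero dynamic range")
  abs(g - p) / rng
}
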