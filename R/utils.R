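#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' fftshift / ifftshift for matrices
#'
#' Swap quadrants so the zero-frequency (or geometric centre) sample moves
#' between index 1 and index `floor(n/2)+1`.
#'
#' @param m numeric or complex matrix.
#' @return shifted matrix.
#' @keywords internal
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  r <- c(seq.int(floor(nr / 2) + 1, nr), seq_len(floor(nr / 2)))
  cc <- c(seq.int(floor(nc / 2) + 1, nc), seq_len(floor(nc / 2)))
  m[r, cc, drop = FALSE]
}

#' @rdname fftshift2
#' @keywords internal
ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  r <- c(seq.int(ceiling(nr / 2) + 1, nr), seq_len(ceiling(nr / 2)))
  cc <- c(seq.int(ceiling(nc / 2) + 1, nc), seq_len(ceiling(nc / 2)))
  m[r, cc, drop = FALSE]
}

# next power of two >= n (FFT-friendly sizes)
next_pow2 <- function(n) 2^ceiling(log2(n))

#' Linear 2D convolution via FFT, "same" output
#'
#' Zero-padded (non-circular) convolution of image `a` with kernel `k`.
#' The kernel centre is taken at `(floor(kh/2)+1, floor(kw/2)+1)` (1-based),
#' so convolving an impulse reproduces the kernel centred on the impulse.
#'
#' @param a numeric matrix (image).
#' @param k numeric matrix (kernel).
#' @return matrix of `dim(a)`.
#' @keywords internal
conv2_same <- function(a, k) {
  ha <- nrow(a); wa <- ncol(a); hk <- nrow(k); wk <- ncol(k)
  P <- next_pow2(ha + hk - 1); Q <- next_pow2(wa + wk - 1)
  A <- matrix(0, P, Q); A[seq_len(ha), seq_len(wa)] <- a
  K <- matrix(0, P, Q); K[seq_len(hk), seq_len(wk)] <- k
  full <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / (P * Q)
  r0 <- floor(hk / 2); c0 <- floor(wk / 2)
  full[r0 + seq_len(ha), c0 + seq_len(wa), drop = FALSE]
}

# centre index (1-based) of an axis of length n, matching fftshift2 convention
centre_index <- function(n) floor(n / 2) + 1

# embed a small matrix centred into an n x n zero canvas
embed_centred <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  r0 <- centre_index(nr) - centre_index(nrow(m))
  c0 <- centre_index(nc) - centre_index(ncol(m))
  stopifnot(r0 >= 0, c0 >= 0, r0 + nrow(m) <= nr, c0 + ncol(m) <= nc)
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

# crop a centred window of size (nr, nc) out of matrix m
crop_centred <- function(m, nr, nc) {
  r0 <- centre_index(nrow(m)) - centre_index(nr)
  c0 <- centre_index(ncol(m)) - centre_index(nc)
  stopifnot(r0 >= 0, c0 >= 0)
  m[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

#' Rotate an image about its centre (bilinear, zero fill)
#'
#' Inverse-mapping bilinear rotation; pixels sampled from outside the input
#' are zero. `degrees = 0` returns the input untouched (bit-exact).
#'
#' @param img numeric matrix.
#' @param degrees rotation angle, counter-clockwise in the (x up?, see
#'   details) sensor frame. Rows increase downwards; a positive angle rotates
#'   image content counter-clockwise when displayed with row 1 on top.
#' @param centre rotation centre `(row, col)`, default image centre.
#' @return rotated matrix of the same size.
#' @keywords internal
rotate_image <- function(img, degrees, centre = NULL) {
  if (degrees == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(centre)) centre <- c(centre_index(nr), centre_index(nc))
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - centre[1]; dc <- g$c - centre[2]
  # inverse map: source = R(-theta) * (dest - centre) + centre
  sr <- co * dr + si * dc + centre[1]
  sc <- -si * dr + co * dc + centre[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, nr, nc)
}

# Otsu threshold of an image or array (EBImage, histogram-based, so the
# data is flattened; scaled to [0,1] and back)
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) stop("cannot threshold a constant image")
  scaled <- matrix((as.numeric(img) - rng[1]) / diff(rng), ncol = 1)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  th * diff(rng) + rng[1]
}

# md5 of an R object via serialization to a raw connection (text-stable)
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
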