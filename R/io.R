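#' Write a volume or view stack as multi-page 32-bit TIFF
#'
#' Pages are the first array index (depth or view). Values are rescaled to
#' `[0, 1]` for storage (the TIFF writer clamps outside this range) and the
#' scale factor plus metadata are recorded in a JSON sidecar
#' `<path>.json`, so [read_volume_tiff()] restores original intensities.
#'
#' @param x 3D array `(page, y, x)` or an `flfm_volume`.
#' @param path output `.tif` path.
#' @param metadata optional named list merged into the sidecar (e.g. depth
#'   values, pixel pitch).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path, metadata = list()) {
  if (inherits(x, "flfm_volume")) {
    metadata$voxel_size_nm <- x$voxel_size_nm
    x <- x$data
  }
  stopifnot(length(dim(x)) == 3)
  mx <- max(x)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none",
                  reduce = FALSE)
  meta <- c(list(scale = scale, pages = dim(x)[1],
                 height = dim(x)[2], width = dim(x)[3]), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_volume_tiff()]
#'
#' @param path `.tif` path; the `<path>.json` sidecar is consulted when
#'   present to undo the storage rescaling.
#' @return list with `data` (3D array `(page, y, x)`) and `metadata`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  scale <- meta$scale %||% 1
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale
  list(data = arr, metadata = meta)
}

#' Write / read a single 2D light-field image as TIFF
#' @param lf an `flfm_lf` or numeric matrix.
#' @param path `.tif` path.
#' @return `path` (write) or an `flfm_lf` (read).
#' @export
write_lf_tiff <- function(lf, path) {
  m <- if (inherits(lf, "flfm_lf")) lf$data else lf
  pitch <- if (inherits(lf, "flfm_lf")) lf$pixel_pitch_um else NA_real_
  write_volume_tiff(array(m, dim = c(1, nrow(m), ncol(m))), path,
                    metadata = list(pixel_pitch_um = pitch))
}

#' @rdname write_lf_tiff
#' @export
read_lf_tiff <- function(path) {
  x <- read_volume_tiff(path)
  lf_image(x$data[1, , ], pixel_pitch_um = x$metadata$pixel_pitch_um %||% NA_real_)
}

#' Construct a light-field image object
#' @param data nonnegative numeric matrix (sensor image).
#' @param pixel_pitch_um sensor pixel pitch, um.
#' @return an `flfm_lf`.
#' @export
lf_image <- function(data, pixel_pitch_um = NA_real_) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  if (any(data < 0)) stop("light-field image must be nonnegative")
  structure(list(data = data, pixel_pitch_um = pixel_pitch_um),
            class = "flfm_lf")
}

#' Construct a volume object
#' @param data nonnegative 3D array `(z, y, x)`.
#' @param voxel_size_nm `(dz, dy, dx)` voxel size, nm.
#' @return an `flfm_volume`.
#' @export
volume <- function(data, voxel_size_nm) {
  stopifnot(length(dim(data)) == 3, length(voxel_size_nm) == 3)
  if (any(data < 0)) stop("volume intensities must be nonnegative")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "flfm_volume")
}

#' Construct a view stack
#' @param data 3D array `(view, y, x)`, exactly 3 views.
#' @param provenance one of `"raw"`, `"denoised"`, `"synthetic"`.
#' @return an `flfm_views`.
#' @export
view_stack <- function(data, provenance = "synthetic") {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != 3) stop("a view stack holds exactly 3 views")
  if (any(data < 0)) stop("view intensities must be nonnegative")
  provenance <- match.arg(provenance, c("raw", "denoised", "synthetic"))
  structure(list(data = data, provenance = provenance), class = "flfm_views")
}
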