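#' Field-grid shape of a sensor tiled into patches
#'
#' @param sensor_shape sensor resolution as `c(width, height)` in pixels
#'   (camera-spec order; default 2048 x 1536)
#' @param patch_size patch side in pixels (default 256)
#' @return integer vector `c(rows, cols)`; with the defaults `c(6, 8)`,
#'   i.e. 48 field cells per zoom state
#' @export
grid_shape <- function(sensor_shape = c(2048L, 1536L), patch_size = 256L) {
  if (patch_size <= 0) stop("patch_size must be positive")
  if (any(sensor_shape %% patch_size != 0))
    warning("patch_size does not divide the sensor; using floor division")
  c(rows = sensor_shape[2] %/% patch_size, cols = sensor_shape[1] %/% patch_size)
}

#' Build the 4D PSF dictionary
#'
#' Renders every (zoom level, field row, field col, wavelength) kernel from
#' the pupil model. With the defaults this is 48 field cells (8 x 6 grid)
#' times three wavelengths per zoom state.
#'
#' @inheritParams render_psf
#' @param sensor_shape sensor resolution `c(width, height)`
#' @param patch_size field-cell side in sensor pixels
#' @param zoom_levels magnifications at which PSFs are stored
#' @param wavelengths wavelengths to render; default the pupil model's
#' @return an object of class `psf_dictionary` holding a 6-D kernel array
#'   indexed (level, row, col, channel, ky, kx) plus metadata
#' @export
build_dictionary <- function(pupil = pupil_model(),
                             sensor_shape = c(2048L, 1536L),
                             patch_size = 256L,
                             zoom_levels = c(10, 20, 40, 60, 80, 100),
                             wavelengths = pupil$wavelengths,
                             kernel_side = 33L, n_pad = 256L,
                             pixel_um = 3.45) {
  stopifnot(length(zoom_levels) >= 1)
  gs <- grid_shape(sensor_shape, patch_size)
  nl <- length(zoom_levels); nw <- length(wavelengths)
  kernels <- array(0, unname(c(nl, gs[1], gs[2], nw, kernel_side, kernel_side)))
  energy <- array(0, unname(c(nl, gs[1], gs[2], nw)))
  for (l in seq_len(nl)) for (r in seq_len(gs[1])) for (cc in seq_len(gs[2]))
    for (w in seq_len(nw)) {
      k <- render_psf(pupil, zoom_levels[l], c(r - 1L, cc - 1L),
                      wavelengths[w], grid = gs, kernel_side = kernel_side,
                      n_pad = n_pad, pixel_um = pixel_um)
      kernels[l, r, cc, w, , ] <- k$kernel
      energy[l, r, cc, w] <- k$captured_energy
    }
  structure(list(kernels = kernels, zoom_levels = zoom_levels,
                 wavelengths = wavelengths,
                 sensor_shape = as.integer(sensor_shape),
                 patch_size = as.integer(patch_size),
                 kernel_side = as.integer(kernel_side),
                 pixel_um = pixel_um, grid = gs, energy = energy),
            class = "psf_dictionary")
}

#' @export
print.psf_dictionary <- function(x, ...) {
  cat(sprintf(paste0("4D PSF dictionary: %d zoom level(s) x %d x %d field ",
                     "cells x %d wavelength(s)\n"),
              length(x$zoom_levels), x$grid[1], x$grid[2],
              length(x$wavelengths)))
  cat(sprintf("  zoom levels: %s\n", paste(x$zoom_levels, collapse = ", ")))
  cat(sprintf("  wavelengths (um): %s\n", paste(x$wavelengths, collapse = ", ")))
  cat(sprintf("  kernel %d x %d px at %.2f um/px\n",
              x$kernel_side, x$kernel_side, x$pixel_um))
  invisible(x)
}

# Nearest stored zoom level, ties resolved toward the lower level.
nearest_level <- function(zoom_levels, beta) {
  d <- abs(zoom_levels - beta)
  cand <- which(d == min(d))
  cand[which.min(zoom_levels[cand])]
}

#' Look up the stored PSF for a sensor pixel
#'
#' Maps a 0-based sensor pixel to its field cell by half-open tiling
#' `[row*patch, (row+1)*patch)`, selects the nearest stored zoom level
#' (ties toward the lower level) and returns the stored kernel unmodified.
#' For magnifications between stored levels, re-render via the pupil model
#' rather than interpolating kernels: kernel interpolation is not
#' energy-preserving.
#'
#' @param dict a [build_dictionary()] result
#' @param beta requested magnification
#' @param pixel_rc 0-based sensor pixel `c(row, col)`
#' @param channel wavelength channel index (1-based R index)
#' @return a `psf_kernel` with lookup metadata
#' @export
psf_lookup <- function(dict, beta, pixel_rc, channel) {
  stopifnot(inherits(dict, "psf_dictionary"))
  h <- dict$sensor_shape[2]; w <- dict$sensor_shape[1]
  if (any(pixel_rc < 0) || pixel_rc[1] >= h || pixel_rc[2] >= w)
    stop("pixel outside the sensor")
  if (channel < 1 || channel > length(dict$wavelengths))
    stop("channel index out of range")
  row <- pixel_rc[1] %/% dict$patch_size
  col <- pixel_rc[2] %/% dict$patch_size
  row <- min(row, dict$grid[1] - 1L); col <- min(col, dict$grid[2] - 1L)
  lev <- nearest_level(dict$zoom_levels, beta)
  structure(list(kernel = dict$kernels[lev, row + 1L, col + 1L, channel, , ],
                 meta = list(beta = dict$zoom_levels[lev],
                             requested_beta = beta,
                             field_rc = c(row, col),
                             wavelength = dict$wavelengths[channel],
                             pixel_um = dict$pixel_um),
                 captured_energy = dict$energy[lev, row + 1L, col + 1L, channel]),
            class = "psf_kernel")
}

# Kernels for a whole field window (k x k cells) at one zoom level:
# array (ky, kx, channel, cell_row, cell_col).
psf_window <- function(dict, beta, cells_row, cells_col) {
  lev <- nearest_level(dict$zoom_levels, beta)
  nw <- length(dict$wavelengths)
  out <- array(0, c(dict$kernel_side, dict$kernel_side, nw,
                    length(cells_row), length(cells_col)))
  for (i in seq_along(cells_row)) for (j in seq_along(cells_col))
    for (w in seq_len(nw))
      out[, , w, i, j] <- dict$kernels[lev, cells_row[i] + 1L,
                                       cells_col[j] + 1L, w, , ]
  attr(out, "level_beta") <- dict$zoom_levels[lev]
  out
}

#' Radial modulation transfer function of a PSF kernel
#'
#' Magnitude of the kernel's Fourier transform, radially averaged; the
#' frequency axis is in cycles/mm derived from the image-plane sampling.
#' A unit-sum kernel has MTF(0) = 1.
#'
#' @param psf a `psf_kernel` or a unit-sum kernel matrix
#' @param pixel_um sampling interval (micrometres per pixel); taken from the
#'   kernel metadata when available
#' @return a tibble with columns `freq_cpmm` and `mtf`
#' @export
psf_mtf <- function(psf, pixel_um = NULL) {
  if (inherits(psf, "psf_kernel")) {
    if (is.null(pixel_um)) pixel_um <- psf$meta$pixel_um
    k <- psf$kernel
  } else k <- psf
  if (is.null(pixel_um)) pixel_um <- 3.45
  if (abs(sum(k) - 1) > 1e-6)
    stop("kernel is not normalized to unit sum")
  n <- nrow(k)
  otf <- Mod(fft2(k))
  ix <- c(0:((n - 1) %/% 2), -(n %/% 2):-1)  # cycles per n-pixel span
  fx <- matrix(ix, n, n, byrow = TRUE); fy <- matrix(ix, n, n)
  fr <- sqrt(fx^2 + fy^2)
  bins <- round(fr)
  mtfs <- tapply(as.vector(otf), as.vector(bins), mean)
  freqs <- as.numeric(names(mtfs)) / (n * pixel_um * 1e-3)  # cycles/mm
  tibble::tibble(freq_cpmm = freqs, mtf = as.numeric(mtfs))
}

#' Save / load a 4D PSF dictionary as an HDF5 container
#'
#' The file holds one 6-D dataset `kernels` indexed
#' (level, row, col, channel, ky, kx) plus the attributes `zoom_levels`,
#' `wavelengths`, `sensor_shape`, `patch_size` and `pixel_um`. Loading a
#' saved dictionary reproduces the kernel array bit-exactly.
#'
#' @param dict a `psf_dictionary`
#' @param path file path of the HDF5 container
#' @return `load_dictionary` returns the reconstructed `psf_dictionary`;
#'   `save_dictionary` returns `path` invisibly
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "psf_dictionary"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(dict$kernels, path, "kernels")
  rhdf5::h5write(dict$energy, path, "captured_energy")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(as.numeric(dict$zoom_levels), fid, "zoom_levels")
  rhdf5::h5writeAttribute(as.numeric(dict$wavelengths), fid, "wavelengths")
  rhdf5::h5writeAttribute(as.integer(dict$sensor_shape), fid, "sensor_shape")
  rhdf5::h5writeAttribute(as.integer(dict$patch_size), fid, "patch_size")
  rhdf5::h5writeAttribute(as.numeric(dict$pixel_um), fid, "pixel_um")
  rhdf5::h5writeAttribute(as.integer(dict$kernel_side), fid, "kernel_side")
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  att <- rhdf5::h5readAttributes(path, "/")
  for (a in c("zoom_levels", "wavelengths", "sensor_shape", "patch_size",
              "pixel_um", "kernel_side"))
    if (is.null(att[[a]]))
      stop(sprintf("malformed dictionary file: missing attribute '%s'", a))
  kernels <- rhdf5::h5read(path, "kernels")
  energy <- tryCatch(rhdf5::h5read(path, "captured_energy"),
                     error = function(e) NULL)
  gs <- grid_shape(as.integer(att$sensor_shape), as.integer(att$patch_size))
  structure(list(kernels = kernels,
                 zoom_levels = as.numeric(att$zoom_levels),
                 wavelengths = as.numeric(att$wavelengths),
                 sensor_shape = as.integer(att$sensor_shape),
                 patch_size = as.integer(att$patch_size),
                 kernel_side = as.integer(att$kernel_side),
                 pixel_um = as.numeric(att$pixel_um),
                 grid = gs, energy = energy),
            class = "psf_dictionary")
}

#' Export a single dictionary kernel as a float TIFF for inspection
#'
#' @param dict a `psf_dictionary`
#' @param level,row,col,channel 1-based indices into the dictionary
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
export_kernel_tiff <- function(dict, level, row, col, channel, path) {
  k <- dict$kernels[level, row, col, channel, , ]
  tiff::writeTIFF(k / max(k), path, bits.per.sample = 32L)
  invisible(path)
}
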