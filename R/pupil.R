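#' Parametric Zernike pupil model of the zoom objective
#'
#' A stand-in for ray-traced optical simulation: the system's point spread
#' function at a given magnification, field position and wavelength is
#' rendered from a circular pupil carrying a Zernike aberration phase whose
#' coefficients vary smoothly with normalized field radius, field azimuth
#' and magnification. The model reproduces the qualitative structure of a
#' zoom objective's aberrations -- defocus and astigmatism growing with the
#' square of the field radius, coma linearly, spherical aberration constant
#' over the field, all scaled by a per-magnification severity factor -- and
#' a per-wavelength chromatic defocus offset.
#'
#' All Zernike coefficients are in waves (Noll indices Z4 defocus, Z5/Z6
#' astigmatism, Z7/Z8 coma, Z11 spherical).
#'
#' @param na_of_beta function mapping magnification to the effective
#'   image-side numerical aperture; must return values in (0, 1.1]
#' @param zernike_base named numeric vector of base coefficient amplitudes
#'   (waves) for `defocus`, `astig`, `coma`, `spherical`
#' @param severity_of_beta function mapping magnification to the
#'   dimensionless aberration severity multiplier
#' @param chromatic_defocus per-wavelength defocus offsets (waves), same
#'   length and order as `wavelengths`
#' @param wavelengths wavelengths in micrometres; the default three are the
#'   F, d and C spectral lines mapped to the blue, green and red channels
#' @return an object of class `pupil_model`
#' @examples
#' pm <- pupil_model()
#' k <- render_psf(pm, beta = 60, field_rc = c(0, 0), wavelength = 0.588)
#' sum(k$kernel)  # 1
#' @export
pupil_model <- function(na_of_beta = function(beta)
                          0.03 + 0.02 * pmin(pmax(log(beta / 10) / log(10), 0), 1),
                        zernike_base = c(defocus = 0.45, astig = 0.35,
                                         coma = 0.30, spherical = 0.15),
                        severity_of_beta = function(beta)
                          0.4 + 0.8 * pmin(pmax(log(beta / 10) / log(10), 0), 1),
                        chromatic_defocus = c(0.25, 0, -0.25),
                        wavelengths = c(0.486, 0.588, 0.656)) {
  stopifnot(is.function(na_of_beta), is.function(severity_of_beta),
            length(chromatic_defocus) == length(wavelengths),
            all(wavelengths > 0))
  need <- c("defocus", "astig", "coma", "spherical")
  stopifnot(all(need %in% names(zernike_base)))
  structure(list(na_of_beta = na_of_beta, zernike_base = zernike_base,
                 severity_of_beta = severity_of_beta,
                 chromatic_defocus = chromatic_defocus,
                 wavelengths = wavelengths),
            class = "pupil_model")
}

# Cache of pupil-grid geometry (coordinates, mask, Zernike basis) keyed by
# (pupil radius in px, embedding size).
.pupil_cache <- new.env(parent = emptyenv())

pupil_geometry <- function(radius_px, n_pad) {
  key <- sprintf("%.4f_%d", radius_px, n_pad)
  g <- .pupil_cache[[key]]
  if (!is.null(g)) return(g)
  ix <- c(0:(n_pad / 2 - 1), -(n_pad / 2):-1)  # FFT-ordered coordinates
  fx <- matrix(ix, n_pad, n_pad, byrow = TRUE) / radius_px
  fy <- matrix(ix, n_pad, n_pad) / radius_px
  rho2 <- fx^2 + fy^2
  mask <- rho2 <= 1
  rho <- sqrt(rho2)
  th <- atan2(fy, fx)
  idx <- which(mask)
  rho2 <- rho2[idx]; rho <- rho[idx]; th <- th[idx]
  # Zernike basis evaluated on the pupil samples only
  g <- list(
    mask = mask, idx = idx,
    z4 = sqrt(3) * (2 * rho2 - 1),
    z5 = sqrt(6) * rho2 * sin(2 * th),
    z6 = sqrt(6) * rho2 * cos(2 * th),
    z7 = sqrt(8) * (3 * rho^3 - 2 * rho) * sin(th),
    z8 = sqrt(8) * (3 * rho^3 - 2 * rho) * cos(th),
    z11 = sqrt(5) * (6 * rho2^2 - 6 * rho2 + 1))
  .pupil_cache[[key]] <- g
  g
}

# Zernike coefficients (waves) for a field position and magnification.
# r in [0,1] is the normalized field radius, phi the field azimuth.
zernike_coeffs <- function(pupil, beta, r, phi, wl_index) {
  sev <- pupil$severity_of_beta(beta)
  zb <- pupil$zernike_base
  r <- unname(r); phi <- unname(phi)
  stats::setNames(
    as.numeric(c(zb["defocus"] * r^2 * sev + pupil$chromatic_defocus[wl_index],
                 zb["astig"] * r^2 * sin(2 * phi) * sev,
                 zb["astig"] * r^2 * cos(2 * phi) * sev,
                 zb["coma"] * r * sin(phi) * sev,
                 zb["coma"] * r * cos(phi) * sev,
                 zb["spherical"] * sev)),
    c("z4", "z5", "z6", "z7", "z8", "z11"))
}

# Complex pupil field embedded in an n_pad x n_pad FFT grid (DC-cornered).
# Returned invisibly by render_psf consumers that need the raw samples
# (e.g. a direct-DFT cross-check).
pupil_field <- function(pupil, beta, field_rc, wavelength,
                        grid = c(6L, 8L), n_pad = 256L,
                        pixel_um = 3.45, coeffs = NULL) {
  na <- pupil$na_of_beta(beta)
  if (!(na > 0 && na <= 1.1)) stop("numerical aperture out of range (0, 1.1]")
  wl_index <- match(wavelength, pupil$wavelengths)
  if (is.na(wl_index)) stop("wavelength not in the pupil model")
  radius_px <- na / wavelength * n_pad * pixel_um
  if (radius_px < 3 || radius_px > n_pad / 2 - 1)
    stop(sprintf(paste0("pupil radius %.1f px outside simulation grid; ",
                        "adjust NA, wavelength or embedding size"), radius_px))
  # normalized field coordinates of the cell center: corner cells ~ r = 1
  cy <- (field_rc[1] + 0.5) / grid[1] * 2 - 1
  cx <- (field_rc[2] + 0.5) / grid[2] * 2 - 1
  r <- sqrt(cx^2 + cy^2) / sqrt(2)
  phi <- atan2(cy, cx)
  if (is.null(coeffs)) coeffs <- zernike_coeffs(pupil, beta, r, phi, wl_index)
  g <- pupil_geometry(radius_px, n_pad)
  W <- coeffs["z4"] * g$z4 + coeffs["z5"] * g$z5 + coeffs["z6"] * g$z6 +
    coeffs["z7"] * g$z7 + coeffs["z8"] * g$z8 + coeffs["z11"] * g$z11
  P <- matrix(0i, n_pad, n_pad)
  P[g$idx] <- exp(2i * pi * W)
  attr(P, "coeffs") <- coeffs
  P
}

fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  hn <- (n + 1L) %/% 2L; hm <- (m + 1L) %/% 2L
  x[c((hn + 1L):n, 1:hn), c((hm + 1L):m, 1:hm)]
}

#' Render one point spread function from the pupil model
#'
#' Evaluates the Zernike phase on a circular pupil grid, forms the intensity
#' PSF as the squared modulus of the pupil's Fourier transform, crops the
#' central `kernel_side` pixels and normalizes to unit sum. The image-plane
#' sampling is `pixel_um` micrometres per pixel (default 3.45, the sensor
#' pitch), which fixes the pupil radius in frequency samples as
#' `NA / lambda * n_pad * pixel_um`.
#'
#' @param pupil a [pupil_model()]
#' @param beta system magnification
#' @param field_rc 0-based field-cell indices `c(row, col)` in the field grid
#' @param wavelength one of the model's wavelengths (micrometres)
#' @param grid field-grid shape `c(rows, cols)`; default the 6 x 8 sensor
#'   tiling
#' @param kernel_side odd kernel support in pixels (default 33)
#' @param n_pad pupil embedding size for the FFT (default 256)
#' @param pixel_um image-plane sampling interval (micrometres per pixel)
#' @return an object of class `psf_kernel`: list with the unit-sum `kernel`
#'   matrix, `meta` (beta, field indices, wavelength), and the pre-crop
#'   `captured_energy` fraction
#' @export
render_psf <- function(pupil, beta, field_rc, wavelength,
                       grid = c(6L, 8L), kernel_side = 33L, n_pad = 256L,
                       pixel_um = 3.45) {
  stopifnot(is_odd(kernel_side), kernel_side < n_pad)
  if (any(field_rc < 0) || field_rc[1] >= grid[1] || field_rc[2] >= grid[2])
    stop("field indices outside the field grid")
  P <- pupil_field(pupil, beta, field_rc, wavelength, grid, n_pad, pixel_um)
  A <- fft2(P)
  psf <- fftshift2(Re(A)^2 + Im(A)^2)
  c0 <- n_pad / 2 + 1
  h <- (kernel_side - 1L) %/% 2L
  crop <- psf[(c0 - h):(c0 + h), (c0 - h):(c0 + h)]
  energy <- sum(crop) / sum(psf)
  structure(list(kernel = crop / sum(crop),
                 meta = list(beta = beta, field_rc = as.integer(field_rc),
                             wavelength = wavelength, pixel_um = pixel_um,
                             coeffs = attr(P, "coeffs")),
                 captured_energy = energy),
            class = "psf_kernel")
}
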