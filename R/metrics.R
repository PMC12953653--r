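#' Peak signal-to-noise ratio
#'
#' `10 log10(max_val^2 / MSE)`. Identical images (MSE = 0) report the
#' capped sentinel 100 dB.
#'
#' @param a,b images of equal shape
#' @param max_val peak value of the representation (1 for [0,1] images,
#'   255 for 8-bit)
#' @return PSNR in dB
#' @export
psnr <- function(a, b, max_val = 1) {
  stopifnot(all(dim(as.array(a)) == dim(as.array(b))))
  mse <- mean((a - b)^2)
  if (mse == 0) return(100)
  min(10 * log10(max_val^2 / mse), 100)
}

#' Single-scale structural similarity (SSIM)
#'
#' Standard formulation with the 11x11 Gaussian window (sigma 1.5) and
#' constants C1 = 0.01^2, C2 = 0.03^2 on the [0,1] scale.
#'
#' @param a,b images in [0,1] of equal shape
#' @return mean SSIM over the image
#' @export
ssim <- function(a, b) {
  a <- as.array(a); b <- as.array(b)
  if (length(dim(a)) == 2L) { a <- array(a, c(dim(a), 1L)); b <- array(b, c(dim(b), 1L)) }
  stopifnot(all(dim(a) == dim(b)))
  ag_value(ssim_terms(a, b)$map_mean)
}
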