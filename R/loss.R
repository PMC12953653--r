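# --- physics-constrained composite loss ------------------------------------

#' Physics-consistency loss
#'
#' Mean squared error between the re-degraded restoration --- the restored
#' image pushed through the identical spatially-variant patch convolution
#' and 2x2 area downsampling used by the forward model --- and the observed
#' degraded input. Penalizing this residual suppresses non-physical
#' artifacts: any content the restoration invents must still re-degrade to
#' the observation.
#'
#' @param x_hat restored image (2N x 2N x C), array or autodiff node
#' @param psf_set kernel array (k, k, C, tiles_r, tiles_c); use the
#'   CALW-corrected set ([calw_corrected_kernels()]) during training
#' @param y observed degraded image (N x N x C)
#' @param tile tile side of the GT patch grid (defaults to x_hat side /
#'   number of tiles)
#' @return scalar (or scalar node)
#' @export
physics_loss <- function(x_hat, psf_set, y, tile = NULL) {
  dx <- dim(ag_value(x_hat)); dy <- dim(y)
  if (!all(dx[1:2] == 2L * dy[1:2]))
    stop("restored image must be twice the degraded image size")
  dk <- dim(psf_set)
  if (is.null(tile)) tile <- dx[1] %/% dk[4]
  if (tile * dk[4] != dx[1] || (dx[2] %/% dk[5]) * dk[5] != dx[2])
    stop("patch grid of the PSF set does not tile the restored image")
  blur <- patch_convolve(x_hat, psf_set, tile)
  down <- ag_area_down2(blur)
  ag_mean(ag_pow(ag_sub(down, y), 2))
}

# 11-tap 1-D Gaussian (sigma 1.5); the separable SSIM window
ssim_window_1d <- function() {
  g <- stats::dnorm(seq(-5, 5), 0, 1.5)
  g / sum(g)
}

# depthwise same-padded convolution of every channel by the SSIM window
blur_fixed <- function(x, w1d) ag_sepconv_fixed(x, w1d)

# single-scale SSIM statistics; returns list(l = luminance term mean,
# cs = contrast-structure term mean, map_mean = mean full SSIM)
ssim_terms <- function(a, b, C1 = 0.01^2, C2 = 0.03^2) {
  w <- ssim_window_1d()
  mu_a <- blur_fixed(a, w); mu_b <- blur_fixed(b, w)
  mu_aa <- ag_mul(mu_a, mu_a); mu_bb <- ag_mul(mu_b, mu_b)
  mu_ab <- ag_mul(mu_a, mu_b)
  s_aa <- ag_sub(blur_fixed(ag_mul(a, a), w), mu_aa)
  s_bb <- ag_sub(blur_fixed(ag_mul(b, b), w), mu_bb)
  s_ab <- ag_sub(blur_fixed(ag_mul(a, b), w), mu_ab)
  l_num <- ag_add(ag_mul(mu_ab, 2), C1)
  l_den <- ag_add(ag_add(mu_aa, mu_bb), C1)
  cs_num <- ag_add(ag_mul(s_ab, 2), C2)
  cs_den <- ag_add(ag_add(s_aa, s_bb), C2)
  lmap <- ag_div(l_num, l_den)
  csmap <- ag_div(cs_num, cs_den)
  list(l = ag_mean(lmap), cs = ag_mean(csmap),
       map_mean = ag_mean(ag_mul(lmap, csmap)))
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Standard construction: contrast-structure terms at each scale of a 2x
#' area-downsampling pyramid, luminance at the coarsest, combined with the
#' standard weights (renormalized when fewer than five levels are used).
#' Differentiable; accepts plain arrays or autodiff nodes.
#'
#' @param a,b images in [0,1] of equal shape (H x W x C)
#' @param levels number of scales (default 5; the image must be at least
#'   `11 * 2^(levels-1)` pixels on each side)
#' @return scalar in [0, 1] (or scalar node)
#' @export
ms_ssim <- function(a, b, levels = 5L) {
  da <- dim(ag_value(a))
  stopifnot(all(da == dim(ag_value(b))))
  if (min(da[1:2]) < 11L * 2L^(levels - 1L))
    stop("image too small for the requested MS-SSIM pyramid")
  wts <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(levels)]
  wts <- wts / sum(wts)
  out <- NULL
  for (l in seq_len(levels)) {
    st <- ssim_terms(a, b)
    term <- if (l == levels) ag_mul(st$l, st$cs) else st$cs
    # clamp to positive before the fractional power
    term <- ag_add(ag_relu(term), 1e-8)
    contrib <- ag_pow(term, wts[l])
    out <- if (is.null(out)) contrib else ag_mul(out, contrib)
    if (l < levels) { a <- ag_area_down2(a); b <- ag_area_down2(b) }
  }
  out
}

#' Anisotropic total variation
#'
#' Sum of absolute horizontal and vertical first differences divided by the
#' pixel count (H*W*C).
#'
#' @param x image array or node
#' @return scalar (or node), >= 0
#' @export
tv_loss <- function(x) {
  d <- dim(ag_value(x))
  dx <- ag_sub(ag_crop(x, seq_len(d[1]), 2:d[2]),
               ag_crop(x, seq_len(d[1]), seq_len(d[2] - 1L)))
  dy <- ag_sub(ag_crop(x, 2:d[1], seq_len(d[2])),
               ag_crop(x, seq_len(d[1] - 1L), seq_len(d[2])))
  ag_mul(ag_add(ag_sum(ag_abs(dx)), ag_sum(ag_abs(dy))), 1 / prod(d))
}

#' Loss weights of the physics-constrained composite loss
#'
#' @param w_fid GT-fidelity MSE weight
#' @param w_phys physics re-degradation MSE weight
#' @param w_ssim (1 - MS-SSIM) weight
#' @param w_tv total-variation weight
#' @return a `loss_weights` list
#' @export
loss_weights <- function(w_fid = 1, w_phys = 0.5, w_ssim = 0.15, w_tv = 1e-4) {
  w <- c(w_fid = w_fid, w_phys = w_phys, w_ssim = w_ssim, w_tv = w_tv)
  if (any(w < 0)) stop("loss weights must be non-negative")
  if (all(w == 0)) stop("at least one loss weight must be positive")
  structure(as.list(w), class = "loss_weights")
}

#' Composite physics-constrained training loss
#'
#' `w_fid * MSE(x_hat, gt) + w_phys * physics_loss(x_hat, psf_set, y) +
#'  w_ssim * (1 - MS_SSIM(x_hat, gt)) + w_tv * TV(x_hat)`.
#'
#' @param x_hat restored image (node during training)
#' @param gt ground truth of the same shape
#' @param y degraded input (half resolution)
#' @param psf_set kernel set for the physics term
#' @param weights a [loss_weights()]
#' @param ssim_levels MS-SSIM pyramid depth (reduce for small images)
#' @return scalar (or node) with attribute `breakdown`: named numeric of
#'   the four unweighted term values
#' @export
total_loss <- function(x_hat, gt, y, psf_set, weights = loss_weights(),
                       ssim_levels = 5L) {
  stopifnot(inherits(weights, "loss_weights"))
  fid <- ag_mean(ag_pow(ag_sub(x_hat, gt), 2))
  phys <- if (weights$w_phys > 0) physics_loss(x_hat, psf_set, y) else 0
  ssim_term <- if (weights$w_ssim > 0)
    ag_sub(1, ms_ssim(x_hat, gt, levels = ssim_levels)) else 0
  tv <- if (weights$w_tv > 0) tv_loss(x_hat) else 0
  total <- ag_add(ag_add(ag_mul(fid, weights$w_fid),
                         ag_mul(phys, weights$w_phys)),
                  ag_add(ag_mul(ssim_term, weights$w_ssim),
                         ag_mul(tv, weights$w_tv)))
  breakdown <- c(fid = ag_value(fid), phys = ag_value(phys),
                 ssim = ag_value(ssim_term), tv = ag_value(tv))
  if (is_node(total)) total$breakdown <- breakdown
  else attr(total, "breakdown") <- breakdown
  total
}
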