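# --- Content-Adaptive Learnable Wiener (CALW) front end --------------------
#
# Closed-form channel-wise Wiener deconvolution, diagonalized in the Fourier
# domain:
#
#   xhat_c = F^H [ conj(D_K) F y_c / (|D_K|^2 + e^{alpha_c} sum_d |D_Gd|^2) ]
#
# with three learnable ingredients: a bounded multiplicative correction of
# the PSF spectrum (manufacturing tolerances make tabulated PSFs slightly
# wrong), a content-adaptive bank of D regularization kernels predicted
# from the degraded image, and an independent log-strength alpha_c per
# color channel.

#' The fixed base regularization kernel bank
#'
#' Eight 3x3 kernels: first derivatives along x and y, the Laplacian, four
#' oriented second derivatives (x, y and both diagonals), and
#' identity-minus-mean. All are zero-mean, so the bank leaves the DC
#' component of the restoration untouched.
#'
#' @return array (3, 3, 8)
#' @export
base_reg_bank <- function() {
  b <- array(0, c(3, 3, 8))
  b[2, 1:2, 1] <- c(-1, 1)                           # d/dx
  b[1:2, 2, 2] <- c(-1, 1)                           # d/dy
  b[, , 3] <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3)  # Laplacian
  b[2, , 4] <- c(1, -2, 1)                           # d2/dx2
  b[, 2, 5] <- c(1, -2, 1)                           # d2/dy2
  b[cbind(1:3, 1:3, 6)] <- c(1, -2, 1) * 0.5         # diagonal
  b[cbind(1:3, 3:1, 7)] <- c(1, -2, 1) * 0.5         # anti-diagonal
  b[, , 8] <- -1 / 9; b[2, 2, 8] <- 1 - 1 / 9        # identity - mean
  b
}

#' Initialize CALW parameters
#'
#' The regularization-kernel predictor and the PSF-spectrum correction are
#' both identity-initialized: their output heads start at zero, so at
#' initialization the predicted bank equals [base_reg_bank()] exactly and
#' the corrected spectrum equals the input spectrum exactly.
#'
#' @param n_reg number of regularization kernels D (default 8)
#' @param alpha_init initial per-channel log-strength (default `log(1e-3)`,
#'   a weak prior regularization)
#' @param seed seed for the encoder weights
#' @return named list of parameter arrays
#' @export
calw_init <- function(n_reg = 8L, alpha_init = log(1e-3), seed = 1L) {
  with_seed(seed, list(
    alpha = rep(alpha_init, 3),
    # reg-kernel predictor: shallow encoder on the RGB input, zero-init head
    pk_conv_w = array(stats::rnorm(3 * 3 * 3 * 8, 0, sqrt(2 / (9 * 3))),
                      c(3, 3, 3, 8)),
    pk_conv_b = rep(0, 8),
    pk_lin_w = matrix(0, 8, n_reg * 9L),
    pk_lin_b = rep(0, n_reg * 9L),
    # spectrum correction: pointwise map on stacked (re, im), zero-init head
    sc_w1 = array(stats::rnorm(2 * 8, 0, sqrt(2 / 2)), c(1, 1, 2, 8)),
    sc_b1 = rep(0, 8),
    sc_w2 = array(0, c(1, 1, 8, 2)),
    sc_b2 = rep(0, 2)))
}

# extract element i of a parameter vector as a scalar node
ag_index <- function(v, i) {
  vv <- ag_value(v)
  ag_op(vv[i], list(v), list(function(g) {
    out <- numeric(length(vv)); out[i] <- g; out
  }))
}

#' Predict the content-adaptive regularization kernel bank
#'
#' Base bank plus a learned residual: a shallow convolutional encoder over
#' the degraded RGB image is average-pooled and mapped linearly (zero-
#' initialized) to per-kernel residuals. With a zero-initialized head the
#' output equals the base bank exactly.
#'
#' @param y degraded RGB image (H x W x 3), plain array
#' @param params CALW parameter list (plain arrays or autodiff nodes)
#' @param n_reg number of kernels D
#' @return array or node of shape (3, 3, D)
#' @export
predict_reg_kernels <- function(y, params, n_reg = 8L) {
  h <- ag_relu(ag_conv2d(y, params$pk_conv_w, params$pk_conv_b))
  p <- ag_gmean_c(h)                                  # length 8
  res <- ag_add(ag_matmul(ag_reshape(p, c(1L, 8L)), params$pk_lin_w),
                ag_reshape(params$pk_lin_b, c(1L, n_reg * 9L)))
  base <- base_reg_bank()[, , seq_len(n_reg), drop = FALSE]
  ag_add(ag_reshape(res, c(3L, 3L, n_reg)), base)
}

#' Bounded learnable correction of a PSF spectrum
#'
#' `corrected = otf * (1 + g(otf))` where `g` is a pointwise two-layer map
#' on the stacked real/imaginary planes with a zero-initialized, tanh-
#' bounded output (each plane scaled by 0.35, so `|g| <= 0.5` and the DC
#' magnitude stays within [0.5, 2] by construction). At initialization the
#' corrected spectrum equals the input exactly.
#'
#' @param otf complex matrix (transfer function on the image grid)
#' @param params CALW parameter list
#' @return list with `re` and `im` (arrays or nodes, H x W)
#' @export
optimize_psf_spectrum <- function(otf, params) {
  n1 <- nrow(otf); n2 <- ncol(otf)
  stacked <- array(0, c(n1, n2, 2))
  stacked[, , 1] <- Re(otf); stacked[, , 2] <- Im(otf)
  h <- ag_relu(ag_conv2d(stacked, params$sc_w1, params$sc_b1))
  res <- ag_conv2d(h, params$sc_w2, params$sc_b2)
  gre <- ag_mul(ag_tanh(ag_slice_c(res, 1L)), 0.35)
  gim <- ag_mul(ag_tanh(ag_slice_c(res, 2L)), 0.35)
  ore <- array(Re(otf), c(n1, n2, 1)); oim <- array(Im(otf), c(n1, n2, 1))
  # otf * (1 + gre + i gim), split into planes
  re <- ag_sub(ag_add(ore, ag_mul(ore, gre)), ag_mul(oim, gim))
  im <- ag_add(ag_add(oim, ag_mul(oim, gre)), ag_mul(ore, gim))
  list(re = ag_reshape(re, c(n1, n2)), im = ag_reshape(im, c(n1, n2)))
}

#' Channel-wise Wiener deconvolution (closed form)
#'
#' Direct evaluation of the Wiener filter for one channel with a given
#' kernel, regularization bank and log-strength alpha, under the circular
#' convolution convention.
#'
#' @param y degraded channel image (matrix)
#' @param kernel blur kernel (odd side, unit sum recommended)
#' @param reg_bank regularization kernels, array (k, k, D)
#' @param alpha log-strength of the regularization
#' @return restored channel image (matrix)
#' @export
wiener_deconvolve <- function(y, kernel, reg_bank, alpha) {
  otf <- kernel_otf(kernel, dim(y))
  ag_value(ag_wiener(y, Re(otf), Im(otf), reg_bank, alpha))
}

#' CALW forward pass: initial restoration at input resolution
#'
#' Per channel: embed the channel's PSF on the (mirror-padded) image grid,
#' apply the learnable spectrum correction, and Wiener-deconvolve with the
#' content-predicted regularization bank and the channel's alpha_c. The
#' 16-px mirrored pre-padding suppresses wrap-around ringing of the
#' circular convolution convention; the result is center-cropped back.
#'
#' @param y degraded RGB image (H x W x 3), plain array in [0,1]
#' @param kernels per-channel PSF kernels, array (k, k, 3)
#' @param params CALW parameter list (arrays, or nodes during training)
#' @param pad mirrored pre-padding in pixels
#' @param reg_bank optional fixed regularization bank overriding the
#'   content-adaptive prediction (diagnostics)
#' @return restored RGB image at input resolution (array or node)
#' @export
calw_forward <- function(y, kernels, params, pad = 16L, reg_bank = NULL) {
  d <- dim(y)
  stopifnot(length(d) == 3L, d[3] == dim(kernels)[3])
  G <- if (is.null(reg_bank))
    predict_reg_kernels(y, params, n_reg = length(ag_value(params$pk_lin_b)) %/% 9L)
  else reg_bank
  yp <- map_channels(y, function(m) pad_reflect_mat(m, pad))
  chans <- vector("list", d[3])
  for (ch in seq_len(d[3])) {
    otf0 <- kernel_otf(kernels[, , ch], dim(yp)[1:2])
    corr <- optimize_psf_spectrum(otf0, params)
    xch <- ag_wiener(yp[, , ch], corr$re, corr$im, G,
                     ag_index(params$alpha, ch))
    chans[[ch]] <- ag_reshape(xch, c(dim(yp)[1], dim(yp)[2], 1L))
  }
  out <- ag_concat_c(chans)
  ag_crop(out, pad + seq_len(d[1]), pad + seq_len(d[2]))
}

#' Corrected PSF kernel set for the physics-consistency loss
#'
#' Applies the learned spectrum correction to each kernel of a sample's PSF
#' set on the kernel's own support and renormalizes to unit sum. Values are
#' detached from the autodiff tape: the physics term steers the restored
#' image, not the correction itself.
#'
#' @param psf_set kernel array (k, k, C, tiles_r, tiles_c)
#' @param params CALW parameter list
#' @return corrected kernel array of the same shape
#' @export
calw_corrected_kernels <- function(psf_set, params) {
  dk <- dim(psf_set)
  out <- array(0, dk)
  pl <- lapply(params, ag_value)
  for (i in seq_len(dk[4])) for (j in seq_len(dk[5])) for (ch in seq_len(dk[3])) {
    k <- psf_set[, , ch, i, j]
    otf <- kernel_otf(k, c(dk[1], dk[2]))
    corr <- optimize_psf_spectrum(otf, pl)
    cotf <- ag_value(corr$re) + 1i * ag_value(corr$im)
    kc <- Re(ifft2(cotf))
    # gather back to centered support and renormalize
    kc <- fftshift2(kc)
    kc <- pmax(kc, 0)
    if (sum(kc) > 0) kc <- kc / sum(kc) else kc <- k
    out[, , ch, i, j] <- kc
  }
  attr(out, "level_beta") <- attr(psf_set, "level_beta")
  out
}
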