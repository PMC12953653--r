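# --- Degradation-guided restoration network --------------------------------
#
# Encoder-decoder of degradation-guided transformer (DGT) blocks at three
# scales, each block = layernorm -> degradation-guided multi-head channel
# attention (DGMSA) -> layernorm -> gated feed-forward, with residual
# connections. Physical Degradation Feature Fusion (PDFF) injects the PSF's
# transfer-function magnitude into the features at every scale; the fused
# features condition the attention keys. The head is a sub-pixel x2
# upsampler with a global residual from the bilinear-upsampled CALW output.

#' Network size profile
#'
#' @param profile `"tiny"` (CPU-trainable, < 300k parameters) or `"base"`
#' @return a `network_config` list: channels, attention heads and block
#'   counts per scale, feed-forward expansion, and the fixed x2 upsampling
#'   factor (256 px inputs pair with 512 px ground truth)
#' @export
network_config <- function(profile = c("tiny", "base")) {
  profile <- match.arg(profile)
  cfg <- if (profile == "tiny")
    list(channels = c(16L, 32L, 64L), heads = c(1L, 2L, 4L),
         blocks_enc = c(1L, 1L, 1L), blocks_dec = c(1L, 1L))
  else
    list(channels = c(48L, 96L, 192L), heads = c(2L, 4L, 8L),
         blocks_enc = c(2L, 3L, 3L), blocks_dec = c(3L, 3L))
  cfg$profile <- profile
  cfg$expansion <- 2
  cfg$upsample <- 2L
  stopifnot(all(cfg$channels %% cfg$heads == 0L))
  structure(cfg, class = "network_config")
}

he_w <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

dgt_block_init <- function(C, heads, expansion) {
  h <- as.integer(round(expansion * C))
  list(ln1_g = rep(1, C), ln1_b = rep(0, C),
       w_qkv = he_w(c(C, 3L * C), C),
       w_proj = he_w(c(C, C), C) * 0.5,
       tau = rep(1, heads),
       gd_scale = matrix(0, C, C),   # zero-init guidance: reduces to plain attention
       gd_bias = matrix(0, C, C),
       ln2_g = rep(1, C), ln2_b = rep(0, C),
       ff_w1 = he_w(c(C, 2L * h), C), ff_b1 = rep(0, 2L * h),
       ff_w2 = he_w(c(h, C), h), ff_b2 = rep(0, C))
}

#' Initialize the degradation-guided network parameters
#'
#' Guidance projections and the output head are zero-initialized: at
#' initialization DGMSA equals plain channel attention and the network
#' output equals the bilinear-upsampled CALW restoration.
#'
#' @param config a [network_config()]
#' @param seed RNG seed
#' @return nested named list of parameter arrays
#' @export
dgnet_init <- function(config, seed = 1L) {
  ch <- config$channels
  with_seed(seed, {
    p <- list(shallow_w = he_w(c(3L, 3L, 3L, ch[1]), 27), shallow_b = rep(0, ch[1]))
    for (s in 1:3) {
      C <- ch[s]
      p[[paste0("pdff_w", s)]] <- he_w(c(1L, 1L, 2L * C, C), 2 * C)
      p[[paste0("pdff_b", s)]] <- rep(0, C)
      p[[paste0("enc", s)]] <- lapply(seq_len(config$blocks_enc[s]), function(i)
        dgt_block_init(C, config$heads[s], config$expansion))
    }
    p$down1 <- list(w = he_w(c(1L, 1L, ch[1], ch[2]), ch[1]), b = rep(0, ch[2]))
    p$down2 <- list(w = he_w(c(1L, 1L, ch[2], ch[3]), ch[2]), b = rep(0, ch[3]))
    p$up2 <- list(w = he_w(c(1L, 1L, ch[3], ch[2]), ch[3]), b = rep(0, ch[2]))
    p$fuse2 <- list(w = he_w(c(1L, 1L, 2L * ch[2], ch[2]), 2 * ch[2]), b = rep(0, ch[2]))
    p$dec2 <- lapply(seq_len(config$blocks_dec[2]), function(i)
      dgt_block_init(ch[2], config$heads[2], config$expansion))
    p$up1 <- list(w = he_w(c(1L, 1L, ch[2], ch[1]), ch[2]), b = rep(0, ch[1]))
    p$fuse1 <- list(w = he_w(c(1L, 1L, 2L * ch[1], ch[1]), 2 * ch[1]), b = rep(0, ch[1]))
    p$dec1 <- lapply(seq_len(config$blocks_dec[1]), function(i)
      dgt_block_init(ch[1], config$heads[1], config$expansion))
    p$head_w <- array(0, c(3L, 3L, ch[1], 12L))   # zero-init: pure residual at start
    p$head_b <- rep(0, 12L)
    p
  })
}

#' Total number of parameters in a (nested) parameter list
#' @param params nested list of arrays
#' @return integer count
#' @export
parameter_count <- function(params) {
  if (is.list(params)) sum(vapply(params, parameter_count, numeric(1)))
  else length(ag_value(params))
}

#' Physical degradation feature fusion at one scale
#'
#' Feature channels are split into three groups tied to the RGB wavelengths.
#' Each group is transformed to the frequency domain, modulated element-wise
#' by its channel's DC-normalized transfer-function magnitude (resampled to
#' the scale's grid), transformed back, concatenated with the original
#' features and mixed to the scale's width by a learned pointwise map.
#'
#' @param x feature map (H x W x C), array or node
#' @param kernels per-channel PSF kernels (k, k, 3)
#' @param w,b pointwise mixing weights (1, 1, 2C, C) and bias
#' @return fused degradation features (H x W x C)
#' @export
pdff_scale <- function(x, kernels, w, b) {
  d <- dim(ag_value(x)); C <- d[3]
  shape <- c(d[1], d[2])
  groups <- split(seq_len(C), cut(seq_len(C), 3, labels = FALSE))
  mods <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    M <- Mod(kernel_otf(kernels[, , g], shape))
    M <- M / M[1, 1]                     # DC-normalized magnitude
    mods[[g]] <- ag_freq_filter(ag_slice_c(x, groups[[g]]), M)
  }
  mod <- ag_concat_c(mods)
  ag_conv2d(ag_concat_c(list(x, mod)), w, b)
}

# L2-normalize matrix columns (safe at zero via eps inside the sqrt)
ag_l2norm_cols <- function(X, eps = 1e-8) {
  n2 <- ag_colsums(ag_pow(X, 2))
  ag_colscale(X, ag_div(1, ag_sqrt(ag_add(n2, eps))))
}

#' Degradation-guided multi-head channel attention
#'
#' Channel-transposed attention: queries, keys and values are per-channel
#' descriptors over space, so the attention matrix is channels x channels
#' and cost stays linear in pixels. The degradation features produce a
#' per-channel scale and bias (zero-initialized projections) applied to the
#' keys, `K' = K * (1 + s) + b`; with zero-initialized guidance the
#' operator is exactly plain multi-head channel attention. No bias terms
#' exist in the value path, so a zero input maps to a zero output.
#'
#' @param x input features (H x W x C)
#' @param deg degradation features of the same scale (H x W x C)
#' @param bp block parameter list (`w_qkv`, `w_proj`, `tau`, `gd_scale`,
#'   `gd_bias`)
#' @param heads number of attention heads (must divide C)
#' @return attended features (H x W x C)
#' @export
dgmsa <- function(x, deg, bp, heads) {
  d <- dim(ag_value(x)); C <- d[3]
  if (C %% heads != 0L) stop("heads must divide the channel count")
  Ch <- C %/% heads
  X <- ag_reshape(x, c(d[1] * d[2], C))
  qkv <- ag_matmul(X, bp$w_qkv)
  Q <- ag_cols(qkv, 1:C); K <- ag_cols(qkv, C + 1:C); V <- ag_cols(qkv, 2 * C + 1:C)
  # guidance: pooled degradation descriptor -> per-channel key scale/bias
  p <- ag_reshape(ag_gmean_c(deg), c(1L, C))
  s <- ag_reshape(ag_matmul(p, bp$gd_scale), C)
  bvec <- ag_reshape(ag_matmul(p, bp$gd_bias), C)
  K <- ag_coladd(ag_colscale(K, ag_add(s, 1)), bvec)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * Ch + seq_len(Ch)
    Qn <- ag_l2norm_cols(ag_cols(Q, idx))
    Kn <- ag_l2norm_cols(ag_cols(K, idx))
    scores <- ag_mul(ag_matmul(ag_t(Qn), Kn), ag_index(bp$tau, h))
    A <- ag_softmax_rows(scores)
    outs[[h]] <- ag_matmul(ag_cols(V, idx), ag_t(A))
  }
  out <- ag_matmul(ag_cbind(outs), bp$w_proj)
  ag_reshape(out, d)
}

# gated feed-forward: pointwise expand to 2h, gate one half by the other's
# sigmoid, project back
gdfn <- function(x, bp) {
  d <- dim(ag_value(x)); C <- d[3]
  h <- ncol(bp$ff_w1 |> ag_value()) %/% 2L
  X <- ag_reshape(x, c(d[1] * d[2], C))
  u <- ag_coladd(ag_matmul(X, bp$ff_w1), bp$ff_b1)
  gtd <- ag_mul(ag_cols(u, seq_len(h)), ag_sigmoid(ag_cols(u, h + seq_len(h))))
  out <- ag_coladd(ag_matmul(gtd, bp$ff_w2), bp$ff_b2)
  ag_reshape(out, d)
}

# one DGT block: norm -> DGMSA -> residual; norm -> gated FF -> residual
dgt_block <- function(x, deg, bp, heads) {
  x <- ag_add(x, dgmsa(ag_layernorm_c(x, bp$ln1_g, bp$ln1_b), deg, bp, heads))
  ag_add(x, gdfn(ag_layernorm_c(x, bp$ln2_g, bp$ln2_b), bp))
}

run_blocks <- function(x, deg, blocks, heads, where) {
  for (i in seq_along(blocks)) {
    x <- dgt_block(x, deg, blocks[[i]], heads)
    if (any(!is.finite(ag_value(x))))
      stop(sprintf("non-finite activation after %s block %d", where, i))
  }
  x
}

#' Degradation-guided network forward pass
#'
#' @param calw_out CALW initial restoration (H x W x 3), array or node
#' @param kernels per-channel PSF kernels (k, k, 3) of the sample
#' @param params a [dgnet_init()] parameter list
#' @param config the matching [network_config()]
#' @return restored image at 2H x 2W x 3 (unclipped)
#' @export
dgnet_forward <- function(calw_out, kernels, params, config) {
  heads <- config$heads
  x0 <- ag_conv2d(calw_out, params$shallow_w, params$shallow_b)
  deg1 <- pdff_scale(x0, kernels, params$pdff_w1, params$pdff_b1)
  e1 <- run_blocks(x0, deg1, params$enc1, heads[1], "enc1")
  d1 <- ag_conv2d(ag_area_down2(e1), params$down1$w, params$down1$b)
  deg2 <- pdff_scale(d1, kernels, params$pdff_w2, params$pdff_b2)
  e2 <- run_blocks(d1, deg2, params$enc2, heads[2], "enc2")
  d2 <- ag_conv2d(ag_area_down2(e2), params$down2$w, params$down2$b)
  deg3 <- pdff_scale(d2, kernels, params$pdff_w3, params$pdff_b3)
  e3 <- run_blocks(d2, deg3, params$enc3, heads[3], "enc3")
  u2 <- ag_conv2d(ag_up_bilinear2(e3), params$up2$w, params$up2$b)
  f2 <- ag_conv2d(ag_concat_c(list(u2, e2)), params$fuse2$w, params$fuse2$b)
  dd2 <- run_blocks(f2, deg2, params$dec2, heads[2], "dec2")
  u1 <- ag_conv2d(ag_up_bilinear2(dd2), params$up1$w, params$up1$b)
  f1 <- ag_conv2d(ag_concat_c(list(u1, e1)), params$fuse1$w, params$fuse1$b)
  dd1 <- run_blocks(f1, deg1, params$dec1, heads[1], "dec1")
  head <- ag_pixel_shuffle2(ag_conv2d(dd1, params$head_w, params$head_b))
  ag_add(head, ag_up_bilinear2(calw_out))
}

# kernels of the field cell containing the image center
center_kernels <- function(psf_set) {
  dk <- dim(psf_set)
  psf_set[, , , (dk[4] + 1L) %/% 2L, (dk[5] + 1L) %/% 2L]
}

#' Restore a degraded image
#'
#' Full pipeline: CALW Wiener front end at input resolution, then the
#' degradation-guided network with x2 sub-pixel upsampling and a global
#' residual from the bilinear-upsampled CALW output. `mode = "wiener"`
#' bypasses the network (bilinear-upsampled CALW output); `mode = "bicubic"`
#' is the classical interpolation baseline.
#'
#' @param y degraded RGB image (H x W x 3) in [0,1]
#' @param psf_set kernel array (k, k, 3) or a `degraded_sample` PSF set
#'   (k, k, 3, tiles_r, tiles_c), in which case the center cell is used
#' @param params list with elements `calw` and `net`
#' @param config the [network_config()] matching `params$net`
#' @param mode `"full"`, `"wiener"` or `"bicubic"`
#' @param clip clip the output to [0, 1] (TRUE for inference; training
#'   leaves the output unclipped)
#' @return restored RGB image, 2H x 2W x 3
#' @export
restore_image <- function(y, psf_set, params, config = network_config("tiny"),
                          mode = c("full", "wiener", "bicubic"), clip = TRUE) {
  mode <- match.arg(mode)
  d <- dim(y)
  if (mode == "bicubic") return(resize_bicubic(y, 2L * d[1], 2L * d[2]))
  kernels <- if (length(dim(psf_set)) == 5L) center_kernels(psf_set) else psf_set
  out <- ag_value(restore_node(y, kernels, params, config,
                               wiener_only = mode == "wiener"))
  if (clip) clip01(out) else out
}

# differentiable restoration (returns the node; used by the trainer).
# Dictionary kernels live at the ground-truth (sensor) pixel pitch; the
# degraded input is 2x coarser, so the front end and PDFF see the 2x2-
# rebinned kernels while the physics loss keeps the fine-pitch set.
restore_node <- function(y, kernels, params, config, wiener_only = FALSE) {
  kin <- kernels
  ds <- vapply(seq_len(dim(kernels)[3]),
               function(ch) list(downsample_kernel2(kernels[, , ch])), vector("list", 1))
  kin <- array(0, c(dim(ds[[1]]), length(ds)))
  for (ch in seq_along(ds)) kin[, , ch] <- ds[[ch]]
  x0 <- calw_forward(y, kin, params$calw)
  if (wiener_only) return(ag_up_bilinear2(x0))
  dgnet_forward(x0, kin, params$net, config)
}
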