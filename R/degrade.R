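# Field window: which cells of the dictionary grid a square ground-truth
# frame maps onto. A GT frame of side >= patch_size covers a centered
# k x k block of cells (k = side / patch_size); smaller frames sit inside
# the single centered cell.
field_window <- function(dict, gt_side) {
  ps <- dict$patch_size
  k <- if (gt_side >= ps) {
    if (gt_side %% ps != 0)
      stop("GT side must be a multiple of the dictionary patch size")
    gt_side %/% ps
  } else 1L
  if (k > min(dict$grid)) stop("GT frame larger than the sensor field grid")
  r0 <- (dict$grid[1] - k) %/% 2L
  c0 <- (dict$grid[2] - k) %/% 2L
  list(rows = r0 + seq_len(k) - 1L, cols = c0 + seq_len(k) - 1L, k = k,
       tile = gt_side %/% k)
}

#' Spatially-variant patch convolution
#'
#' Convolves each patch tile of an image with its own kernel, using
#' mirrored margins at tile borders and linear overlap-add blending (ramps
#' across a 32-pixel overlap), so seams between neighbouring kernels are
#' smooth. The identical operator is used by the dataset degradation
#' pipeline and by the physics-consistency loss: it accepts either plain
#' arrays or autodiff nodes.
#'
#' @param x image, H x W x C (H, W multiples of the tile size)
#' @param kset kernel array (ky, kx, C, tile_rows, tile_cols): one kernel
#'   per channel per tile
#' @param tile tile side in pixels
#' @param overlap half-width of the blending overlap (pixels); the mirrored
#'   margin is `2 * overlap` and must cover the kernel radius plus the ramp
#' @return the blurred image (same type as `x`)
#' @export
patch_convolve <- function(x, kset, tile, overlap = 16L) {
  vx <- ag_value(x)
  d <- dim(vx); H <- d[1]; W <- d[2]; C <- d[3]
  dk <- dim(kset)
  stopifnot(dk[3] == C, H %% tile == 0L, W %% tile == 0L)
  nr <- H %/% tile; nc <- W %/% tile
  stopifnot(dk[4] == nr, dk[5] == nc)
  # shrink the blending overlap for small frames (mirror padding cannot
  # exceed the frame); the kernel radius must still fit inside it
  overlap <- min(overlap, (min(H, W) - 2L) %/% 2L)
  m <- 2L * overlap                        # mirrored margin per side
  if ((dk[1] - 1L) %/% 2L > overlap)
    stop("kernel radius exceeds the blending overlap for this frame size")
  win <- tile + 2L * m                     # circular-conv window
  keep <- tile + 2L * overlap              # retained center of the window
  xp <- ag_pad_reflect(x, m)
  # 1-D ramp over the first/last `2*overlap` pixels of the kept region
  ramp1 <- function(n) {
    w <- rep(1, n)
    r <- (seq_len(2L * overlap) - 0.5) / (2L * overlap)
    w[seq_len(2L * overlap)] <- r
    w[n + 1L - seq_len(2L * overlap)] <- pmin(w[n + 1L - seq_len(2L * overlap)], r)
    w
  }
  wk <- outer(ramp1(keep), ramp1(keep))
  # accumulate weighted kept regions and the weight map
  acc <- NULL
  wmap <- matrix(0, H + 2L * overlap, W + 2L * overlap)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r0 <- (i - 1L) * tile + 1L            # window origin in padded coords
    c0 <- (j - 1L) * tile + 1L
    winx <- ag_crop(xp, r0:(r0 + win - 1L), c0:(c0 + win - 1L))
    chans <- vector("list", C)
    for (ch in seq_len(C)) {
      M <- kernel_otf(kset[, , ch, i, j], c(win, win))
      chans[[ch]] <- ag_freq_filter(ag_slice_c(winx, ch), M)
    }
    conv <- if (C > 1L) ag_concat_c(chans) else chans[[1L]]
    kept <- ag_crop(conv, (m - overlap + 1L):(m - overlap + keep),
                    (m - overlap + 1L):(m - overlap + keep))
    wgt <- ag_mul(kept, array(wk, c(keep, keep, C)))
    emb <- ag_embed(wgt, H + 2L * overlap, W + 2L * overlap,
                    (i - 1L) * tile + 1L, (j - 1L) * tile + 1L)
    acc <- if (is.null(acc)) emb else ag_add(acc, emb)
    wmap[(i - 1L) * tile + seq_len(keep), (j - 1L) * tile + seq_len(keep)] <-
      wmap[(i - 1L) * tile + seq_len(keep), (j - 1L) * tile + seq_len(keep)] + wk
  }
  core <- ag_crop(acc, overlap + seq_len(H), overlap + seq_len(W))
  wcore <- wmap[overlap + seq_len(H), overlap + seq_len(W)]
  ag_div(core, array(wcore, c(H, W, C)))
}

#' Degrade a ground-truth specimen through the 4D PSF model
#'
#' Reproduces the paired-data recipe: (1) spatially-variant PSF blur by
#' [patch_convolve()] with kernels looked up per field cell and color
#' channel, (2) additive Gaussian noise with standard deviation `sigma` on
#' the 8-bit (0-255) scale, (3) 2x downsampling by 2x2 area averaging; the
#' result is clipped to [0, 1]. Noise is added before downsampling, so the
#' effective noise level on the degraded image is `sigma / 2`.
#'
#' @param gt a [generate_specimen()] result or an S x S x 3 array in [0,1]
#' @param dict a [build_dictionary()] PSF dictionary
#' @param beta requested magnification (nearest stored level is used)
#' @param sigma Gaussian noise standard deviation on the 0-255 scale, in
#'   [2, 10] (0 is also accepted for noiseless diagnostics)
#' @param seed RNG seed for the noise draw
#' @return object of class `degraded_sample`: `input_y` (S/2 x S/2 x 3),
#'   `gt_x`, `psf_set` (kernels per channel and tile), `sigma`, `beta`
#'   (the stored level used), `seed`, and the field `window` used
#' @export
degrade <- function(gt, dict, beta, sigma, seed = 1L) {
  px <- if (inherits(gt, "specimen")) gt$pixels else gt
  stopifnot(length(dim(px)) == 3L, dim(px)[1] == dim(px)[2])
  if (!(sigma == 0 || (sigma >= 2 && sigma <= 10)))
    stop("sigma must be 0 or within [2, 10] (8-bit scale)")
  S <- dim(px)[1]
  fw <- field_window(dict, S)
  kset <- psf_window(dict, beta, fw$rows, fw$cols)
  blurred <- patch_convolve(px, kset, fw$tile)
  noisy <- if (sigma > 0) {
    with_seed(seed, blurred + array(stats::rnorm(length(blurred), 0, sigma / 255),
                                    dim(blurred)))
  } else blurred
  y <- clip01(map_channels(noisy, area_down2_mat))
  structure(list(input_y = y, gt_x = px, psf_set = kset, sigma = sigma,
                 beta = attr(kset, "level_beta"), requested_beta = beta,
                 seed = seed, window = fw,
                 style = if (inherits(gt, "specimen")) gt$style else NA_character_),
            class = "degraded_sample")
}

#' The eight dihedral variants of a degraded sample
#'
#' Applies each of the 8 flip/rotation transforms consistently to the input,
#' the ground truth and every PSF kernel, so the degradation relation
#' between input and ground truth is preserved in each variant.
#'
#' @param pair a [degrade()] result
#' @return list of 8 `degraded_sample` objects (the first is the original)
#' @export
augment_sample <- function(pair) {
  stopifnot(inherits(pair, "degraded_sample"))
  lapply(1:8, function(k) {
    out <- pair
    out$input_y <- dihedral_apply(pair$input_y, k)
    out$gt_x <- dihedral_apply(pair$gt_x, k)
    dk <- dim(pair$psf_set)
    # transform tile positions and the kernels themselves
    perm_grid <- matrix(seq_len(dk[4] * dk[5]), dk[4], dk[5])
    pg <- dihedral_apply(perm_grid, k)
    nr2 <- nrow(pg); nc2 <- ncol(pg)
    ks <- array(0, c(dk[1], dk[2], dk[3], nr2, nc2))
    for (i in seq_len(nr2)) for (j in seq_len(nc2)) {
      src <- which(perm_grid == pg[i, j], arr.ind = TRUE)
      for (ch in seq_len(dk[3]))
        ks[, , ch, i, j] <- dihedral_apply(pair$psf_set[, , ch, src[1], src[2]], k)
    }
    attr(ks, "level_beta") <- attr(pair$psf_set, "level_beta")
    out$psf_set <- ks
    out$transform <- k
    out
  })
}

#' Build a paired synthetic dataset on disk
#'
#' For each phantom ground truth: one degraded pair per zoom level, with the
#' noise level drawn uniformly from `sigma_range`, then the 8 dihedral
#' augmentations. Images are written as float TIFF (or 8-bit PNG) and a
#' manifest CSV records path, magnification, noise level, seed and style.
#' Deterministic given the master seed.
#'
#' @param n_gt number of ground-truth phantoms
#' @param dict PSF dictionary
#' @param out_dir output directory (created if missing)
#' @param zoom_levels magnifications to sample (default: the dictionary's)
#' @param sigma_range noise-level range on the 8-bit scale
#' @param seed master seed
#' @param size GT side in pixels
#' @param styles recycled over phantoms
#' @param augment apply the 8 dihedral transforms (default TRUE)
#' @param format `"tiff"` (float32) or `"png"` (8-bit)
#' @return tibble manifest (also written to `manifest.csv` in `out_dir`)
#' @export
build_dataset <- function(n_gt, dict, out_dir,
                          zoom_levels = NULL, sigma_range = c(2, 10),
                          seed = 7L, size = 512L,
                          styles = c("texture", "cells", "grating", "usaf"),
                          augment = TRUE, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(n_gt >= 1)
  if (is.null(zoom_levels)) zoom_levels <- dict$zoom_levels
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (g in seq_len(n_gt)) {
    style <- styles[(g - 1L) %% length(styles) + 1L]
    gseed <- derive_seed(seed, paste0("gt", g))
    gt <- generate_specimen(gseed, size = size, style = style)
    for (li in seq_along(zoom_levels)) {
      dseed <- derive_seed(seed, paste0("deg", g, "_", li))
      sigma <- with_seed(dseed, stats::runif(1, sigma_range[1], sigma_range[2]))
      pair <- degrade(gt, dict, zoom_levels[li], sigma, seed = dseed)
      variants <- if (augment) augment_sample(pair) else list(pair)
      for (vi in seq_along(variants)) {
        stem <- sprintf("g%03d_b%g_v%d", g, zoom_levels[li], vi)
        pin <- file.path(out_dir, paste0(stem, "_in.", format))
        pgt <- file.path(out_dir, paste0(stem, "_gt.", format))
        write_image(variants[[vi]]$input_y, pin)
        write_image(variants[[vi]]$gt_x, pgt)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          input = basename(pin), gt = basename(pgt),
          beta = variants[[vi]]$beta, sigma = sigma, seed = dseed,
          style = style, transform = vi)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read / write images (float TIFF or 8-bit PNG)
#' @param x H x W x C array in [0,1]
#' @param path destination; format chosen by extension
#' @return `read_image` returns an H x W x C array in [0,1]
#' @export
write_image <- function(x, path) {
  x <- clip01(x)
  if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(x, path)
  else
    tiff::writeTIFF(x, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  img
}
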