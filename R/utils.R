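#' @keywords internal
"_PACKAGE"

# 2-D FFT helpers. R's fft() is unnormalized; ifft2() divides by the element
# count so ifft2(fft2(x)) == x.
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_odd <- function(n) n %% 2L == 1L

#' Embed a small kernel into a larger grid for circular convolution
#'
#' Places the kernel with its center at index (1,1) (DC position), wrapping
#' negative offsets around, so `fft2()` of the result is the transfer
#' function of circular convolution by the kernel. When the target grid is
#' smaller than the kernel the kernel is wrapped modulo the grid, which is
#' the exact spectrum of circular convolution on that grid.
#'
#' @param k odd-sided 2-D kernel matrix
#' @param shape integer vector (rows, cols) of the target grid
#' @return matrix of dimension `shape`
#' @keywords internal
kernel_embed <- function(k, shape) {
  kh <- nrow(k); kw <- ncol(k)
  ch <- (kh - 1L) %/% 2L; cw <- (kw - 1L) %/% 2L
  out <- matrix(0, shape[1], shape[2])
  ri <- ((seq_len(kh) - 1L - ch) %% shape[1]) + 1L
  ci <- ((seq_len(kw) - 1L - cw) %% shape[2]) + 1L
  if (!anyDuplicated(ri) && !anyDuplicated(ci)) {
    out[ri, ci] <- k
  } else {
    for (i in seq_len(kh)) for (j in seq_len(kw))
      out[ri[i], ci[j]] <- out[ri[i], ci[j]] + k[i, j]
  }
  out
}

#' Optical transfer function of a kernel on a given grid
#' @keywords internal
kernel_otf <- function(k, shape) fft2(kernel_embed(k, shape))

# Reflect (mirror, no edge repeat) padding of a matrix by p pixels each side.
pad_reflect_mat <- function(x, p) {
  if (p == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  stopifnot(p < n, p < m)
  ri <- c((p + 1L):2L, 1L:n, (n - 1L):(n - p))
  ci <- c((p + 1L):2L, 1L:m, (m - 1L):(m - p))
  x[ri, ci, drop = FALSE]
}

# Adjoint of pad_reflect_mat: fold the padded gradient back onto the core.
pad_reflect_mat_adj <- function(g, p, n, m) {
  if (p == 0L) return(g)
  fold_rows <- function(gg, nn) {
    out <- gg[p + seq_len(nn), , drop = FALSE]
    out[(p + 1L):2L, ] <- out[(p + 1L):2L, , drop = FALSE] +
      gg[seq_len(p), , drop = FALSE]
    out[(nn - 1L):(nn - p), ] <- out[(nn - 1L):(nn - p), , drop = FALSE] +
      gg[nn + p + seq_len(p), , drop = FALSE]
    out
  }
  t(fold_rows(t(fold_rows(g, n)), m))
}

# 2x2 area (box) downsampling of a matrix with even sides.
area_down2_mat <- function(x) {
  n <- nrow(x); m <- ncol(x)
  stopifnot(n %% 2L == 0L, m %% 2L == 0L)
  (x[seq(1L, n, 2L), seq(1L, m, 2L)] + x[seq(2L, n, 2L), seq(1L, m, 2L)] +
   x[seq(1L, n, 2L), seq(2L, m, 2L)] + x[seq(2L, n, 2L), seq(2L, m, 2L)]) / 4
}

# Adjoint of area_down2_mat: spread each coarse value over its 2x2 block /4.
area_down2_mat_adj <- function(g) {
  n <- nrow(g); m <- ncol(g)
  out <- matrix(0, 2L * n, 2L * m)
  out[seq(1L, 2L * n, 2L), seq(1L, 2L * m, 2L)] <- g / 4
  out[seq(2L, 2L * n, 2L), seq(1L, 2L * m, 2L)] <- g / 4
  out[seq(1L, 2L * n, 2L), seq(2L, 2L * m, 2L)] <- g / 4
  out[seq(2L, 2L * n, 2L), seq(2L, 2L * m, 2L)] <- g / 4
  out
}

# Factor-2 bilinear upsampling (align_corners = FALSE convention) of a
# matrix, separable taps (3/4, 1/4) with edge clamping.
up_bilinear2_mat <- function(x) {
  up1 <- function(v_prev, v, v_next) list(0.25 * v_prev + 0.75 * v,
                                          0.75 * v + 0.25 * v_next)
  n <- nrow(x)
  prev <- x[c(1L, seq_len(n - 1L)), , drop = FALSE]
  nxt  <- x[c(seq_len(n)[-1L], n), , drop = FALSE]
  rows <- matrix(0, 2L * n, ncol(x))
  rows[seq(1L, 2L * n, 2L), ] <- 0.25 * prev + 0.75 * x
  rows[seq(2L, 2L * n, 2L), ] <- 0.75 * x + 0.25 * nxt
  m <- ncol(rows)
  prevc <- rows[, c(1L, seq_len(m - 1L)), drop = FALSE]
  nxtc  <- rows[, c(seq_len(m)[-1L], m), drop = FALSE]
  out <- matrix(0, nrow(rows), 2L * m)
  out[, seq(1L, 2L * m, 2L)] <- 0.25 * prevc + 0.75 * rows
  out[, seq(2L, 2L * m, 2L)] <- 0.75 * rows + 0.25 * nxtc
  out
}

# Adjoint of up_bilinear2_mat (scatter-add of the same taps).
up_bilinear2_mat_adj <- function(g) {
  fold_cols <- function(gg) {
    m2 <- ncol(gg); m <- m2 %/% 2L
    odd <- gg[, seq(1L, m2, 2L), drop = FALSE]
    even <- gg[, seq(2L, m2, 2L), drop = FALSE]
    out <- 0.75 * odd + 0.75 * even
    # odd output j drew 0.25 from column j-1 (clamped to 1)
    out[, 1L] <- out[, 1L] + 0.25 * odd[, 1L]
    if (m > 1L) out[, seq_len(m - 1L)] <- out[, seq_len(m - 1L), drop = FALSE] +
      0.25 * odd[, seq_len(m - 1L) + 1L, drop = FALSE]
    # even output j drew 0.25 from column j+1 (clamped to m)
    out[, m] <- out[, m] + 0.25 * even[, m]
    if (m > 1L) out[, seq_len(m - 1L) + 1L] <- out[, seq_len(m - 1L) + 1L, drop = FALSE] +
      0.25 * even[, seq_len(m - 1L), drop = FALSE]
    out
  }
  t(fold_cols(t(fold_cols(g))))
}

# Apply a matrix op channel-wise over an H x W x C array.
map_channels <- function(x, f) {
  d <- dim(x)
  if (length(d) == 2L) return(f(x))
  out <- array(0, c(dim(f(x[, , 1L]))[1:2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- f(x[, , c])
  out
}

#' Bicubic image resizing (Catmull-Rom kernel)
#'
#' Separable bicubic interpolation with the standard a = -0.5 kernel and
#' edge clamping; used as the classical upsampling baseline in evaluation.
#'
#' @param x matrix or H x W x C array
#' @param out_h,out_w output dimensions in pixels
#' @return resized array of the same rank
#' @export
resize_bicubic <- function(x, out_h, out_w) {
  cubic <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  weights_1d <- function(n_in, n_out) {
    # half-pixel centers mapping
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    base <- floor(src - 2) + 1
    W <- matrix(0, n_out, n_in)
    for (k in 0:3) {
      idx <- base + k
      w <- cubic(src - idx)
      idx <- pmin(pmax(idx, 1), n_in)
      for (i in seq_len(n_out)) W[i, idx[i]] <- W[i, idx[i]] + w[i]
    }
    W / rowSums(W)
  }
  f <- function(m) {
    Wr <- weights_1d(nrow(m), out_h)
    Wc <- weights_1d(ncol(m), out_w)
    Wr %*% m %*% t(Wc)
  }
  map_channels(x, f)
}

# Rebin an odd-sided kernel to half resolution (2x2 block sums), keeping an
# odd side and the center pixel centered; models the effective blur on an
# image that is 2x area-downsampled after convolution at fine pitch.
downsample_kernel2 <- function(k) {
  n <- nrow(k)
  stopifnot(n %% 2L == 1L)
  ke <- matrix(0, n + 1L, n + 1L)
  ke[seq_len(n), seq_len(n)] <- k
  h <- (n + 1L) %/% 2L
  out <- ke[seq(1L, n, 2L), seq(1L, n, 2L)] + ke[seq(2L, n + 1L, 2L), seq(1L, n, 2L)] +
    ke[seq(1L, n, 2L), seq(2L, n + 1L, 2L)] + ke[seq(2L, n + 1L, 2L), seq(2L, n + 1L, 2L)]
  out / sum(out)
}

# The eight dihedral (flip/rotation) transforms of a matrix, indexed 1..8:
# 1 identity, 2 rot90, 3 rot180, 4 rot270, 5 h-flip, 6 v-flip,
# 7 transpose, 8 anti-transpose.
dihedral_apply <- function(x, k) {
  stopifnot(k %in% 1:8)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  f <- switch(k,
    function(m) m,
    rot90,
    function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
    function(m) rot90(rot90(rot90(m))),
    function(m) m[, ncol(m):1, drop = FALSE],
    function(m) m[nrow(m):1, , drop = FALSE],
    function(m) t(m),
    function(m) rot90(m)[nrow(m):1, ncol(m):1, drop = FALSE])
  map_channels(x, f)
}

# Inverse transform index for each dihedral element.
dihedral_inverse <- c(1L, 4L, 3L, 2L, 5L, 6L, 7L, 8L)

# Deterministic child seed derived from a master seed and a key string;
# kept below 2^31.
derive_seed <- function(seed, key) {
  v <- utf8ToInt(paste0(key, ":", seed))
  h <- sum(v * (seq_along(v) %% 97 + 1))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483399)
}
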