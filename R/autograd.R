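# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every operator accepts either plain numeric arrays or `ag_node` objects.
# With plain inputs the operator just computes the value, so the same code
# path serves both the (non-differentiable) forward model and training.
# Nodes record their parents and per-parent backward closures; ag_backward()
# runs a topological sweep accumulating gradients into leaf nodes created
# with ag_param().

.ag <- new.env(parent = emptyenv())
.ag$n <- 0L

ag_node <- function(value, parents = list(), backfns = list()) {
  e <- new.env(parent = emptyenv())
  e$value <- value; e$parents <- parents; e$backfns <- backfns
  .ag$n <- .ag$n + 1L
  e$id <- .ag$n
  class(e) <- "ag_node"
  e
}

#' Create a differentiable leaf (parameter) node
#' @param value numeric array
#' @return an `ag_node`; after [ag_backward()] its `$grad` holds dL/dvalue
#' @keywords internal
ag_param <- function(value) ag_node(value)

is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_node(x)) x$value else x

# Wrap an op: keep only node inputs as parents; plain inputs contribute no
# gradient. If nothing is a node, return the bare value.
ag_op <- function(value, inputs, backfns) {
  keep <- vapply(inputs, is_node, logical(1))
  if (!any(keep)) return(value)
  ag_node(value, inputs[keep], backfns[keep])
}

#' Reverse sweep: accumulate gradients of a scalar (or seeded) node
#' @param root output node
#' @param seed gradient seed; defaults to ones of the root's shape
#' @keywords internal
ag_backward <- function(root, seed = NULL) {
  stopifnot(is_node(root))
  nodes <- vector("list", 256L); nn <- 0L
  stack <- list(root)
  seen <- new.env(parent = emptyenv())
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (is.null(seen[[key]])) {
      assign(key, TRUE, envir = seen)
      nn <- nn + 1L
      if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
      nodes[[nn]] <- n
      for (p in n$parents) stack[[length(stack) + 1L]] <- p
    }
  }
  nodes <- nodes[seq_len(nn)]
  for (n in nodes) n$grad <- NULL
  root$grad <- if (is.null(seed)) {
    v <- root$value
    if (is.null(dim(v))) rep(1, length(v)) else array(1, dim(v))
  } else seed
  ids <- vapply(nodes, function(n) n$id, numeric(1))
  for (i in order(ids, decreasing = TRUE)) {
    n <- nodes[[i]]
    if (is.null(n$grad) || !length(n$parents)) next
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      g <- n$backfns[[j]](n$grad)
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# --- elementwise arithmetic ------------------------------------------------

# reduce a gradient to a scalar if the forward input was length-1
.red <- function(g, v) if (length(v) == 1L) sum(g) else g

ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va + vb, list(a, b),
        list(function(g) .red(g, va), function(g) .red(g, vb)))
}

ag_sub <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va - vb, list(a, b),
        list(function(g) .red(g, va), function(g) .red(-g, vb)))
}

ag_neg <- function(a) {
  va <- ag_value(a)
  ag_op(-va, list(a), list(function(g) -g))
}

ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va * vb, list(a, b),
        list(function(g) .red(g * vb, va), function(g) .red(g * va, vb)))
}

ag_div <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va / vb, list(a, b),
        list(function(g) .red(g / vb, va),
             function(g) .red(-g * va / vb^2, vb)))
}

ag_exp <- function(a) {
  v <- exp(ag_value(a)); ag_op(v, list(a), list(function(g) g * v))
}

ag_log <- function(a) {
  va <- ag_value(a); ag_op(log(va), list(a), list(function(g) g / va))
}

ag_sqrt <- function(a) {
  v <- sqrt(ag_value(a)); ag_op(v, list(a), list(function(g) g / (2 * v)))
}

ag_pow <- function(a, p) {
  va <- ag_value(a)
  ag_op(va^p, list(a), list(function(g) g * p * va^(p - 1)))
}

ag_tanh <- function(a) {
  v <- tanh(ag_value(a)); ag_op(v, list(a), list(function(g) g * (1 - v^2)))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_value(a)))
  ag_op(v, list(a), list(function(g) g * v * (1 - v)))
}

ag_relu <- function(a) {
  va <- ag_value(a)
  ag_op(pmax(va, 0), list(a), list(function(g) g * (va > 0)))
}

ag_abs <- function(a) {
  va <- ag_value(a)
  ag_op(abs(va), list(a), list(function(g) g * sign(va)))
}

ag_sum <- function(a) {
  va <- ag_value(a)
  ag_op(sum(va), list(a), list(function(g) {
    if (is.null(dim(va))) rep(as.numeric(g), length(va))
    else array(as.numeric(g), dim(va))
  }))
}

ag_mean <- function(a) {
  va <- ag_value(a)
  ag_op(mean(va), list(a), list(function(g) {
    gv <- as.numeric(g) / length(va)
    if (is.null(dim(va))) rep(gv, length(va)) else array(gv, dim(va))
  }))
}

# --- shaping ---------------------------------------------------------------

ag_reshape <- function(a, dims) {
  va <- ag_value(a); od <- dim(va)
  v <- va; dim(v) <- dims
  ag_op(v, list(a), list(function(g) { dim(g) <- od; g }))
}

ag_t <- function(a) {
  va <- ag_value(a)
  ag_op(t(va), list(a), list(function(g) t(g)))
}

ag_cols <- function(a, idx) {
  va <- ag_value(a)
  ag_op(va[, idx, drop = FALSE], list(a), list(function(g) {
    out <- matrix(0, nrow(va), ncol(va)); out[, idx] <- g; out
  }))
}

# concatenate matrices column-wise
ag_cbind <- function(xs) {
  vals <- lapply(xs, ag_value)
  nc <- vapply(vals, ncol, integer(1))
  ends <- cumsum(nc); starts <- ends - nc + 1L
  backfns <- lapply(seq_along(xs), function(i) {
    force(i)
    function(g) g[, starts[i]:ends[i], drop = FALSE]
  })
  ag_op(do.call(cbind, vals), xs, backfns)
}

# concatenate H x W x C arrays along channels
ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  nc <- vapply(vals, function(v) dim(v)[3], integer(1))
  ends <- cumsum(nc); starts <- ends - nc + 1L
  backfns <- lapply(seq_along(xs), function(i) {
    force(i)
    function(g) g[, , starts[i]:ends[i], drop = FALSE]
  })
  d1 <- dim(vals[[1]])
  out <- array(0, c(d1[1], d1[2], sum(nc)))
  for (i in seq_along(vals)) out[, , starts[i]:ends[i]] <- vals[[i]]
  ag_op(out, xs, backfns)
}

ag_slice_c <- function(a, idx) {
  va <- ag_value(a)
  ag_op(va[, , idx, drop = FALSE], list(a), list(function(g) {
    out <- array(0, dim(va)); out[, , idx] <- g; out
  }))
}

# --- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_op(va %*% vb, list(a, b),
        list(function(g) g %*% t(vb), function(g) t(va) %*% g))
}

ag_rowsums <- function(a) {
  va <- ag_value(a)
  ag_op(rowSums(va), list(a),
        list(function(g) matrix(g, nrow(va), ncol(va))))
}

ag_colsums <- function(a) {
  va <- ag_value(a)
  ag_op(colSums(va), list(a),
        list(function(g) matrix(g, nrow(va), ncol(va), byrow = TRUE)))
}

# scale row i of X by s[i]
ag_rowscale <- function(X, s) {
  vx <- ag_value(X); vs <- ag_value(s)
  ag_op(vx * vs, list(X, s),
        list(function(g) g * vs, function(g) rowSums(g * vx)))
}

# scale column j of X by s[j]
ag_colscale <- function(X, s) {
  vx <- ag_value(X); vs <- ag_value(s)
  ag_op(sweep(vx, 2, vs, "*"), list(X, s),
        list(function(g) sweep(g, 2, vs, "*"),
             function(g) colSums(g * vx)))
}

# add b[j] to column j of X
ag_coladd <- function(X, b) {
  vx <- ag_value(X); vb <- ag_value(b)
  ag_op(sweep(vx, 2, vb, "+"), list(X, b),
        list(function(g) g, function(g) colSums(g)))
}

ag_softmax_rows <- function(X) {
  vx <- ag_value(X)
  m <- apply(vx, 1, max)
  e <- exp(vx - m)
  p <- e / rowSums(e)
  ag_op(p, list(X), list(function(g) {
    (g - rowSums(g * p)) * p
  }))
}

# --- image-shaped (H x W x C) operators ------------------------------------

csum3 <- function(a, d) colSums(matrix(a, d[1] * d[2], d[3]))

ag_scale_c <- function(x, s) {
  vx <- ag_value(x); vs <- ag_value(s)
  d <- dim(vx); sc <- rep(vs, each = d[1] * d[2])
  ag_op(vx * array(sc, d), list(x, s),
        list(function(g) g * array(sc, d),
             function(g) csum3(g * vx, d)))
}

ag_addbias_c <- function(x, b) {
  vx <- ag_value(x); vb <- ag_value(b)
  d <- dim(vx); bc <- array(rep(vb, each = d[1] * d[2]), d)
  ag_op(vx + bc, list(x, b),
        list(function(g) g, function(g) csum3(g, d)))
}

# global average pooling over pixels -> channel vector
ag_gmean_c <- function(x) {
  vx <- ag_value(x); d <- dim(vx)
  ag_op(csum3(vx, d) / (d[1] * d[2]), list(x), list(function(g) {
    array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
  }))
}

# layer normalization over the channel dimension, per pixel
ag_layernorm_c <- function(x, gamma, beta, eps = 1e-5) {
  vx <- ag_value(x); d <- dim(vx); C <- d[3]
  mu <- rowSums(vx, dims = 2) / C
  xm <- vx - array(mu, d)
  v <- rowSums(xm^2, dims = 2) / C + eps
  inv <- 1 / sqrt(v)
  xh <- xm * array(inv, d)
  vg <- ag_value(gamma); vb <- ag_value(beta)
  y <- xh * array(rep(vg, each = d[1] * d[2]), d) +
    array(rep(vb, each = d[1] * d[2]), d)
  ag_op(y, list(x, gamma, beta), list(
    function(g) {
      gx <- g * array(rep(vg, each = d[1] * d[2]), d)
      s1 <- rowSums(gx, dims = 2)
      s2 <- rowSums(gx * xm, dims = 2)
      (gx - array(s1 / C, d) - xm * array(s2 * inv^2 / C, d)) * array(inv, d)
    },
    function(g) csum3(g * xh, d),
    function(g) csum3(g, d)))
}

# --- separable fixed-window blur (e.g. the SSIM Gaussian) ------------------

.band_cache <- new.env(parent = emptyenv())

# band matrix B (n x n) with B[i, j] = k1d[j - i + h + 1], zero-padded same
band_matrix <- function(k1d, n) {
  key <- sprintf("%d_%s", n, paste(signif(k1d, 8), collapse = ","))
  B <- .band_cache[[key]]
  if (!is.null(B)) return(B)
  h <- (length(k1d) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (off in -h:h) {
    i <- seq_len(n); j <- i + off
    ok <- j >= 1L & j <= n
    B[cbind(i[ok], j[ok])] <- k1d[off + h + 1L]
  }
  .band_cache[[key]] <- B
  B
}

# depthwise separable convolution of each channel by outer(k1d, k1d),
# zero-padded same; adjoint uses the transposed band matrices
ag_sepconv_fixed <- function(x, k1d) {
  vx <- ag_value(x); d <- dim(vx)
  Br <- band_matrix(k1d, d[1]); Bc <- band_matrix(k1d, d[2])
  fwd <- function(v, R, Cc) map_channels(v, function(m) R %*% m %*% t(Cc))
  ag_op(fwd(vx, Br, Bc), list(x),
        list(function(g) fwd(g, t(Br), t(Bc))))
}

ag_area_down2 <- function(x) {
  vx <- ag_value(x)
  ag_op(map_channels(vx, area_down2_mat), list(x),
        list(function(g) map_channels(g, area_down2_mat_adj)))
}

ag_up_bilinear2 <- function(x) {
  vx <- ag_value(x)
  ag_op(map_channels(vx, up_bilinear2_mat), list(x),
        list(function(g) map_channels(g, up_bilinear2_mat_adj)))
}

ag_pad_reflect <- function(x, p) {
  vx <- ag_value(x); d <- dim(vx)
  ag_op(map_channels(vx, function(m) pad_reflect_mat(m, p)), list(x),
        list(function(g) map_channels(g, function(m)
          pad_reflect_mat_adj(m, p, d[1], d[2]))))
}

ag_crop <- function(x, rows, cols) {
  vx <- ag_value(x); d <- dim(vx)
  ag_op(vx[rows, cols, , drop = FALSE], list(x), list(function(g) {
    out <- array(0, d); out[rows, cols, ] <- g; out
  }))
}

# place x into a zero canvas of (out_h, out_w) at 1-based offset (r0, c0)
ag_embed <- function(x, out_h, out_w, r0, c0) {
  vx <- ag_value(x); d <- dim(vx)
  rows <- r0:(r0 + d[1] - 1L); cols <- c0:(c0 + d[2] - 1L)
  out <- array(0, c(out_h, out_w, d[3]))
  out[rows, cols, ] <- vx
  ag_op(out, list(x),
        list(function(g) g[rows, cols, , drop = FALSE]))
}

# sub-pixel rearrangement: (H, W, 4C) -> (2H, 2W, C); channel blocks are
# ordered (dy, dx) = (0,0), (0,1), (1,0), (1,1)
ag_pixel_shuffle2 <- function(x) {
  vx <- ag_value(x); d <- dim(vx); C <- d[3] %/% 4L
  fwd <- function(v) {
    out <- array(0, c(2L * d[1], 2L * d[2], C))
    q <- 0L
    for (dy in 0:1) for (dx in 0:1) {
      q <- q + 1L
      out[seq(1L + dy, 2L * d[1], 2L), seq(1L + dx, 2L * d[2], 2L), ] <-
        v[, , ((q - 1L) * C + 1L):(q * C), drop = FALSE]
    }
    out
  }
  ag_op(fwd(vx), list(x), list(function(g) {
    out <- array(0, d); q <- 0L
    for (dy in 0:1) for (dx in 0:1) {
      q <- q + 1L
      out[, , ((q - 1L) * C + 1L):(q * C)] <-
        g[seq(1L + dy, 2L * d[1], 2L), seq(1L + dx, 2L * d[2], 2L), ,
          drop = FALSE]
    }
    out
  }))
}

# --- convolution -----------------------------------------------------------

# im2col for stride-1 same zero-padding; column order matches
# matrix(w, kh*kw*Cin, Cout) of a (kh, kw, Cin, Cout) weight array.
im2col <- function(x, kh, kw) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2L * ph, W + 2L * pw, Cin))
  xp[(ph + 1L):(ph + H), (pw + 1L):(pw + W), ] <- x
  cols <- matrix(0, H * W, kh * kw * Cin)
  k <- 0L
  for (ci in seq_len(Cin)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- xp[i:(i + H - 1L), j:(j + W - 1L), ci]
  }
  cols
}

col2im <- function(gcols, H, W, Cin, kh, kw) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2L * ph, W + 2L * pw, Cin))
  k <- 0L
  for (ci in seq_len(Cin)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    k <- k + 1L
    xp[i:(i + H - 1L), j:(j + W - 1L), ci] <-
      xp[i:(i + H - 1L), j:(j + W - 1L), ci] + matrix(gcols[, k], H, W)
  }
  xp[(ph + 1L):(ph + H), (pw + 1L):(pw + W), , drop = FALSE]
}

# 2-D convolution (cross-correlation, the deep-learning convention),
# stride 1, zero-padded same: x (H,W,Cin), w (kh,kw,Cin,Cout), b (Cout)
ag_conv2d <- function(x, w, b = NULL) {
  vx <- ag_value(x); vw <- ag_value(w)
  d <- dim(vx); dw <- dim(vw)
  H <- d[1]; W <- d[2]; Cin <- d[3]; kh <- dw[1]; kw <- dw[2]; Cout <- dw[4]
  stopifnot(dw[3] == Cin)
  cols <- if (kh == 1L && kw == 1L) matrix(vx, H * W, Cin)
          else im2col(vx, kh, kw)
  Wmat <- matrix(vw, kh * kw * Cin, Cout)
  out <- cols %*% Wmat
  if (!is.null(b)) out <- sweep(out, 2, ag_value(b), "+")
  outa <- array(out, c(H, W, Cout))
  inputs <- list(x, w)
  backfns <- list(
    function(g) {
      gmat <- matrix(g, H * W, Cout)
      if (kh == 1L && kw == 1L) array(gmat %*% t(Wmat), c(H, W, Cin))
      else col2im(gmat %*% t(Wmat), H, W, Cin, kh, kw)
    },
    function(g) {
      gmat <- matrix(g, H * W, Cout)
      array(t(cols) %*% gmat, dw)
    })
  if (!is.null(b)) {
    inputs <- c(inputs, list(b))
    backfns <- c(backfns, list(function(g) colSums(matrix(g, H * W, Cout))))
  }
  ag_op(outa, inputs, backfns)
}

# --- frequency-domain operators --------------------------------------------

# per-channel circular filtering by a fixed transfer function M (H x W,
# real or complex): Re(IFFT(FFT(x_c) * M)). Adjoint uses conj(M).
ag_freq_filter <- function(x, M) {
  vx <- ag_value(x)
  CM <- Conj(M)
  fwd <- function(v, tf) map_channels(v, function(m) Re(ifft2(fft2(m) * tf)))
  ag_op(fwd(vx, M), list(x),
        list(function(g) fwd(g, CM)))
}

# Channel-wise learnable Wiener deconvolution (closed form, circular
# convolution convention), as one composite differentiable operator.
#
#   xhat = Re F^H [ conj(DK) .* F y / (|DK|^2 + e^alpha * sum_d |DG_d|^2) ]
#
# y: fixed real matrix (N x N). K re/im: the (possibly corrected) OTF as two
# real matrices. gbank: (gk, gk, D) real regularization kernels whose
# spectra are taken on the N x N grid. alpha: scalar log-strength.
# Gradients are propagated to K (both planes), gbank and alpha; y is input
# data and receives no gradient.
ag_wiener <- function(y, k_re, k_im, gbank, alpha) {
  vy <- ag_value(y)
  vre <- ag_value(k_re); vim <- ag_value(k_im)
  vg <- ag_value(gbank); valpha <- as.numeric(ag_value(alpha))
  N1 <- nrow(vy); N2 <- ncol(vy)
  DK <- vre + 1i * vim
  Dg <- ag_value(gbank)
  D <- dim(vg)[3]
  DG <- vector("list", D)
  S <- matrix(0, N1, N2)
  for (d in seq_len(D)) {
    DG[[d]] <- kernel_otf(vg[, , d], c(N1, N2))
    S <- S + Mod(DG[[d]])^2
  }
  den <- Mod(DK)^2 + exp(valpha) * S
  if (any(den == 0))
    stop("singular Wiener filter: zero transfer and zero regularization at some frequency")
  Y <- fft2(vy)
  X <- Conj(DK) * Y / den
  xhat <- Re(ifft2(X))
  ag_op(xhat, list(k_re, k_im, gbank, alpha), list(
    function(g) {
      Gx <- ifft2(g)   # plain-transpose adjoint of Re(ifft2(.)) seed
      A <- Gx * (Y - X * DK) / den
      B <- -Gx * X * Conj(DK) / den
      Re(A) + Re(B)
    },
    function(g) {
      Gx <- ifft2(g)
      A <- Gx * (Y - X * DK) / den
      B <- -Gx * X * Conj(DK) / den
      Im(A) - Im(B)
    },
    function(g) {
      Gx <- ifft2(g)
      Wf <- Re(-Gx * X / den) * exp(valpha)
      out <- array(0, dim(vg))
      gk <- dim(vg)[1]
      for (d in seq_len(D)) {
        full <- 2 * Re(fft2(Wf * Conj(DG[[d]])))
        # gather the pad positions of kernel_embed
        ch <- (gk - 1L) %/% 2L
        km <- matrix(0, gk, gk)
        ri <- ((seq_len(gk) - 1L - ch) %% N1) + 1L
        ci <- ((seq_len(gk) - 1L - ch) %% N2) + 1L
        for (i in seq_len(gk)) for (j in seq_len(gk))
          km[i, j] <- full[ri[i], ci[j]]
        out[, , d] <- km
      }
      out
    },
    function(g) {
      Gx <- ifft2(g)
      sum(Re(-Gx * X / den) * exp(valpha) * S)
    }))
}
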