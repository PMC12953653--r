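# Content-adaptive learnable Wiener front end

test_that("identity initialization: base bank and uncorrected spectrum", {
  params <- calw_init(seed = 2)
  y <- generate_specimen(5, 32, "texture")$pixels
  expect_identical(predict_reg_kernels(y, params), base_reg_bank())
  otf <- kernel_otf(outer(dnorm(-1:1), dnorm(-1:1)) / sum(outer(dnorm(-1:1), dnorm(-1:1))),
                    c(16, 16))
  co <- optimize_psf_spectrum(otf, params)
  expect_identical(co$re, Re(otf))
  expect_identical(co$im, Im(otf))
})

test_that("base regularization kernels are zero-mean (no DC penalty)", {
  b <- base_reg_bank()
  for (d in 1:8) {
    expect_lt(abs(sum(b[, , d])), 1e-12)
    expect_lt(Mod(kernel_otf(b[, , d], c(8, 8))[1, 1]), 1e-12)
  }
})

test_that("corrected DC magnitude is bounded within [0.5, 2] by construction", {
  set.seed(9)
  params <- calw_init(seed = 2)
  # random (trained-looking) correction head
  params$sc_w2 <- array(rnorm(16, 0, 3), c(1, 1, 8, 2))
  params$sc_b2 <- rnorm(2, 0, 3)
  k <- outer(dnorm(-2:2), dnorm(-2:2)); k <- k / sum(k)
  otf <- kernel_otf(k, c(16, 16))
  co <- optimize_psf_spectrum(otf, params)
  dc <- sqrt(ag_value(co$re)[1, 1]^2 + ag_value(co$im)[1, 1]^2)
  expect_gte(dc, 0.5)
  expect_lte(dc, 2)
})

test_that("delta kernel with zero bank is the exact identity filter", {
  y <- generate_specimen(1, 32, "cells")$pixels[, , 1]
  kdel <- matrix(0, 33, 33); kdel[17, 17] <- 1
  out <- wiener_deconvolve(y, kdel, array(0, c(3, 3, 1)), -2)
  expect_lt(max(abs(out - y)), 1e-12)
  # zero input stays zero
  expect_identical(max(abs(wiener_deconvolve(matrix(0, 16, 16), kdel,
                                             base_reg_bank(), -2))), 0)
})

test_that("a zero transfer function with zero bank is singular", {
  expect_error(wiener_deconvolve(matrix(1, 8, 8), matrix(0, 3, 3),
                                 array(0, c(3, 3, 1)), 0), "singular")
})

test_that("Wiener output solves the dense circulant normal equations", {
  circ_mat <- function(k, N) {
    ke <- kernel_embed(k, c(N, N))
    M <- matrix(0, N * N, N * N)
    for (j in seq_len(N * N)) {
      e <- matrix(0, N, N); e[j] <- 1
      M[, j] <- as.vector(Re(psf4d:::ifft2(psf4d:::fft2(e) * psf4d:::fft2(ke))))
    }
    M
  }
  set.seed(31)
  for (trial in 1:20) {
    N <- if (trial %% 2 == 0) 8L else 16L
    s <- runif(1, 0.6, 1.6)
    k <- outer(dnorm(-1:1, 0, s), dnorm(-1:1, 0, s)); k <- k / sum(k)
    D <- sample(1:3, 1)
    gb <- array(rnorm(9 * D) * 0.5, c(3, 3, D))
    alpha <- runif(1, -4, 0)
    y <- matrix(runif(N * N), N)
    K <- circ_mat(k, N)
    A <- t(K) %*% K
    for (d in seq_len(D)) {
      G <- circ_mat(gb[, , d], N)
      A <- A + exp(alpha) * t(G) %*% G
    }
    x_direct <- solve(A, t(K) %*% as.vector(y))
    x_wiener <- wiener_deconvolve(y, k, gb, alpha)
    expect_lt(max(abs(as.vector(x_wiener) - x_direct)), 1e-5)
  }
})

test_that("restoration norm is non-increasing in the regularization strength", {
  set.seed(12)
  y <- generate_specimen(4, 32, "texture")$pixels[, , 2]
  k <- outer(dnorm(-2:2), dnorm(-2:2)); k <- k / sum(k)
  norms <- vapply(seq(-8, 4, by = 1), function(a)
    sqrt(sum(wiener_deconvolve(y, k, base_reg_bank(), a)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("predicted banks differ between images once the head is perturbed", {
  params <- calw_init(seed = 2)
  params$pk_lin_w <- matrix(rnorm(8 * 72, 0, 0.05), 8, 72)  # one training step away
  y1 <- generate_specimen(1, 32, "texture")$pixels
  y2 <- generate_specimen(2, 32, "cells")$pixels
  g1 <- predict_reg_kernels(y1, params)
  g2 <- predict_reg_kernels(y2, params)
  expect_gt(sqrt(sum((g1 - g2)^2)), 0)
})

test_that("calw_forward composes to the identity for delta kernels", {
  params <- calw_init(seed = 2)
  y <- generate_specimen(6, 32, "grating")$pixels
  kdel <- array(0, c(17, 17, 3)); kdel[9, 9, ] <- 1
  out <- calw_forward(y, kdel, params, reg_bank = array(0, c(3, 3, 1)))
  expect_lt(max(abs(out - y)), 1e-10)
})

test_that("channels are processed independently", {
  params <- calw_init(seed = 2)
  y <- generate_specimen(7, 32, "cells")$pixels
  kern <- array(0, c(17, 17, 3))
  for (ch in 1:3) {
    k <- outer(dnorm(-8:8, 0, ch), dnorm(-8:8, 0, ch)); kern[, , ch] <- k / sum(k)
  }
  out <- calw_forward(y, kern, params)
  # replicate per channel with the shared predicted bank and padding
  G <- predict_reg_kernels(y, params)
  for (ch in 1:3) {
    yp <- pad_reflect_mat(y[, , ch], 16)
    ref <- ag_value(ag_wiener(yp, Re(kernel_otf(kern[, , ch], dim(yp))),
                              Im(kernel_otf(kern[, , ch], dim(yp))),
                              G, params$alpha[ch]))
    expect_lt(max(abs(out[, , ch] - ref[16 + 1:32, 16 + 1:32])), 1e-12)
  }
})

test_that("deconvolution of a blurred noiseless grating beats the input", {
  dict <- fix_dict()
  gt <- generate_specimen(9, 128, "grating", grating_freq = 20)
  s <- degrade(gt, dict, 100, 0)
  params <- calw_init(seed = 2)
  params$alpha <- rep(-6, 3)
  kern <- center_kernels(s$psf_set)
  kin <- array(0, c(17, 17, 3))
  for (ch in 1:3) kin[, , ch] <- psf4d:::downsample_kernel2(kern[, , ch])
  out <- clip01(ag_value(calw_forward(s$input_y, kin, params)))
  gt_half <- map_channels(s$gt_x, area_down2_mat)
  expect_gt(psnr(out, gt_half), psnr(s$input_y, gt_half))
})

test_that("alpha gradients from the tape match finite differences", {
  dict <- fix_dict()
  s <- fix_samples(1, 700, size = 64, dict = dict)[[1]]
  params <- calw_init(seed = 2)
  kern <- center_kernels(s$psf_set)
  kin <- array(0, c(17, 17, 3))
  for (ch in 1:3) kin[, , ch] <- psf4d:::downsample_kernel2(kern[, , ch])
  gt_half <- map_channels(s$gt_x, area_down2_mat)
  loss_of <- function(alpha_vec) {
    p <- params; p$alpha <- alpha_vec
    ag_mean(ag_pow(ag_sub(calw_forward(s$input_y, kin, p), gt_half), 2))
  }
  # autodiff gradient
  w <- wrap_params(params)
  l <- ag_mean(ag_pow(ag_sub(calw_forward(s$input_y, kin, w$tree), gt_half), 2))
  ag_backward(l)
  ga <- w$leaves[["/alpha"]]$grad
  eps <- 1e-4
  for (ch in 1:3) {
    ap <- params$alpha; ap[ch] <- ap[ch] + eps
    am <- params$alpha; am[ch] <- am[ch] - eps
    gn <- (ag_value(loss_of(ap)) - ag_value(loss_of(am))) / (2 * eps)
    expect_lt(abs(ga[ch] - gn) / max(abs(gn), 1e-10), 1e-4)
  }
})

test_that("spectrum correction learns a kernel mismatch (paired ablation)", {
  # true blur is slightly wider than the tabulated dictionary kernel
  # (a manufacturing-tolerance-style mismatch); fit CALW alone and compare
  # the physics residual with the spectrum correction enabled vs frozen,
  # on the same fixed validation pair
  dict <- fix_dict()
  kern_true <- dict$kernels[2, 3, 4, , , ]           # (3, 33, 33)
  gk <- outer(dnorm(-2:2, 0, 0.8), dnorm(-2:2, 0, 0.8)); gk <- gk / sum(gk)
  widen <- function(k) {
    o <- Re(psf4d:::ifft2(psf4d:::fft2(kernel_embed(k, c(33, 33))) *
                          kernel_otf(gk, c(33, 33))))
    o <- pmax(psf4d:::fftshift2(o), 0)
    o / sum(o)
  }
  mk_sample <- function(seed) {
    gt <- generate_specimen(seed, 64, "cells")$pixels
    kset <- array(0, c(33, 33, 3, 1, 1))
    for (ch in 1:3) kset[, , ch, 1, 1] <- widen(kern_true[ch, , ])
    blur <- patch_convolve(gt, kset, 64L)
    y <- clip01(map_channels(blur, area_down2_mat))
    # CALW is told the unwidened dictionary kernel
    kdict <- array(aperm(kern_true, c(2, 3, 1)), c(33, 33, 3, 1, 1))
    attr(kdict, "level_beta") <- 60
    list(y = y, gt = gt, kdict = kdict, ktrue = kset)
  }
  train_pairs <- lapply(1:2, mk_sample)
  val <- mk_sample(99)
  fit_calw <- function(enable_correction) {
    params <- calw_init(seed = 5)
    flat <- psf4d:::flatten_params(params)
    state <- lapply(flat, function(v) list(m = v * 0, v = v * 0))
    frozen <- c("/sc_w1", "/sc_b1", "/sc_w2", "/sc_b2")
    for (step in 1:25) {
      w <- wrap_params(psf4d:::unflatten_params(flat, params))
      loss <- NULL
      for (tp in train_pairs) {
        kin <- array(0, c(17, 17, 3))
        for (ch in 1:3) kin[, , ch] <- psf4d:::downsample_kernel2(tp$kdict[, , ch, 1, 1])
        gt_half <- map_channels(tp$gt, area_down2_mat)
        li <- ag_mean(ag_pow(ag_sub(calw_forward(tp$y, kin, w$tree), gt_half), 2))
        loss <- if (is.null(loss)) li else ag_add(loss, li)
      }
      ag_backward(loss)
      grads <- lapply(w$leaves, function(n) n$grad)
      if (!enable_correction) for (nm in frozen) grads[[nm]] <- NULL
      upd <- psf4d:::adam_step(flat, grads, state, step, 2e-2, 0.9, 0.999)
      flat <- upd$values; state <- upd$state
    }
    psf4d:::unflatten_params(flat, params)
  }
  p_on <- fit_calw(TRUE)
  p_off <- fit_calw(FALSE)
  phys_resid <- function(p) {
    kc <- calw_corrected_kernels(val$kdict, p)
    kin <- array(0, c(17, 17, 3))
    for (ch in 1:3) kin[, , ch] <- psf4d:::downsample_kernel2(kc[, , ch, 1, 1])
    xh <- map_channels(ag_value(calw_forward(val$y, kin, p)), up_bilinear2_mat)
    ag_value(physics_loss(xh, kc, val$y))
  }
  expect_lt(phys_resid(p_on), phys_resid(p_off))
})
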