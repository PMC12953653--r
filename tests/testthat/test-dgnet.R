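# Degradation-guided attention network

test_that("PDFF with a delta PSF leaves the modulated branch invariant", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  kdel <- array(0, c(5, 5, 3)); kdel[3, 3, ] <- 1
  # delta kernel -> flat unit transfer function -> identity modulation
  M <- Mod(kernel_otf(kdel[, , 1], c(8, 8)))
  expect_lt(max(abs(M - 1)), 1e-12)
  expect_lt(max(abs(ag_freq_filter(x, M) - x)), 1e-12)
  # through pdff_scale the mixing is learned, but shape is preserved
  C <- 6L
  w <- array(rnorm(2 * C * C), c(1, 1, 2 * C, C)); b <- rnorm(C)
  out <- pdff_scale(x, kdel, w, b)
  expect_identical(dim(out), dim(x))
})

test_that("PDFF modulation equals a naive per-pixel DFT oracle", {
  set.seed(2)
  x <- array(rnorm(16), c(4, 4, 1))
  k <- matrix(runif(9), 3); k <- k / sum(k)
  M <- Mod(kernel_otf(k, c(4, 4))); M <- M / M[1, 1]
  res <- ag_freq_filter(x, M)
  # naive double loop: forward DFT, modulate, inverse DFT
  Xf <- matrix(0i, 4, 4)
  for (u in 1:4) for (v in 1:4) {
    acc <- 0i
    for (a in 1:4) for (b in 1:4)
      acc <- acc + x[a, b, 1] * exp(-2i * pi * ((a - 1) * (u - 1) + (b - 1) * (v - 1)) / 4)
    Xf[u, v] <- acc
  }
  Xf <- Xf * M
  orac <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    acc <- 0i
    for (u in 1:4) for (v in 1:4)
      acc <- acc + Xf[u, v] * exp(2i * pi * ((a - 1) * (u - 1) + (b - 1) * (v - 1)) / 4)
    orac[a, b] <- Re(acc) / 16
  }
  expect_lt(max(abs(res[, , 1] - orac)), 1e-10)
})

test_that("zero-initialized DGMSA equals plain channel attention (loop oracle)", {
  set.seed(3)
  for (trial in 1:20) {
    C <- sample(c(4L, 8L), 1)
    heads <- sample(c(1L, 2L), 1)
    bp <- psf4d:::dgt_block_init(C, heads, 2)
    x <- array(rnorm(4 * 4 * C), c(4, 4, C))
    deg <- array(rnorm(4 * 4 * C), c(4, 4, C))
    res <- dgmsa(x, deg, bp, heads)
    orac <- dgmsa_loop_oracle(x, deg, bp, heads)
    expect_lt(max(abs(res - orac)), 1e-5)
    # guidance is inert at zero init: plain attention ignores deg
    res2 <- dgmsa(x, deg * 0, bp, heads)
    expect_lt(max(abs(res - res2)), 1e-12)
  }
})

test_that("nonzero guidance modulates the keys", {
  set.seed(4)
  bp <- psf4d:::dgt_block_init(8L, 2L, 2)
  bp$gd_scale <- matrix(rnorm(64, 0, 0.2), 8, 8)
  bp$gd_bias <- matrix(rnorm(64, 0, 0.2), 8, 8)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  deg <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_lt(max(abs(dgmsa(x, deg, bp, 2L) - dgmsa_loop_oracle(x, deg, bp, 2L))),
            1e-5)
  expect_gt(max(abs(dgmsa(x, deg, bp, 2L) - dgmsa(x, deg * 0, bp, 2L))), 1e-8)
})

test_that("DGMSA maps zero input to zero output and validates heads", {
  bp <- psf4d:::dgt_block_init(8L, 2L, 2)
  deg <- array(rnorm(36 * 8), c(6, 6, 8))
  expect_identical(max(abs(dgmsa(array(0, c(6, 6, 8)), deg, bp, 2L))), 0)
  expect_error(dgmsa(array(0, c(6, 6, 8)), deg, bp, 3L), "heads")
})

test_that("restore doubles the spatial size and is deterministic", {
  params <- list(calw = calw_init(seed = 3),
                 net = dgnet_init(network_config("tiny"), seed = 4))
  s <- fix_samples(1, 800, size = 64)[[1]]
  out1 <- restore_image(s$input_y, s$psf_set, params)
  out2 <- restore_image(s$input_y, s$psf_set, params)
  expect_identical(dim(out1), c(64L, 64L, 3L))
  expect_identical(out1, out2)
  expect_true(all(out1 >= 0 & out1 <= 1))
})

test_that("with a zero head the network reduces to its residual path", {
  cfgN <- network_config("tiny")
  params <- list(calw = calw_init(seed = 3), net = dgnet_init(cfgN, seed = 4))
  s <- fix_samples(1, 810, size = 64)[[1]]
  kern <- center_kernels(s$psf_set)
  out <- restore_image(s$input_y, s$psf_set, params, cfgN, mode = "full")
  ref <- restore_image(s$input_y, s$psf_set, params, cfgN, mode = "wiener")
  expect_identical(out, ref)
})

test_that("the tiny profile stays CPU-trainable (< 300k parameters)", {
  n <- parameter_count(dgnet_init(network_config("tiny"))) +
    parameter_count(calw_init())
  expect_lt(n, 3e5)
  # base profile is larger but constructible
  expect_gt(parameter_count(dgnet_init(network_config("base"))), n)
})

test_that("non-finite activations are reported with their block", {
  cfgN <- network_config("tiny")
  params <- list(calw = calw_init(seed = 3), net = dgnet_init(cfgN, seed = 4))
  params$net$enc1[[1]]$ff_w2[1] <- NaN
  s <- fix_samples(1, 820, size = 64)[[1]]
  expect_error(restore_image(s$input_y, s$psf_set, params, cfgN),
               "non-finite activation after enc1 block 1")
})
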