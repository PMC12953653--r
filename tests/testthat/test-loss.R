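# Physics-constrained loss and image metrics

test_that("physics loss vanishes for the true GT on a noiseless sample", {
  dict <- fix_dict()
  gt <- generate_specimen(3, 128, "texture")
  s <- degrade(gt, dict, 60, 0)
  expect_lt(physics_loss(s$gt_x, s$psf_set, s$input_y), 1e-8)
})

test_that("physics loss of the true GT sits on the noise floor", {
  dict <- fix_dict()
  for (sg in c(2, 6, 10)) {
    vals <- vapply(1:50, function(i) {
      gt <- generate_specimen(200 + i, 64, "texture")
      s <- degrade(gt, dict, 60, sg, seed = 300 + i)
      physics_loss(s$gt_x, s$psf_set, s$input_y)
    }, numeric(1))
    expected <- (sg / 2 / 255)^2
    expect_lt(abs(mean(vals) - expected) / expected, 0.10,
              label = sprintf("sigma = %g", sg))
  }
})

test_that("physics loss handles degenerate restorations", {
  dict <- fix_dict()
  s <- fix_samples(1, 900, size = 64, dict = dict, sigma = 4)[[1]]
  # zero restoration: loss equals mean(y^2)
  expect_equal(physics_loss(s$gt_x * 0, s$psf_set, s$input_y),
               mean(s$input_y^2), tolerance = 1e-10)
  expect_error(physics_loss(s$input_y, s$psf_set, s$input_y), "twice")
})

test_that("MS-SSIM is 1 on identical images and drops with distortion", {
  a <- generate_specimen(4, 64, "cells")$pixels
  expect_equal(ms_ssim(a, a, levels = 3), 1, tolerance = 1e-6)
  b <- clip01(a + array(0.1 * sin(outer(1:64, 1:64) / 5), dim(a)))
  expect_lt(ms_ssim(a, b, levels = 3), 0.999)
  expect_error(ms_ssim(a, a, levels = 5), "too small")
})

test_that("total variation matches hand-enumerated finite differences", {
  expect_identical(tv_loss(array(0.7, c(16, 16, 3))), 0)
  # 4x4 single-channel unit step across one column: 4 unit horizontal
  # differences, 0 vertical -> (4 + 0) / 16
  step <- array(0, c(4, 4, 1)); step[, 3:4, ] <- 1
  expect_equal(tv_loss(step), 4 / 16, tolerance = 1e-12)
})

test_that("the composite loss decomposes and respects one-hot weights", {
  dict <- fix_dict()
  gt <- generate_specimen(5, 64, "cells")
  s <- degrade(gt, dict, 60, 0)
  # perfect restoration: only TV can be nonzero
  l <- total_loss(s$gt_x, s$gt_x, s$input_y, s$psf_set,
                  loss_weights(w_tv = 0), ssim_levels = 2)
  expect_lt(abs(l), 1e-8)
  bd <- attr(l, "breakdown")
  expect_lt(bd["fid"], 1e-12)
  expect_lt(bd["phys"], 1e-8)
  expect_lt(bd["ssim"], 1e-6)
  # one-hot physics weight reproduces physics_loss alone
  s2 <- degrade(gt, dict, 60, 5, seed = 2)
  xh <- map_channels(s2$input_y, up_bilinear2_mat)
  l2 <- total_loss(xh, s2$gt_x, s2$input_y, s2$psf_set,
                   loss_weights(w_fid = 0, w_phys = 1, w_ssim = 0, w_tv = 0),
                   ssim_levels = 2)
  expect_equal(as.numeric(l2), physics_loss(xh, s2$psf_set, s2$input_y),
               tolerance = 1e-12)
  expect_error(loss_weights(w_fid = -1), "non-negative")
  expect_error(loss_weights(0, 0, 0, 0), "positive")
})

test_that("the composite loss equals a straight-line recomputation", {
  # independent recomputation of all four terms on a small fixture with a
  # delta PSF (so the physics operator reduces to plain downsampling)
  set.seed(8)
  gt <- generate_specimen(6, 32, "texture")$pixels
  xh <- clip01(gt + array(rnorm(length(gt), 0, 0.03), dim(gt)))
  y <- clip01(map_channels(gt, area_down2_mat))
  kset <- array(0, c(5, 5, 3, 1, 1)); kset[3, 3, , 1, 1] <- 1
  w <- loss_weights(w_fid = 1, w_phys = 1, w_ssim = 1, w_tv = 1)
  l <- total_loss(xh, gt, y, kset, w, ssim_levels = 1)
  # term 1: MSE
  fid <- mean((xh - gt)^2)
  # term 2: physics (delta kernel -> area downsample only)
  phys <- mean((apply(xh, 3, area_down2_mat) - as.vector(y))^2)
  # term 3: 1 - SSIM via direct loops with the Gaussian window
  g1 <- dnorm(seq(-5, 5), 0, 1.5); g1 <- g1 / sum(g1)
  w2 <- outer(g1, g1)
  conv_same <- function(m) {
    mp <- matrix(0, 42, 42); mp[6:37, 6:37] <- m
    o <- matrix(0, 32, 32)
    for (i in 1:32) for (j in 1:32) o[i, j] <- sum(mp[i:(i + 10), j:(j + 10)] * w2)
    o
  }
  ssim_ch <- vapply(1:3, function(ch) {
    ma <- conv_same(xh[, , ch]); mb <- conv_same(gt[, , ch])
    va <- conv_same(xh[, , ch]^2) - ma^2
    vb <- conv_same(gt[, , ch]^2) - mb^2
    cab <- conv_same(xh[, , ch] * gt[, , ch]) - ma * mb
    lmap <- (2 * ma * mb + 0.01^2) / (ma^2 + mb^2 + 0.01^2)
    cmap <- (2 * cab + 0.03^2) / (va + vb + 0.03^2)
    c(mean(lmap), mean(cmap))
  }, numeric(2))
  ssim_term <- 1 - (mean(ssim_ch[1, ]) * mean(ssim_ch[2, ]) + 1e-8)^1
  # term 4: TV
  tv <- (sum(abs(xh[, -1, ] - xh[, -32, ])) + sum(abs(xh[-1, , ] - xh[-32, , ]))) /
    length(xh)
  expect_equal(as.numeric(l), fid + phys + ssim_term + tv, tolerance = 1e-6)
})

test_that("PSNR and SSIM closed forms and symmetry", {
  a <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(psnr(a, a), 100)
  # uniform 16-level offset on the 8-bit scale: MSE = 256
  x8 <- array(100, c(16, 16)); y8 <- x8 + 16
  expect_equal(psnr(x8, y8, max_val = 255), 10 * log10(255^2 / 256),
               tolerance = 1e-12)
  expect_equal(round(psnr(x8, y8, max_val = 255), 2), 24.05)
  b <- clip01(a + 0.05)
  expect_equal(psnr(a, b), psnr(b, a), tolerance = 1e-10)
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-10)
})
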