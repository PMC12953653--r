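# Forward degradation model: blur -> noise -> downsample

delta_dict <- function(dict) {
  dict$kernels[] <- 0
  dict$kernels[, , , , 17, 17] <- 1
  dict
}

test_that("delta kernels and zero noise reduce to area averaging", {
  d <- delta_dict(fix_dict())
  gt <- generate_specimen(3, 128, "cells")
  s <- degrade(gt, d, 60, 0)
  ref <- clip01(map_channels(gt$pixels, area_down2_mat))
  expect_lt(max(abs(s$input_y - ref)), 1e-6)
  expect_identical(dim(s$input_y), c(64L, 64L, 3L))
  expect_identical(dim(s$gt_x), c(128L, 128L, 3L))
})

test_that("uniform kernels match whole-image convolution in the interior", {
  dict <- fix_dict()
  k1 <- dict$kernels[2, 3, 4, 2, , ]
  duni <- dict
  for (l in 1:3) for (r in 1:6) for (cc in 1:8) for (w in 1:3)
    duni$kernels[l, r, cc, w, , ] <- k1
  gt <- generate_specimen(4, 128, "texture")   # 2 x 2 tiles of 64 px
  s <- degrade(gt, duni, 60, 0)
  oracle <- map_channels(gt$pixels, function(m) {
    mp <- pad_reflect_mat(m, 32)
    conv <- Re(psf4d:::ifft2(psf4d:::fft2(mp) * kernel_otf(k1, dim(mp))))
    conv[33:160, 33:160]
  })
  oracle_y <- clip01(map_channels(oracle, area_down2_mat))
  interior <- 5:60
  expect_lt(max(abs(s$input_y - oracle_y)[interior, interior, ]), 1e-3)
})

test_that("degradation is seeded and byte-stable", {
  dict <- fix_dict()
  gt <- generate_specimen(5, 64, "grating")
  a <- degrade(gt, dict, 100, 6, seed = 9)
  b <- degrade(gt, dict, 100, 6, seed = 9)
  expect_identical(a$input_y, b$input_y)
  c2 <- degrade(gt, dict, 100, 6, seed = 10)
  expect_gt(max(abs(a$input_y - c2$input_y)), 0)
  expect_error(degrade(gt, dict, 100, 1), "sigma")
  expect_error(degrade(gt, dict, 100, 11), "sigma")
})

test_that("blur is linear and conserves mean intensity before noise", {
  dict <- fix_dict()
  gt <- generate_specimen(6, 128, "texture")$pixels
  s1 <- degrade(gt, dict, 60, 0)
  s2 <- degrade(gt * 0.5, dict, 60, 0)
  expect_lt(max(abs(s1$input_y * 0.5 - s2$input_y)), 1e-6)
  interior <- 9:56
  expect_lt(abs(mean(s1$input_y[interior, interior, ]) -
                mean(map_channels(gt, area_down2_mat)[interior, interior, ])),
            1e-3)
})

test_that("realized noise level matches sigma after 2x2 averaging", {
  dict <- fix_dict()
  gt <- generate_specimen(8, 256, "texture")
  for (sg in c(2, 6, 10)) {
    noiseless <- degrade(gt, dict, 60, 0)
    noisy <- degrade(gt, dict, 60, sg, seed = 21)
    resid <- (noisy$input_y - noiseless$input_y) * 255
    expect_lt(abs(stats::sd(resid) - sg / 2) / (sg / 2), 0.03)
  }
})

test_that("dihedral augmentation preserves the degradation relation", {
  dict <- fix_dict()
  gt <- generate_specimen(7, 128, "cells")
  pair <- degrade(gt, dict, 60, 5, seed = 3)
  aug <- augment_sample(pair)
  expect_length(aug, 8)
  expect_identical(aug[[1]]$input_y, pair$input_y)
  # horizontal flip is an involution
  flip2 <- dihedral_apply(dihedral_apply(pair$gt_x, 5), 5)
  expect_identical(flip2, pair$gt_x)
  residual <- function(s) {
    blur <- patch_convolve(s$gt_x, s$psf_set, s$window$tile)
    mean((map_channels(blur, area_down2_mat) - s$input_y)^2)
  }
  r0 <- residual(aug[[1]])
  for (k in 2:8) expect_lt(abs(residual(aug[[k]]) - r0), 1e-6)
})

test_that("build_dataset writes a consistent, reproducible manifest", {
  dict <- fix_dict()
  out1 <- file.path(tempdir(), "ds1"); out2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  m1 <- build_dataset(2, dict, out1, zoom_levels = c(10, 100), seed = 5,
                      size = 64)
  # n_gt x levels x 8 dihedral augmentations
  expect_identical(nrow(m1), 2L * 2L * 8L)
  expect_true(all(file.exists(file.path(out1, m1$input))))
  expect_true(all(file.exists(file.path(out1, m1$gt))))
  expect_true(all(m1$sigma >= 2 & m1$sigma <= 10))
  # pairs on disk reload at the right shapes and dynamic range
  img <- read_image(file.path(out1, m1$input[1]))
  expect_identical(dim(img), c(32L, 32L, 3L))
  m2 <- build_dataset(2, dict, out2, zoom_levels = c(10, 100), seed = 5,
                      size = 64)
  m1$input <- NULL; m2$input <- NULL; m1$gt <- NULL; m2$gt <- NULL
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  h1 <- tools::md5sum(file.path(out1, "manifest.csv"))
  h2 <- tools::md5sum(file.path(out2, "manifest.csv"))
  expect_identical(unname(h1), unname(h2))
})
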