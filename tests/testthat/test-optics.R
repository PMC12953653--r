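# Liquid-lens focal length and two-group zoom magnification

test_that("focal length follows the Young-Lippmann relation", {
  # zero voltage: the voltage term vanishes
  lens <- liquid_lens()
  f0 <- focal_length(lens, 0)
  expect_equal(f0, -lens$aperture_D * (lens$n_conductive - lens$n_nonconductive) /
                 cos(lens$theta0))
  # frozen hand evaluation: D = 5.8 mm, n_c - n_n = -0.2, theta0 = 120 deg,
  # eps*eps0/(2 H gamma) = 1e-3 V^-2, U = 30 V -> f = 1.16e-3 / 0.4 = 2.9 mm
  lens2 <- liquid_lens(aperture_D = 5.8e-3, n_conductive = 1.3,
                       n_nonconductive = 1.5, theta0 = 2 * pi / 3,
                       eps_rel = 1e-3, eps0 = 1, thickness_H = 0.5,
                       tension_gamma = 1)
  expect_equal(focal_length(lens2, 30), 2.9e-3, tolerance = 1e-12)
  # the voltage-dependent denominator term is quadratic in U
  d_of <- function(U) 1 / focal_length(lens2, U) - 1 / focal_length(lens2, 0)
  expect_equal(d_of(60) / d_of(30), 4, tolerance = 1e-9)
})

test_that("optical power is affine in the squared voltage", {
  lens <- liquid_lens()
  U <- seq(0, 60, length.out = 50)
  pw <- optical_power(lens, U)
  fit <- stats::lm(pw ~ I(U^2))
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
  # slope agrees with the analytic coefficient
  slope <- lens$eps_rel * lens$eps0 / (2 * lens$thickness_H * lens$tension_gamma) /
    (-lens$aperture_D * (lens$n_conductive - lens$n_nonconductive))
  expect_equal(unname(stats::coef(fit)[2]), slope, tolerance = 1e-8)
})

test_that("singular focus voltage is reported", {
  # cos(theta0) = -0.5 cancels the voltage term at U = sqrt(0.5/1e-3)
  lens <- liquid_lens(theta0 = 2 * pi / 3, eps_rel = 1e-3, eps0 = 1,
                      thickness_H = 0.5, tension_gamma = 1)
  u_sing <- sqrt(0.5 / 1e-3)
  expect_error(focal_length(lens, u_sing), "singular focus")
})

test_that("system magnification matches the two-group formula", {
  # both factors reduce to 1
  expect_equal(system_magnification(zoom_config(0, 0, 0.05, 0.1)), 1)
  # front power zero: beta = (1 + Phi_c * u)^-1
  for (pc in c(-3, 2, 10))
    expect_equal(system_magnification(zoom_config(0, pc, 0.05, 0.1)),
                 1 / (1 + pc * 0.05), tolerance = 1e-12)
  # frozen hand evaluation: 2 * 1.5 = 3
  expect_equal(system_magnification(zoom_config(10, 20, 0.05, 0.1)), 3,
               tolerance = 1e-12)
})

test_that("singular configurations name the offending factor", {
  expect_error(system_magnification(zoom_config(20, 0, 0.05, 0.1)),
               "1 - Phi_f\\*u")
  expect_error(system_magnification(zoom_config(-20, 5, 0.05, 0.1)),
               "Phi_f \\+ 1/u")
  # rear bracket zero: Phi_f = 0, Phi_c * u = -1
  expect_error(system_magnification(zoom_config(0, -20, 0.05, 0.1)),
               "rear bracket")
})

test_that("magnification derivatives match finite differences", {
  beta_of <- function(pf, pc) system_magnification(zoom_config(pf, pc, 0.05, 0.1))
  pf <- 4; pc <- 7; u <- 0.05; d <- 0.1
  t1 <- 1 - pf * u; t2 <- pf + 1 / u; t3 <- 1 + pc / t2 - pf * d
  b <- 1 / (t1 * t3)
  d_pc <- -b / t3 / t2
  d_pf <- -b * (-u / t1 + (-pc / t2^2 - d) / t3)
  h <- 1e-6
  expect_equal((beta_of(pf, pc + h) - beta_of(pf, pc - h)) / (2 * h), d_pc,
               tolerance = 1e-6)
  expect_equal((beta_of(pf + h, pc) - beta_of(pf - h, pc)) / (2 * h), d_pf,
               tolerance = 1e-6)
})

test_that("solve_powers inverts system_magnification", {
  # fixed-front closed cases
  s <- solve_powers(1, zoom_config(0, 0, 0.05, 0.1), power_bounds = c(-5, 30),
                    fix_front = TRUE)
  expect_equal(s$power_rear, 0, tolerance = 1e-8)
  s3 <- solve_powers(3, zoom_config(10, 0, 0.05, 0.1), power_bounds = c(-5, 30),
                     fix_front = TRUE)
  expect_equal(s3$power_rear, 20, tolerance = 1e-6)
  # round-trip identity over random feasible targets
  set.seed(42)
  targets <- exp(stats::runif(100, log(5), log(110)))
  for (tg in targets) {
    cfg <- solve_powers(tg)
    expect_lt(abs(system_magnification(cfg) - tg) / tg, 1e-6)
  }
})

test_that("infeasible targets report the achievable range", {
  expect_error(solve_powers(1e5), "infeasible magnification")
  expect_error(solve_powers(1e5), "achievable")
})

test_that("magnification_grid is a geometric ladder with exact endpoints", {
  cfgs <- magnification_grid(10.6, 101.4, 2)
  expect_identical(attr(cfgs, "betas"), c(10.6, 101.4))
  tb <- zoom_table(10, 100, 6)
  expect_s3_class(tb, "tbl_df")
  expect_identical(tb$beta[c(1, 6)], c(10, 100))
  # geometric spacing: constant ratio
  expect_equal(diff(log(tb$beta)), rep(log(10) * 2 / 5, 5) / 2, tolerance = 1e-12)
  # each level round-trips
  for (i in seq_len(nrow(tb))) {
    b <- system_magnification(zoom_config(tb$power_front[i], tb$power_rear[i]))
    expect_lt(abs(b - tb$beta[i]) / tb$beta[i], 1e-6)
  }
  expect_error(magnification_grid(100, 10, 3), "beta_min")
})
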