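coarse_fixed <- corr_grid("fixed", alpha_step = 0.05)
coarse_drift <- corr_grid("drifting", gamma = 0.98, drift_noise_ratio = 0.7,
                          alpha_step = 0.05)

test_that("correlation grids are symmetric with unit diagonal", {
  for (g in list(coarse_fixed, coarse_drift)) {
    for (surf in list(g$rho_value, g$rho_pe)) {
      expect_lt(max(abs(surf - t(surf))), 1e-12)
      expect_lt(max(abs(diag(surf) - 1)), 1e-12)
      expect_true(all(surf >= -1 & surf <= 1))
    }
  }
})

test_that("grid entries equal the scalar closed forms", {
  a <- coarse_fixed$alpha_grid
  i <- 3; j <- 17
  expect_equal(coarse_fixed$rho_value[i, j], value_corr_fixed(a[i], a[j]))
  expect_equal(coarse_drift$rho_pe[i, j],
               pe_corr_drifting(a[i], a[j], 0.98, 0.7))
  one <- corr_grid("fixed", alpha_min = 0.5, alpha_max = 0.5)
  expect_equal(one$rho_value, matrix(1))
  expect_equal(one$rho_pe, matrix(1))
})

test_that("the fixed-regime surfaces have the documented extremes", {
  fine <- corr_grid("fixed", alpha_step = 0.001)
  # PE surface minimum sits at the (alpha_min, 1) corner, above 1/sqrt(2)
  expect_gte(min(fine$rho_pe), 1 / sqrt(2))
  idx <- which(fine$rho_pe == min(fine$rho_pe), arr.ind = TRUE)
  corners <- fine$alpha_grid[as.vector(idx)]
  expect_setequal(round(corners, 3), c(0.001, 1))
  # value surface minimum heads to 0 as alpha_min does
  m1 <- min(corr_grid("fixed", alpha_min = 0.01, alpha_step = 0.01)$rho_value)
  m2 <- min(corr_grid("fixed", alpha_min = 0.001, alpha_step = 0.01)$rho_value)
  expect_lt(m2, m1)
  expect_lt(m2, 0.1)
})

test_that("t grids are monotone images of the correlation grids", {
  tg <- t_grid(coarse_fixed, cnr = 1, n_trials = 50)
  expect_true(all(tg$sig_pe))
  ord_rho <- order(coarse_fixed$rho_value)
  expect_true(all(diff(tg$t_value[ord_rho]) >= -1e-12))
  tiny <- t_grid(coarse_fixed, cnr = 1e-8, n_trials = 50)
  expect_lt(max(abs(tiny$t_value)), 1e-6)
  expect_false(any(tiny$sig_value))
})

test_that("the insensitivity metric counts strict exceedances", {
  expect_equal(insensitivity_metric(matrix(0, 3, 3)), 0)
  expect_equal(insensitivity_metric(matrix(1, 3, 3)), 1)
  expect_equal(insensitivity_metric(matrix(c(0.7, 0.71, 0.69, 1), 2)), 0.5)
  expect_equal(insensitivity_metric(coarse_fixed$rho_pe), 1)
  mv <- insensitivity_metric(coarse_fixed$rho_value)
  expect_gt(mv, 0)
  expect_lt(mv, 1)
  # monotone nonincreasing in the threshold
  thresholds <- seq(0.1, 0.95, 0.05)
  ms <- vapply(thresholds, insensitivity_metric,
               grid_surface = coarse_fixed$rho_value, numeric(1))
  expect_true(all(diff(ms) <= 0))
  expect_error(insensitivity_metric(matrix(numeric(0), 0, 0)), "Empty")
  expect_error(insensitivity_metric(matrix(c(0.5, 1.5), 1)), "\\[-1, 1\\]")
})

test_that("the design scan recovers the regime orderings", {
  scan <- design_scan(gamma_grid = c(0.1, 0.5, 0.98),
                      ratio_grid = c(0, 0.7, 4.5),
                      alpha_step = 0.05, alpha_min = 0.05)
  # zero-drift column equals the fixed-regime metrics for every gamma
  match_grid <- corr_grid("fixed", alpha_min = 0.05, alpha_step = 0.05)
  fixed_v <- insensitivity_metric(match_grid$rho_value)
  fixed_p <- insensitivity_metric(match_grid$rho_pe)
  zero <- scan[scan$drift_noise_ratio == 0, ]
  expect_equal(zero$metric_value, rep(fixed_v, 3))
  expect_equal(zero$metric_pe, rep(fixed_p, 3))
  # slow wide drift: PEs more sensitive than values
  slow <- scan[scan$gamma == 0.98 & scan$drift_noise_ratio == 0.7, ]
  expect_lt(slow$metric_pe, slow$metric_value)
  # fast noisy drift mimics the fixed regime: ordering reversed
  fast <- scan[scan$gamma == 0.1 & scan$drift_noise_ratio == 4.5, ]
  expect_gt(fast$metric_pe, fast$metric_value)
})

test_that("diagonal slices are symmetric and sharpen with CNR and T", {
  sl <- diagonal_slice(difference_grid = (-9:9) / 10,
                       cnr = c(1, 10, 100), n_trials = c(10, 50, 200),
                       regime = "fixed")
  expect_true(all(sl$valid))
  # symmetry in d
  for (cc in c(1, 10)) {
    sub <- sl[sl$cnr == cc & sl$n_trials == 50, ]
    expect_equal(sub$t_value, rev(sub$t_value), tolerance = 1e-12)
    expect_equal(sub$t_pe, rev(sub$t_pe), tolerance = 1e-12)
  }
  # peak sharpness t(0) - t(0.9) grows with CNR (fixed T) and T (fixed CNR)
  sharp <- function(cc, nn, col) {
    sub <- sl[sl$cnr == cc & sl$n_trials == nn, ]
    sub[[col]][sub$d == 0] - sub[[col]][sub$d == 0.9]
  }
  expect_true(all(diff(vapply(c(1, 10, 100), sharp, numeric(1),
                              nn = 50, col = "t_value")) > 0))
  expect_true(all(diff(vapply(c(10, 50, 200), sharp, numeric(1),
                              cc = 1, col = "t_value")) > 0))
  # d = 0 attains the slice maximum (rho = 1 point)
  sub <- sl[sl$cnr == 1 & sl$n_trials == 50, ]
  expect_equal(max(sub$t_pe), sub$t_pe[sub$d == 0])

  # constraint violations are flagged, shape preserved
  wide <- diagonal_slice(difference_grid = c(-1.5, 0, 1.5), cnr = 1,
                         n_trials = 50, regime = "fixed")
  expect_equal(wide$valid, c(FALSE, TRUE, FALSE))
  expect_equal(sum(is.na(wide$t_value)), 2)
  expect_equal(nrow(wide), 3)
})

test_that("tidy() and autoplot() views of grids are consistent", {
  td <- tidy(coarse_fixed)
  expect_equal(nrow(td), length(coarse_fixed$alpha_grid)^2)
  row <- td[td$alpha_g == 0.101 & td$alpha_f == 0.901, ]
  expect_equal(row$rho_value, value_corr_fixed(0.101, 0.901))
  tg <- t_grid(coarse_fixed, 1, 50)
  tt <- tidy(tg)
  expect_true(all(c("t_value", "t_pe", "sig_value", "sig_pe") %in% names(tt)))
  expect_s3_class(autoplot(coarse_fixed), "ggplot")
  expect_s3_class(autoplot(tg), "ggplot")
  expect_s3_class(plot_design_scan(design_scan(c(0.5), c(0.5, 1),
                                               alpha_step = 0.1)), "ggplot")
  expect_s3_class(plot_diagonal_slice(
    diagonal_slice(seq(-0.5, 0.5, 0.25), 1, 50, "fixed")), "ggplot")
})
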