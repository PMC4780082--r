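test_that("Lorentzian peak height, half width and integral follow the area form", {
  expect_equal(lorentzian(1700, 1700, pi / 2, 1), 1)
  A <- 3; w <- 6; xc <- 1660
  peak <- lorentzian(xc, xc, A, w)
  expect_equal(peak, 2 * A / (pi * w))
  expect_equal(lorentzian(xc + w / 2, xc, A, w), peak / 2)
  expect_equal(lorentzian(xc - w / 2, xc, A, w), peak / 2)

  q <- integrate(function(x) lorentzian(x, xc, A, w),
                 xc - 1e4 * w, xc + 1e4 * w, rel.tol = 1e-9,
                 subdivisions = 2000L)
  expect_lt(abs(q$value - A) / A, 1e-4)
  expect_error(lorentzian(1, 1, 1, 0), "positive")
})

test_that("model_eval sums bands linearly and cancels mirrored pairs", {
  grid <- seq(1700, 1650, by = -0.5)
  b1 <- data.frame(xc = 1680, A = 2, w = 7)
  expect_equal(model_eval(b1, grid)$values,
               lorentzian(grid, 1680, 2, 7))
  mirror <- rbind(b1, data.frame(xc = 1680, A = -2, w = 7))
  expect_equal(max(abs(model_eval(mirror, grid)$values)), 0)
  b2 <- data.frame(xc = c(1680, 1660), A = c(2, 1), w = 7)
  expect_equal(model_eval(b2, grid)$values,
               model_eval(b2[1, ], grid)$values +
                 model_eval(b2[2, ], grid)$values)
})

test_that("free-parameter bookkeeping matches the constraint algebra", {
  expect_identical(count_free_parameters(bluf_dd_config()), 5L)
  one_free <- fit_config(single_band(1680, 1), window = c(1650, 1700),
                         shared_fwhm = FALSE)
  expect_identical(count_free_parameters(one_free), 3L)
  all_fixed <- fit_config(single_band(1680, 1, fix_center = TRUE,
                                      fix_area = TRUE),
                          window = c(1650, 1700), fix_fwhm = TRUE)
  expect_identical(count_free_parameters(all_fixed), 0L)
  dd <- noiseless_dd()
  expect_error(fit_bands(dd, all_fixed), "no free parameters")
})

test_that("noiseless refit recovers the generator within 0.1 cm^-1 and 0.1%", {
  dd <- noiseless_dd(step = 0.5)
  # starts displaced well inside the +-5 cm^-1 / +-50% robustness envelope
  cfg <- bluf_dd_config(hidden_start = c(1694.5, 1668), areas = c(1, 0.8, 1.2),
                        fwhm = 10.5)
  fit <- fit_bands(dd, cfg, seed = 5)
  est <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(est[["center.hidden_CN.pos"]] - 1691), 0.1)
  expect_lt(abs(est[["center.hidden_CN.neg"]] - 1672), 0.1)
  expect_lt(abs(est[["fwhm"]] - 7), 0.1)
  expect_lt(abs(est[["area.dark_CO"]] - 1.3) / 1.3, 1e-3)
  expect_lt(abs(est[["area.hidden_CN"]] - 0.8) / 0.8, 1e-3)
  expect_identical(fit$free_parameter_count, 5L)
})

test_that("a single free area reproduces the linear least-squares solution", {
  grid <- seq(1700, 1650, by = -0.5)
  set.seed(31)
  y <- lorentzian(grid, 1675, 1.7, 7) + rnorm(length(grid), 0, 0.01)
  dd <- ir_spectrum(grid, y)
  cfg <- fit_config(single_band(1675, 1, fix_center = TRUE),
                    window = c(1650, 1700), fwhm = 7, fix_fwhm = TRUE,
                    n_starts = 1)
  fit <- fit_bands(dd, cfg)
  phi <- lorentzian(grid, 1675, 1, 7)
  a_hat <- sum(phi * y) / sum(phi * phi)   # normal-equations oracle
  expect_equal(unname(coef(fit)), a_hat, tolerance = 1e-8)
})

test_that("the three-pair fit never fits worse than the nested two-pair fit", {
  grid <- seq(1700, 1650, by = -0.5)
  for (seed in c(2, 9)) {
    set.seed(seed)
    y <- model_eval(truth_bands(), grid)$values +
      rnorm(length(grid), 0, 0.01)
    dd <- ir_spectrum(grid, y)
    cfg3 <- bluf_dd_config()
    cfg2 <- fit_config(
      band_pair(1697, 1689, area = 1, fix_centers = TRUE, fix_area = TRUE,
                label = "flavin_C4O_light"),
      band_pair(1660, 1667, area = 1.3, fix_centers = TRUE,
                label = "dark_CO"),
      window = c(1650, 1700), fwhm = 7)
    rss3 <- deviance(fit_bands(dd, cfg3, seed = 1))
    rss2 <- deviance(fit_bands(dd, cfg2, seed = 1))
    expect_lte(rss3, rss2 + 1e-12)
  }
})

test_that("center recovery under 1% peak noise stays unbiased", {
  grid <- seq(1700, 1650, by = -0.5)
  mu <- model_eval(truth_bands(), grid)$values
  sd_noise <- 0.01 * max(abs(mu))
  set.seed(77)
  cfg <- bluf_dd_config(hidden_start = c(1693, 1670), fwhm = 8,
                        n_starts = 2)
  biases <- replicate(40, {
    dd <- ir_spectrum(grid, mu + rnorm(length(grid), 0, sd_noise))
    est <- coef(fit_bands(dd, cfg))
    c(est[["center.hidden_CN.pos"]] - 1691,
      est[["center.hidden_CN.neg"]] - 1672)
  })
  expect_lt(abs(median(biases[1, ])), 0.2)
  expect_lt(abs(median(biases[2, ])), 0.2)
})

test_that("bandfit methods expose the model consistently", {
  dd <- noiseless_dd()
  fit <- fit_bands(dd, bluf_dd_config(), seed = 1)
  expect_s3_class(fit, "bandfit")
  expect_equal(nobs(fit), 101L)
  expect_equal(df.residual(fit), 96L)
  expect_equal(fitted(fit) + residuals(fit), fit$data$values)
  pr <- predict(fit)
  expect_equal(pr$values, fitted(fit), tolerance = 1e-12)
  sm <- summary(fit)
  expect_named(fit$coefficients)
  expect_equal(rownames(sm$coefficients), names(coef(fit)))
  sims <- simulate(fit, nsim = 2, seed = 8, noise_sd = 1e-3)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$values, sims[[2]]$values))
  expect_output(print(fit), "free parameters")
})
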