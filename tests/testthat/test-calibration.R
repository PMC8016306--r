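# Calibration recovery on deliberately tiny forward models (the acceptance
# suite repeats the recovery at the documented resolutions).

tiny_cfg <- calibration_config(n_interface = 21L, divisions = c(1L, 1L, 2L),
                               deflection_depths = c(0.3, 1.2),
                               fd_displacements = c(0.3, 0.6))

test_that("R squared: exact fits, mean-level predictions, hand-computed case", {
  obs <- c(1, 2, 3, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  pred <- c(1.5, 2, 2.5, 5)
  expect_equal(r_squared(pred, obs),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_error(r_squared(1:3, c(2, 2, 2)), "constant")
  expect_error(r_squared(1:3, 1:4), "aligned")
})

test_that("layer-ratio fit recovers a generating grid point", {
  truth <- c(40, 20, 10) # ratios 0.5, 0.25
  targets <- gen_calibration_targets(truth, cfg = tiny_cfg)
  grid <- list(dermis = c(0.25, 0.5, 0.75), subcutaneous = c(0.125, 0.25, 0.375))
  fit <- fit_layer_ratios(targets, grid, cfg = tiny_cfg)
  i_truth <- which(fit$grid$dermis == 0.5 & fit$grid$subcutaneous == 0.25)
  expect_gt(fit$grid$r2[i_truth], 0.999) # self-consistency: R^2 = 1 at truth
  expect_equal(max(fit$grid$r2), fit$grid$r2[i_truth])
  # noisy targets: selected ratios within one grid spacing of truth
  noisy <- gen_calibration_targets(truth, noise_sd = 0.03, seed = 8,
                                   cfg = tiny_cfg)
  fit2 <- fit_layer_ratios(noisy, grid, cfg = tiny_cfg, threshold = 0.8)
  expect_lte(abs(fit2$selected[["dermis"]] - 0.5), 0.5)
  expect_lte(abs(fit2$selected[["subcutaneous"]] - 0.25), 0.25)
})

test_that("pure-noise targets fail the fit with the best R^2 reported", {
  targets <- gen_calibration_targets(c(40, 20, 10), cfg = tiny_cfg)
  set.seed(12)
  for (k in seq_along(targets$deflection_curves)) {
    targets$deflection_curves[[k]]$deflection_mm <-
      rnorm(nrow(targets$deflection_curves[[k]]))
  }
  expect_error(
    fit_layer_ratios(targets, list(dermis = c(0.25, 0.5),
                                   subcutaneous = c(0.25, 0.5)),
                     cfg = tiny_cfg),
    "fit-failure")
})

test_that("grid ordering does not change the selected ratios", {
  truth <- c(40, 20, 10)
  targets <- gen_calibration_targets(truth, cfg = tiny_cfg)
  g1 <- list(dermis = c(0.25, 0.5, 0.75), subcutaneous = c(0.125, 0.25, 0.375))
  g2 <- list(dermis = rev(g1$dermis), subcutaneous = rev(g1$subcutaneous))
  f1 <- fit_layer_ratios(targets, g1, cfg = tiny_cfg)
  f2 <- fit_layer_ratios(targets, g2, cfg = tiny_cfg)
  expect_equal(f1$selected, f2$selected)
})

test_that("global scale is recovered and obeys modulus-force homogeneity", {
  truth <- c(40, 20, 10)
  targets <- gen_calibration_targets(truth, cfg = tiny_cfg)
  ratios <- c(dermis = 0.5, subcutaneous = 0.25)
  mod <- scale_to_force_displacement(ratios, targets$fd_curve, cfg = tiny_cfg)
  expect_equal(unname(mod["epidermis"]), 40, tolerance = 0.1)
  expect_equal(unname(mod["dermis"]), 20, tolerance = 0.1)
  # doubling all target forces doubles the fitted scale
  fd2 <- targets$fd_curve
  fd2$force_N <- 2 * fd2$force_N
  mod2 <- scale_to_force_displacement(ratios, fd2, cfg = tiny_cfg)
  expect_equal(attr(mod2, "scale"), 2 * attr(mod, "scale"), tolerance = 1e-6)
  expect_error(scale_to_force_displacement(ratios, NULL, cfg = tiny_cfg),
               "data error")
  bad <- data.frame(displacement_mm = c(0.3, 0.6), force_N = c(1, 0.5))
  expect_error(scale_to_force_displacement(ratios, bad, cfg = tiny_cfg),
               "monotone")
})
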