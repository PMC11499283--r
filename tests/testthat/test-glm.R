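test_that("ridge fit recovers a simulated TF kernel and stays silent on null units", {
  ses <- simulate_stimulus_sessions(200, seed = 52)
  beh <- simulate_random_licks(ses, 0.08, seed = 53)
  cfg <- glm_design_config(groups = c("tf", "trial_start"))
  d <- build_design(ses, beh, config = cfg)
  units <- make_unit_config(2, baseline_rate = c(15, 15),
                            tf_gain = c(2, 0), tf_width = 0.3)
  pop <- suppressWarnings(simulate_population(ses, beh, units, seed = 54))
  # coding unit: fitted kernel correlates with the generative boxcar
  y1 <- design_spike_counts(pop, 1, d)
  fit1 <- fit_poisson_ridge(d, y1, seed = 55)
  k1 <- glm_kernel(fit1, d, "tf")
  truth <- c(units$tf_kernel[[1]], rep(0, 30 - length(units$tf_kernel[[1]])))
  expect_gt(cor(k1$weight, truth), 0.9)
  expect_length(fit1$lambda, 10)
  expect_true(all(fit1$lambda %in% glm_lambda_grid()))
  # null unit: tiny weights and chance-level held-out prediction
  y2 <- design_spike_counts(pop, 2, d)
  fit2 <- fit_poisson_ridge(d, y2, seed = 55)
  k2 <- glm_kernel(fit2, d, "tf")
  expect_lt(max(abs(k2$weight)), max(abs(k1$weight)) / 3)
  expect_lt(abs(cor(fit2$cv_pred, y2)), 0.05)
})

test_that("the nested test rejects a vacuous reduction", {
  ses <- simulate_stimulus_sessions(30, seed = 56)
  beh <- simulate_random_licks(ses, 0.1, seed = 57)
  cfg <- glm_design_config(groups = c("tf", "trial_start"))
  d <- build_design(ses, beh, config = cfg)
  units <- make_unit_config(1, baseline_rate = 10, tf_gain = 1.5,
                            tf_width = 0.3)
  pop <- simulate_population(ses, beh, units, seed = 58)
  y <- design_spike_counts(pop, 1, d)
  fit <- fit_poisson_ridge(d, y, seed = 59)
  pl <- ses$pulses[ses$pulses$epoch == "baseline", ]
  ev <- list(fast = pl[pl$log2_tf > 0.125, c("trial_id", "t")],
             slow = pl[pl$log2_tf < -0.125, c("trial_id", "t")])
  # reduced model identical to the full one: residual prediction is zero,
  # criterion 2 cannot pass
  res <- nested_model_test(fit, fit, y, d, ev, c(-0.15, 0.75))
  expect_false(res$flag)
  expect_gte(res$p_residual, 0.01)
})

test_that("kernel metrics compute peak, flip and interpolated FWHM", {
  # triangular kernel peaking at 0.3 s with base 0-0.6 s
  lag <- seq(0, 1.45, by = 0.05)
  tri <- pmax(0, 1 - abs(lag - 0.3) / 0.3)
  m <- kernel_metrics(tri, lag)
  expect_equal(m$peak_time, 0.3)
  expect_equal(m$fwhm, 0.3, tolerance = 1e-9)
  expect_false(m$flipped)
  # Gaussian kernel: FWHM = 2 sqrt(2 ln 2) sigma
  g <- exp(-(lag - 0.5)^2 / (2 * 0.1^2))
  expect_equal(kernel_metrics(g, lag)$fwhm, 2 * sqrt(2 * log(2)) * 0.1,
               tolerance = 0.01)
  # sign symmetry
  mneg <- kernel_metrics(-tri, lag)
  expect_true(mneg$flipped)
  expect_equal(mneg$fwhm, m$fwhm)
  expect_equal(mneg$peak_time, m$peak_time)
  expect_true(is.na(kernel_metrics(rep(0, 30))$peak_time))
})

test_that("change-kernel rise times and the magnitude regression match oracles", {
  lag <- seq(0, 1.95, by = 0.05)
  # linear ramp to max at T: crossings at T/3, T/2, 2T/3 average to T/2
  ramp <- function(T) pmin(lag / T, 1)
  rt <- tfpulse:::kernel_rise_time(ramp(1.2), lag)
  expect_equal(rt, 0.6, tolerance = 1e-9)
  # step kernel rises at t0
  step <- as.numeric(lag >= 0.4)
  expect_lt(abs(tfpulse:::kernel_rise_time(step, lag) - 0.4), 0.05)
  # constructed rise times {0.6, 0.4, 0.2} at magnitudes {0.32,1,2} octaves
  mags <- 2^c(0.32, 1, 2)
  kern <- lapply(c(0.6, 0.4, 0.2), function(T)
    matrix(rep(ramp(2 * T), each = 5), nrow = 5, byrow = FALSE))
  out <- change_kernel_ramp(kern, mags, lag, n_boot = 50, seed = 60)
  oracle <- unname(coef(lm(c(0.6, 0.4, 0.2) ~ log2(mags)))[2])
  expect_equal(out$slope, oracle, tolerance = 1e-9)
  expect_true(out$ci[1] <= out$slope && out$slope <= out$ci[2])
})

test_that("focality index handles confined, uniform and mixed encodings", {
  expect_equal(focality_from_proportions(c(0.5, 0, 0)), 1)
  expect_equal(focality_from_proportions(rep(0.3, 8)), 1 / 8)
  expect_equal(focality_from_proportions(c(0.4, 0.1, 0.1)), 0.5)
  expect_true(is.na(focality_from_proportions(c(0, 0))))
  # unit-level interface with bootstrap CI
  area <- rep(c("a", "b", "c"), each = 40)
  coding <- c(rep(TRUE, 30), rep(FALSE, 10), rep(c(TRUE, FALSE), 20),
              rep(FALSE, 40))
  f <- focality_index(coding, area, n_boot = 300, seed = 61)
  expect_equal(f$F, focality_from_proportions(f$p_a))
  expect_gte(f$F, 1 / 3)
  expect_lte(f$F, 1)
  # concentrated encoding scores higher than distributed encoding
  f_conc <- focality_index(c(rep(TRUE, 40), rep(FALSE, 80)), area,
                           n_boot = 50, seed = 62)
  f_unif <- focality_index(rep(c(TRUE, FALSE), 60), area,
                           n_boot = 50, seed = 63)
  expect_gt(f_conc$F, f_unif$F)
})
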