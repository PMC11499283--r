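test_that("psychometric rates count hits over eligible trials only", {
  beh <- data.frame(
    outcome = c(rep("hit", 8), rep("miss", 2), rep("early", 5), "abort"),
    change_magnitude = c(rep(2, 10), rep(2, 5), 2))
  pc <- psychometric_curve(beh)
  expect_equal(pc$rate, 0.8)
  expect_equal(pc$n_eligible, 10)      # early licks and aborts excluded
  beh$outcome[beh$outcome == "miss"] <- "hit"
  expect_equal(psychometric_curve(beh)$rate, 1)
})

test_that("psychometric rate rises with change size for the default synthetic behaviour", {
  ses <- simulate_stimulus_sessions(2000, seed = 42)
  mtl <- rgamma(100, 4, 20) + 0.05
  beh <- sample_agent_datasets(agent_params(0.0625, 1.6, 0.25, 0.08, 3.5),
                               ses, mtl, seed = 43)[[1]]
  pc <- psychometric_curve(beh)
  expect_true(all(diff(pc$rate) >= -0.05))   # non-decreasing up to noise
  expect_gt(pc$rate[pc$magnitude == 4], 0.9)
  expect_lt(pc$rate[pc$magnitude == 1.25], 0.3)
})

test_that("lick-triggered average is flat at the linear mean for random licks", {
  ses <- simulate_stimulus_sessions(800, seed = 44)
  beh <- simulate_random_licks(ses, rate = 0.15, seed = 45)
  lta <- lick_triggered_average(ses, beh, fit_tau = FALSE)
  lin_mean <- exp((0.25 * log(2))^2 / 2)     # ~1.015 Hz
  expect_lt(max(abs(lta$kernel$mean_tf - lin_mean)), 0.03)
  expect_error(lick_triggered_average(ses, within(beh, outcome <- "miss")))
})

test_that("licks planted after fast pulses produce a kernel peak at the plant lag", {
  ses <- simulate_stimulus_sessions(400, seed = 46)
  ps <- split(ses$pulses, ses$pulses$trial_id)
  lick <- rep(NA_real_, nrow(ses$trials))
  for (j in seq_along(ps)) {
    pp <- ps[[j]]
    k <- which(pp$epoch == "baseline" & pp$log2_tf > 0.35 & pp$t >= 2)
    if (length(k)) lick[j] <- pp$t[k[1]] + 0.1   # lick 100 ms after pulse
  }
  beh <- data.frame(trial_id = ses$trials$trial_id,
                    outcome = ifelse(is.na(lick), "miss", "early"),
                    lick_time = lick, movement_onset = lick,
                    change_onset = ses$trials$change_onset,
                    change_magnitude = ses$trials$change_magnitude)
  lta <- lick_triggered_average(ses, beh, fit_tau = FALSE)
  expect_equal(lta$kernel$lag[which.max(lta$kernel$mean_tf)], -0.1)
})

test_that("the decay fit recovers an exact exponential kernel", {
  lags <- seq(-1.5, -0.05, by = 0.05)
  offset <- exp((0.25 * log(2))^2 / 2)
  kern <- 0.4 * exp(lags / 0.27) + offset
  expect_lt(abs(fit_kernel_decay(lags, kern, offset) - 0.27) / 0.27, 0.01)
})

test_that("independence prediction follows the stated formula", {
  expect_equal(two_pulse_independent_prediction(0.1, 0, 0), 0.1)
  expect_equal(two_pulse_independent_prediction(0.1, 0.05, 0.05), 0.1975)
  # signed deviations pass through the formula unchanged
  expect_equal(two_pulse_independent_prediction(0.2, -0.05, 0.05),
               0.2 - 0.05 + 0.05 + 0.0025)
})

test_that("magnitude bins hold equal pulse counts and the table is coherent", {
  ses <- simulate_stimulus_sessions(600, seed = 47)
  beh <- simulate_random_licks(ses, rate = 0.1, seed = 48)
  tab <- single_pulse_lick_probability(ses, beh)
  cc <- tab$counts
  # the rank binning itself is equal-count to within one pulse
  base <- ses$pulses[ses$pulses$epoch == "baseline", ]
  bins <- pmin(15, ceiling(rank(base$log2_tf, ties.method = "first") *
                             15 / nrow(base)))
  expect_lte(max(table(bins)) - min(table(bins)), 1)
  # per-bin eligible counts stay near-equal up to sampling of trial ends
  occ <- colSums(cc$elig_bins)
  expect_lt((max(occ) - min(occ)) / mean(occ), 0.1)
  expect_length(tab$P, 15)
  expect_true(all(tab$P >= 0 & tab$P <= 1, na.rm = TRUE))
  expect_equal(tab$dP, tab$P - tab$P0)
  # stimulus-independent licks: flat profile across bins
  expect_lt(max(abs(tab$dP), na.rm = TRUE), 0.02)
  # facilitation output is internally consistent
  f <- two_pulse_facilitation(tab, n_boot = 200, seed = 49)
  expect_equal(f$I, (f$P_obs - f$P_ind) / f$P_ind)
  expect_true(all(f$ci_lo <= f$ci_hi))
})

test_that("toy hand count: one lick preceded by one fast pulse", {
  # 60 pulses, all at the mean except one fast pulse 0.5 s before the lick
  lf <- rep(0, 60)
  lf[45] <- 0.5                       # t = 2.2 s
  ses <- manual_session(lf)
  beh <- manual_behaviour("early", lick = 2.7)
  tab <- single_pulse_lick_probability(ses, beh, min_lick = 2)
  # the fast pulse is eligible and followed by the lick at lag 0.5
  expect_equal(tab$P_fast, 1)
})
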