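test_that("homogeneous units are Poisson at the configured baseline rate", {
  ses <- tiny_sessions(30, seed = 8)
  beh <- data.frame(trial_id = ses$trials$trial_id, outcome = "miss",
                    lick_time = NA_real_)
  units <- make_unit_config(1, baseline_rate = 5)
  pop <- simulate_population(ses, beh, units, seed = 9)
  total_t <- sum(ses$trials$duration + 4)   # incl. pre/post padding
  rate <- nrow(pop$spikes) / total_t
  expect_lt(abs(rate - 5), 3 * sqrt(5 / total_t))
  # inter-spike intervals within one long trial look exponential (CV ~ 1)
  st <- pop$spikes$spike_time
  isi <- diff(st)[diff(st) < 2]
  expect_lt(abs(sd(isi) / mean(isi) - 1), 0.1)
  # determinism
  pop2 <- simulate_population(ses, beh, units, seed = 9)
  expect_identical(pop$spikes, pop2$spikes)
})

test_that("total spike count scales linearly with baseline rate", {
  ses <- tiny_sessions(20, seed = 10)
  beh <- data.frame(trial_id = ses$trials$trial_id, outcome = "miss",
                    lick_time = NA_real_)
  counts <- sapply(c(2, 4, 8), function(r) {
    pop <- simulate_population(ses, beh,
                               make_unit_config(1, baseline_rate = r),
                               seed = 11)
    nrow(pop$spikes)
  })
  ratio <- counts / counts[1]
  expect_lt(max(abs(ratio - c(1, 2, 4)) / c(1, 2, 4)), 0.1)
})

test_that("a boxcar TF kernel is recovered in the pulse-aligned PETH", {
  ses <- tiny_sessions(60, seed = 12)
  beh <- data.frame(trial_id = ses$trials$trial_id, outcome = "miss",
                    lick_time = NA_real_, movement_onset = NA_real_,
                    change_onset = ses$trials$change_onset,
                    change_duration = ses$trials$change_duration)
  units <- make_unit_config(1, baseline_rate = 20, tf_gain = 2,
                            tf_width = 0.3)
  pop <- suppressWarnings(simulate_population(ses, beh, units, seed = 13))
  pl <- classify_pulses(ses$pulses)
  ev <- pl[pl$fast, c("trial_id", "t")]
  ev <- select_pulse_events(ev, beh)
  nm <- select_pulse_events(pl[pl$near_mean, c("trial_id", "t")], beh)
  pr <- pulse_peth(pop$spikes, ev, nm)
  # a fast pulse (mean ~0.35 octaves) through the gain-2 boxcar raises
  # the 20-Hz rate by ~2.5 Hz over its 0.3-s support, and the response
  # returns to baseline beyond it
  inside <- mean(pr$response[pr$lag >= 0.05 & pr$lag < 0.3])
  outside <- mean(pr$response[pr$lag >= 0.6 & pr$lag <= 1])
  expect_gt(inside - outside, 1.5)
  expect_lt(abs(outside), 1.5)
  expect_gt(pr$half_peak_width, 0.1)
  expect_lt(pr$half_peak_width, 0.55)
})

test_that("orofacial reference responds only after licks with ~2 shared motifs", {
  ses <- tiny_sessions(40, seed = 14)
  set.seed(15)
  beh <- data.frame(trial_id = ses$trials$trial_id, outcome = "early",
                    lick_time = pmin(3 + rexp(40, 0.5),
                                     ses$trials$duration - 1.3))
  pop <- simulate_orofacial_population(ses, beh, n_units = 20, seed = 16)
  ev <- data.frame(trial_id = beh$trial_id, t = beh$lick_time)
  pe <- population_peth(pop, ev, window = c(-1, 1), bin = 0.02)
  pre <- rowMeans(pe$rates[, pe$time < -0.1])
  post <- rowMeans(pe$rates[, pe$time > 0 & pe$time < 1])
  expect_lt(abs(mean(pre) - 8), 1)         # flat at baseline before lick
  expect_gt(mean(post), mean(pre) * 1.5)   # strong execution response
  # population structure needs ~2 components (shared motif rank)
  M <- pe$rates - rowMeans(pe$rates)
  d <- svd(M)$d
  expect_lt(d[1]^2 / sum(d^2), 0.97)   # one PC is not enough
  # the second component carries real motif structure, later ones only
  # Poisson noise
  expect_gt(d[2]^2, 3 * d[3]^2)
})

test_that("motion energy has the configured noise floor and lick-locked bursts", {
  beh <- data.frame(trial_id = 1:5, outcome = "early",
                    lick_time = c(4, 5, 4.5, 6, 5.5))
  me <- simulate_motion_energy(beh, durations = rep(8, 5), seed = 17)
  # noise floor moments away from bursts
  in_burst <- rep(FALSE, nrow(me$trace))
  for (o in me$gt_onsets$onset_session)
    in_burst <- in_burst | (me$trace$t >= o - 0.1 & me$trace$t < o + 1.2)
  floor_vals <- me$trace$energy[!in_burst]
  expect_lt(abs(mean(floor_vals) - 1), 0.02)
  expect_lt(abs(sd(floor_vals) - 0.1), 0.02)
  # burst onset: first supra-floor crossing at the ground-truth onset
  o1 <- me$gt_onsets$onset_session[1]
  seg <- me$trace[me$trace$t > o1 - 0.5 & me$trace$t < o1 + 0.5, ]
  first_hi <- seg$t[which(seg$energy > 3)[1]]
  expect_lt(abs(first_hi - o1), 0.02)
  # no licks -> stationary noise
  beh0 <- data.frame(trial_id = 1, outcome = "miss", lick_time = NA_real_)
  me0 <- simulate_motion_energy(beh0, durations = 8, seed = 18)
  expect_true(all(me0$trace$energy < 2))
})
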