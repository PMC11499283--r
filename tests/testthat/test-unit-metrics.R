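test_that("pulse-event selection applies the three printed exclusion rules", {
  beh <- data.frame(trial_id = 1:3,
                    outcome = c("early", "miss", "hit"),
                    movement_onset = c(6, NA, 9),
                    change_onset = c(NA, 5, 8),
                    change_duration = c(NA, 2.15, 2.15))
  ev <- data.frame(trial_id = c(1, 1, 1, 2, 2, 3),
                   t = c(0.5, 2.0, 4.5, 3.0, 4.5, 2.0))
  out <- select_pulse_events(ev, beh, window = 1)
  # rule 1: 0.5 s after baseline onset -> excluded
  # rule 2 (early trial, movement at 6): events must end before 6-2-1=3
  #   -> t=2.0 kept, t=4.5 dropped
  # rule 3 (change at 5): the window may not reach the change epoch ->
  #   t=3.0 kept (window ends at 4 < 5), t=4.5 dropped; hit trial t=2.0
  #   kept (window ends at 3, change at 8)
  expect_equal(out$t, c(2.0, 3.0, 2.0))
  expect_equal(out$trial_id, c(1, 2, 3))
  # brute-force filter oracle agrees
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    b <- beh[ev$trial_id[i], ]
    keep[i] <- ev$t[i] >= 1 &&
      (!(b$outcome %in% c("early", "abort")) ||
         ev$t[i] < b$movement_onset - 3) &&
      (is.na(b$change_onset) || ev$t[i] + 1 < b$change_onset ||
         ev$t[i] > b$change_onset + 2.15)
  }
  expect_equal(nrow(out), sum(keep))
})

test_that("pulse PETH subtracts near-mean responses and removes global ramps", {
  set.seed(70)
  # synthetic spikes: rate 10 Hz plus a linear ramp over the trial
  n_tr <- 40
  spikes <- do.call(rbind, lapply(1:n_tr, function(j) {
    tt <- seq(0, 8, by = 0.001)
    rate <- 10 + 1.5 * tt           # ramp, no pulse response
    keep <- runif(length(tt)) < rate * 0.001
    if (!any(keep)) return(NULL)
    data.frame(unit_id = 1, trial_id = j, t_trial = tt[keep])
  }))
  ev <- data.frame(trial_id = rep(1:n_tr, each = 3),
                   t = rep(c(2, 4, 6), n_tr))
  nm <- data.frame(trial_id = rep(1:n_tr, each = 3),
                   t = rep(c(2.5, 4, 5.5), n_tr))   # same mean event time
  raw <- tfpulse:::spike_peth(spikes, ev)
  pr <- pulse_peth(spikes, ev, nm)
  # the raw PETH inherits the 1.5 Hz/s ramp; the near-mean subtraction
  # removes it
  slope_raw <- unname(coef(lm(raw$rate ~ raw$lag))[2])
  slope_sub <- unname(coef(lm(pr$response ~ pr$lag))[2])
  expect_gt(slope_raw, 0.9)
  expect_lt(abs(slope_sub), 0.5)
  expect_lt(abs(mean(pr$response)), 0.6)
  # fewer than 10 events: undefined with the count reported
  small <- pulse_peth(spikes, ev[1:4, ], nm)
  expect_null(small$response)
  expect_equal(small$n_events, 4)
})

test_that("sequence facilitation follows its defining ratio", {
  lag <- seq(-0.5, 1.45, by = 0.05)
  base <- exp(-((lag - 0.2) / 0.1)^2)
  z1 <- matrix(rep(base, each = 8), 8) + 0.001 * matrix(rnorm(8 * length(lag)), 8)
  mk2 <- function(fac, delay) {
    resp <- base + fac * exp(-((lag - delay - 0.2) / 0.1)^2)
    matrix(rep(resp, each = 8), 8) + 0.001 * matrix(rnorm(8 * length(lag)), 8)
  }
  # r2 read out at the single-pulse peak latency after the second pulse:
  # equal responses give delta ~ 0; a 1.5x response gives delta ~ 0.5
  out <- sequence_facilitation(z1, list(mk2(1, 0.2), mk2(1.5, 0.2)),
                               lag, c(0.2, 0.2), n_boot = 100, seed = 71)
  expect_lt(abs(out$delta[1] - 0.0), 0.05)
  expect_lt(abs(out$delta[2] - 0.5), 0.08)
  expect_true(out$significant[2])
})

test_that("preparatory fractions detect ramp onsets and stay flat for noise", {
  set.seed(72)
  tt <- seq(-2, 0.5, by = 0.01)
  # stationary population: z-scores ~ N(0,1), fraction |z|>2.576 ~ 1%
  z_null <- matrix(rnorm(60 * length(tt)), 60)
  pf0 <- preparatory_fractions(z_null, tt, n_boot = 300, seed = 73)
  expect_lt(max(abs(pf0$fraction)), 0.12)
  expect_true(is.na(pf0$latency))
  # ramping population: activation from t0 = -0.8 s
  ramp <- pmax(0, (tt + 0.8) / 0.8) * 6
  z_ramp <- matrix(rep(ramp, each = 60), 60) +
    matrix(rnorm(60 * length(tt)), 60)
  pf1 <- preparatory_fractions(z_ramp, tt, n_boot = 300, seed = 74)
  expect_false(is.na(pf1$latency))
  expect_lt(abs(pf1$latency - (-0.8)), 0.25)
  # default threshold is the two-sided 1% normal quantile
  expect_equal(eval(formals(preparatory_fractions)$threshold), qnorm(0.995))
  expect_equal(round(qnorm(0.995), 3), 2.576)
})

test_that("pulse/preparation alignment reproduces Pearson's r with bootstrap", {
  expect_equal(pulse_prep_alignment(1:12, 1:12, n_boot = 50, seed = 75)$r, 1)
  set.seed(76)
  a <- rnorm(40); b <- rnorm(40)
  out <- pulse_prep_alignment(a, b, n_boot = 500, seed = 77)
  expect_lt(out$ci[1], 0); expect_gt(out$ci[2], 0)   # null CI spans zero
  v1 <- c(1, 2, 3); v2 <- c(2, 4, 6.5)
  expect_error(pulse_prep_alignment(v1, v2))          # < 10 units
  out2 <- pulse_prep_alignment(rep(v1, 4), rep(v2, 4), n_boot = 50,
                               seed = 78)
  expect_equal(out2$r, cor(rep(v1, 4), rep(v2, 4)))
})

test_that("intrinsic timescale grid spans 20 lags and flags non-decaying units", {
  set.seed(79)
  counts <- matrix(rpois(400 * 40, 0.5), 400)   # homogeneous Poisson
  out <- intrinsic_timescale(counts)
  expect_length(out$lag, 20)
  expect_equal(max(out$lag), 1)
  expect_true(is.na(out$tau))
})

test_that("OU-modulated counts yield a recoverable intrinsic timescale", {
  set.seed(80)
  n_win <- 600; nb <- 40; dt <- 0.05
  a <- exp(-dt / 0.2)
  counts <- matrix(0L, n_win, nb)
  for (w in seq_len(n_win)) {
    x <- numeric(nb); x[1] <- rnorm(1, 0, 0.5)
    for (i in 2:nb) x[i] <- a * x[i - 1] + rnorm(1, 0, 0.5 * sqrt(1 - a^2))
    counts[w, ] <- rpois(nb, 10 * exp(x) * dt)
  }
  out <- intrinsic_timescale(counts)
  expect_lt(abs(out$tau - 0.2) / 0.2, 0.2)
})
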