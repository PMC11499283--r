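test_that("decision-time distribution matches closed forms and conserves mass", {
  # unreachable bound
  d_inf <- decision_time_distribution(rep(0, 50), 0.04, Inf)
  expect_equal(sum(d_inf$pmf), 0)
  expect_equal(exp(d_inf$log_p_inf), 1)
  # constant stimulus: D - 1 is geometric with p = 1 - Phi((b-s)/sigma)
  d <- decision_time_distribution(rep(0.1, 200), 0.04, 0.4)
  p <- 1 - pnorm((0.4 - 0.1) / 0.2)
  expect_lt(max(abs(d$pmf - dgeom(0:199, p))), 1e-10)
  # total mass (finite pmf + atom at infinity) is 1
  expect_lt(abs(sum(d$pmf) + exp(d$log_p_inf) - 1), 1e-10)
  expect_error(decision_time_distribution(rep(0, 10), 0, 1))
  expect_error(decision_time_distribution(c(0, NA), 0.1, 1))
})

test_that("3-step decision pmf matches brute-force sampling of Z", {
  s <- c(0.2, -0.1, 0.35)
  sigma <- 0.3; b <- 0.5
  d <- decision_time_distribution(s, sigma^2, b)
  set.seed(20)
  n <- 1e6
  Z <- matrix(rnorm(3 * n, rep(s, each = n), sigma), n)
  cross <- Z > b
  first <- ifelse(cross[, 1], 1, ifelse(cross[, 2], 2, ifelse(cross[, 3], 3, 4)))
  for (k in 1:3) {
    p_emp <- mean(first == k)
    se <- sqrt(p_emp * (1 - p_emp) / n)
    expect_lt(abs(d$pmf[k] - p_emp), 3 * se + 1e-6)
  }
  expect_lt(abs(exp(d$log_p_inf) - mean(first == 4)), 3e-3)
})

test_that("shifted log-logistic delay has the stated support, median and mass", {
  expect_equal(ploglogis(0.1, 0.1, 0.15, 3), 0)
  expect_equal(dloglogis(0.05, 0.1, 0.15, 3), 0)
  expect_equal(ploglogis(0.25, 0.1, 0.15, 3), 0.5)  # F(alpha + beta) = 1/2
  q <- integrate(dloglogis, 0.1, 0.1 + 200 * 0.15,
                 alpha = 0.1, beta = 0.15, gamma = 3)
  expect_lt(abs(q$value - 1), 1e-6)
  expect_error(dloglogis(1, -0.1, 0.15, 3))
  expect_error(dloglogis(1, 0.1, 0.15, 0.9))
})

test_that("response-time distribution is the decision/delay convolution", {
  # decision atom at d0: p_R(r) = p_Delta(r - d0) exactly
  s <- c(10, rep(-10, 20))   # certain crossing at the first frame
  dec <- decision_time_distribution(s, 0.01, 0)
  expect_gt(dec$pmf[1], 1 - 1e-12)
  rt <- response_time_distribution(dec, 0.1, 0.15, 3,
                                   r_grid = seq(0.2, 1.5, by = 0.1))
  expect_equal(rt$pdf, dloglogis(seq(0.2, 1.5, by = 0.1) - 1 / 60,
                                 0.1, 0.15, 3), tolerance = 1e-8)
  # Monte-Carlo check of the cdf on a structured stimulus
  sfr <- c(rep(0, 60), rep(0.5, 30), rep(0, 90))
  dec2 <- decision_time_distribution(sfr, 0.09, 0.6)
  set.seed(21)
  n <- 2e5
  u <- matrix(runif(n * length(sfr)), n)
  pc <- rep(1 - pnorm((0.6 - sfr) / 0.3), each = n)
  crossed <- matrix(u < pc, n)
  D <- apply(crossed, 1, function(z) if (any(z)) which(z)[1] else NA) / 60
  R <- D + rloglogis(n, 0.1, 0.08, 3)
  grid <- seq(0.5, 3, by = 0.25)
  rt2 <- response_time_distribution(dec2, 0.1, 0.08, 3, r_grid = grid)
  emp <- sapply(grid, function(r) mean(!is.na(R) & R <= r))
  expect_lt(max(abs(rt2$cdf - emp)), 3 * sqrt(0.25 / n) + 2e-3)
})

test_that("delay MLE recovers self-sampled parameters and rejects bad input", {
  set.seed(22)
  rts <- rloglogis(1e4, 0.1, 0.15, 3)
  f <- fit_delay_distribution(rts, seed = 23)
  expect_lt(abs(f$alpha - 0.1) / 0.1, 0.05)
  expect_lt(abs(f$beta - 0.15) / 0.15, 0.05)
  expect_lt(abs(f$gamma - 3) / 3, 0.05)
  expect_error(fit_delay_distribution(c(rts[1:50], -0.1)))
  expect_error(fit_delay_distribution(rts[1:10]))
  # optimum beats a scale perturbation
  ll_pert <- sum(dloglogis(rts, f$alpha, f$beta * 1.2, f$gamma, log = TRUE))
  expect_gte(f$logLik, ll_pert)
})

test_that("marginal likelihood matches hand enumeration on a 3-step trial", {
  s <- c(0.1, 0.4, -0.2)
  sigma2 <- 0.09; b <- 0.45
  al <- 0.05; be <- 0.1; ga <- 2.5
  r_obs <- 0.3
  trial <- list(s_frames = s, outcome = "early", r = r_obs)
  ll <- tfpulse:::agent_loglik(list(trial), sigma2, b, al, be, ga)
  # enumeration oracle: p_R(r) = sum_d p_D(d) p_Delta(r - d)
  sg <- sqrt(sigma2)
  phi <- pnorm((b - s) / sg)
  pD <- c(1 - phi[1], phi[1] * (1 - phi[2]), phi[1] * phi[2] * (1 - phi[3]))
  pR <- sum(pD * dloglogis(r_obs - (1:3) / 60, al, be, ga))
  expect_equal(ll, log(pR), tolerance = 1e-10)
  # miss trials use the censored mass beyond the last frame
  trial_m <- list(s_frames = s, outcome = "miss", r = NA)
  ll_m <- tfpulse:::agent_loglik(list(trial_m), sigma2, b, al, be, ga)
  surv <- prod(phi) + sum(pD * (1 - ploglogis(3 / 60 - (1:3) / 60, al, be, ga)))
  expect_equal(ll_m, log(surv), tolerance = 1e-10)
  # raising the bound lowers the likelihood of observed early responses
  ll_hi <- tfpulse:::agent_loglik(list(trial), sigma2, 2 * b, al, be, ga)
  expect_lt(ll_hi, ll)
})

test_that("sampled datasets classify outcomes by rule and are reproducible", {
  ses <- tiny_sessions(60, seed = 24)
  mtl <- rgamma(50, 4, 20) + 0.05
  # very low bound: decision at the first frame on every trial
  pars <- agent_params(1e-4, -10, 0.05, 0.05, 2)
  ds <- sample_agent_datasets(pars, ses, mtl, n_datasets = 2, seed = 25)
  expect_length(ds, 2)
  d1 <- ds[[1]]
  resp <- !is.na(d1$movement_onset)
  expect_true(all(d1$movement_onset[resp] > 1 / 60))
  expect_true(all(d1$movement_onset[resp] < 1 / 60 + 3))  # immediate decisions
  # outcome labels equal brute-force reclassification of lick times
  reclass <- ifelse(is.na(d1$lick_time), "miss",
             ifelse(is.na(d1$change_onset) | d1$lick_time < d1$change_onset,
                    "early",
             ifelse(d1$lick_time <= d1$change_onset + 2.15, "hit", "miss")))
  expect_equal(d1$outcome, reclass)
  # early licks on no-change trials stay within the trial
  nc <- is.na(d1$change_onset) & d1$outcome == "early"
  expect_true(all(d1$lick_time[nc] <= ses$trials$duration[nc]))
  # dataset k is individually reproducible
  ds2 <- sample_agent_datasets(pars, ses, mtl, n_datasets = 2, seed = 25)
  expect_identical(ds[[2]], ds2[[2]])
  expect_error(sample_agent_datasets(pars, ses, numeric(0)))
})
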