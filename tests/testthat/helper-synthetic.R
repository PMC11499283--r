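# Shared fixtures built in code. Kept deliberately small; heavier
# simulations live inside the tests that need them.

# A small session set reused across files (regenerated per file; cheap).
tiny_sessions <- function(n_trials = 40, seed = 7) {
  simulate_stimulus_sessions(n_trials, seed = seed)
}

# Hand-built single-trial session object for cell-level design checks.
manual_session <- function(log2_tf, change_onset = NA, change_magnitude = NA,
                           duration = length(log2_tf) * 0.05) {
  n <- length(log2_tf)
  trials <- data.frame(trial_id = 1L, has_change = !is.na(change_onset),
                       is_probe = FALSE, change_onset = change_onset,
                       change_magnitude = change_magnitude,
                       change_duration = ifelse(is.na(change_onset), NA, 2.15),
                       duration = duration, n_pulses = n,
                       drift_direction = "up")
  epoch <- rep("baseline", n)
  if (!is.na(change_onset)) {
    t <- (seq_len(n) - 1) * 0.05
    epoch[t >= change_onset] <- "change"
  }
  list(trials = trials,
       pulses = data.frame(trial_id = 1L, t = (seq_len(n) - 1) * 0.05,
                           log2_tf = log2_tf, epoch = epoch))
}

# Behaviour row helper.
manual_behaviour <- function(outcome = "miss", lick = NA, movement = lick,
                             change_onset = NA, magnitude = NA) {
  data.frame(trial_id = 1L, outcome = outcome, movement_onset = movement,
             lick_time = lick, change_onset = change_onset,
             change_magnitude = magnitude)
}

# Spike times at a constant rate on [0, dur): Poisson thinned by a 2-ms
# refractory period, as a clean well-isolated unit would look.
const_spikes <- function(rate, dur, seed = 1, refractory = 0.002) {
  set.seed(seed)
  n <- rpois(1, rate * dur)
  st <- sort(runif(n, 0, dur))
  keep <- c(TRUE, diff(st) >= refractory)
  while (!all(keep)) {
    st <- st[keep]
    keep <- c(TRUE, diff(st) >= refractory)
  }
  st
}

# Deterministic rank-2 population for the subspace analyses: a
# preparatory mode (pre-event ramp, quenched at movement onset) carried
# by the flagged minority of units and an execution mode (post-event
# transient) shared with the reference population, orthogonal
# unit-loading patterns, small reproducible noise. The flagged units are
# a minority, as TF-responsive units are in the recordings this
# emulates; with half the population flagged, the population-mean
# subtraction splits every mode's contribution evenly and the
# decomposition cannot rise above chance by construction.
subspace_toy <- function(n_flag = 10, n_rest = 30, nt = 350, dt = 0.01,
                         noise = 0.02, seed = 11) {
  set.seed(seed)
  time <- seq(-2, 1.5 - dt, by = dt) + dt / 2
  prep <- pmax(0, (time + 0.8) / 0.8)
  prep[time > 0] <- pmax(0, 1 - time[time > 0] / 0.15)
  exec1 <- exp(-((time - 0.1) / 0.08)^2)
  exec2 <- pmax(0, sin(pi * pmin(pmax(time, 0) / 1.0, 1)))
  n <- n_flag + n_rest
  # bipolar loadings (units can be activated or suppressed): zero-mean
  # loading vectors keep the population-mean subtraction from mixing the
  # preparatory and execution modes
  a <- c(rnorm(n_flag, 0, 0.8), rep(0, n_rest))       # prep loadings
  b1 <- c(rep(0, n_flag), rnorm(n_rest, 0, 0.8))      # exec loadings
  b2 <- c(rep(0, n_flag), rnorm(n_rest, 0, 0.6))
  rates <- 5 + outer(a, prep) + outer(b1, exec1) + outer(b2, exec2) +
    matrix(rnorm(n * length(time), 0, noise), n)
  ref <- 8 + outer(abs(rnorm(15, 1, 0.3)), exec1) +
    outer(abs(rnorm(15, 0.7, 0.3)), exec2) +
    matrix(rnorm(15 * length(time), 0, noise), 15)
  list(time = time, rates = rates, ref = ref,
       flags = c(rep(TRUE, n_flag), rep(FALSE, n_rest)))
}

# Full subspace pipeline on the toy population.
subspace_toy_fit <- function(toy = subspace_toy()) {
  tgt <- preprocess_population(toy$rates)
  ref <- preprocess_population(toy$ref)
  ptg <- population_pca(tgt$M, toy$time, n_pc = 4)
  prf <- population_pca(ref$M, toy$time, n_pc = 2)
  map <- fit_movement_mapping(ptg$proj, prf$proj, toy$time)
  nb <- null_space_basis(map$W, ptg$proj, prf$proj, toy$time)
  list(toy = toy, tgt = tgt, ptg = ptg, prf = prf, map = map, nb = nb)
}
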