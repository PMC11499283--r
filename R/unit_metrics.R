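# Model-free single-unit statistics: pulse-event selection, pulse PETHs,
# two-pulse facilitation, preparatory-activity fractions and latencies,
# pulse/preparation alignment and intrinsic timescales.

#' Select eligible TF pulse outlier events
#'
#' Keeps pulse events that are: (1) at least 1 s after baseline onset;
#' (2) on early-lick or abort trials, earlier than 2 s plus the analysis
#' window before the movement-onset time; and (3) outside the change
#' period plus the analysis window (the event's window may not overlap
#' the change epoch).
#'
#' @param events candidate events (`trial_id`, `t`).
#' @param behaviour behaviour table (`trial_id`, `outcome`,
#'   `movement_onset`, `change_onset`, `change_duration` optional).
#' @param window post-pulse analysis window length, s.
#' @param min_t earliest admissible time after baseline onset, s.
#' @return the filtered event table.
#' @export
select_pulse_events <- function(events, behaviour, window = 1, min_t = 1) {
  b <- behaviour[match(events$trial_id, behaviour$trial_id), ]
  n <- nrow(b)
  mov <- b$movement_onset %||% rep(NA_real_, n)
  co <- b$change_onset %||% rep(NA_real_, n)
  dur <- b$change_duration %||% rep(2.15, n)
  keep <- events$t >= min_t
  moved <- b$outcome %in% c("early", "abort") & !is.na(mov)
  keep <- keep & (!moved | events$t < mov - 2 - window)
  has_ch <- !is.na(co)
  keep <- keep & (!has_ch | events$t + window < co |
                    events$t > co + ifelse(is.na(dur), 2.15, dur))
  events[keep, , drop = FALSE]
}

# Event-aligned spike-count PETH for one unit (rate in Hz). spikes must
# have trial_id and t_trial columns.
spike_peth <- function(spikes, events, window = c(-0.5, 1), bin = 0.05) {
  lags <- seq(window[1], window[2] - bin / 2, by = bin)
  counts <- numeric(length(lags)); nev <- 0
  ssp <- split(spikes$t_trial, spikes$trial_id)
  for (i in seq_len(nrow(events))) {
    st <- ssp[[as.character(events$trial_id[i])]]
    nev <- nev + 1
    if (is.null(st)) next
    rel <- st - events$t[i]
    ix <- floor((rel - window[1]) / bin) + 1
    ix <- ix[ix >= 1 & ix <= length(lags)]
    if (length(ix)) counts <- counts + tabulate(ix, nbins = length(lags))
  }
  if (!nev) return(NULL)
  list(lag = lags, rate = counts / (nev * bin), n = nev)
}

#' Baseline-subtracted pulse response of one unit
#'
#' Mean firing rate aligned to the selected pulse events, minus the mean
#' rate aligned to near-mean pulses (|log2 TF| within 0.5 s.d.), which
#' removes continuous ramps from the pulse response. Peak time is the
#' largest absolute rate change within 1 s of pulse onset; the half-peak
#' width is measured by linear interpolation.
#'
#' @param spikes one unit's spikes (`trial_id`, `t_trial`).
#' @param events selected pulse events (`trial_id`, `t`).
#' @param near_events near-mean pulse events for baseline subtraction.
#' @param window PETH window, s.
#' @param bin PETH bin, s.
#' @param min_events minimum events required (default 10).
#' @return list with `lag`, `response` (Hz, baseline-subtracted),
#'   `peak_time`, `half_peak_width`, `n_events`; `NULL` response and a
#'   count when under `min_events`.
#' @export
pulse_peth <- function(spikes, events, near_events, window = c(-0.5, 1),
                       bin = 0.05, min_events = 10) {
  if (nrow(events) < min_events)
    return(list(response = NULL, n_events = nrow(events)))
  pe <- spike_peth(spikes, events, window, bin)
  pn <- spike_peth(spikes, near_events, window, bin)
  resp <- pe$rate - pn$rate
  post <- pe$lag >= 0 & pe$lag <= 1
  km <- kernel_metrics(resp[post], lag = pe$lag[post], search = 1)
  list(lag = pe$lag, response = resp, peak_time = km$peak_time,
       half_peak_width = km$fwhm, flipped = km$flipped,
       n_events = pe$n)
}

#' Facilitation of the response to a second fast pulse
#'
#' From the population-mean z-scored response to a single fast pulse,
#' finds the peak value `r1` and its peak time. For each two-pulse delay,
#' the response to the pulse pair is read out at the same latency after
#' the second pulse (peak within a 100-ms window centred on that time
#' point), giving `r2`; the relative facilitation is
#' `delta = (r2 - r1)/r1`. Units whose single-pulse response is negative
#' at its extremum are sign-flipped before averaging. CIs come from
#' bootstrapping units (2000 repetitions).
#'
#' @param z_single units x lags matrix of z-scored single-pulse
#'   responses (z-scored from the 0.5 s before pulse onset).
#' @param z_two named list over delays of units x lags matrices aligned
#'   to the FIRST pulse onset.
#' @param lag lag grid (s) shared by all matrices (0 = first pulse
#'   onset).
#' @param delays numeric delays (s) matching `z_two`.
#' @param n_boot bootstrap repetitions (default 2000).
#' @param seed optional integer seed.
#' @return data.frame per delay: `delay`, `r1`, `r2`, `delta`, `ci_lo`,
#'   `ci_hi`, `significant` (CI above zero).
#' @export
sequence_facilitation <- function(z_single, z_two, lag, delays,
                                  n_boot = 2000, seed = NULL) {
  stopifnot(length(z_two) == length(delays))
  if (!is.null(seed)) set.seed(seed)
  nu <- nrow(z_single)
  post <- lag >= 0 & lag <= 1
  delta_of <- function(idx) {
    m1 <- colMeans(z_single[idx, , drop = FALSE])
    # flip by the population response sign convention is applied per
    # unit upstream; here flip the mean if it is net-negative
    pk_i <- which(post)[which.max(abs(m1[post]))]
    s <- sign(m1[pk_i]); if (s == 0) s <- 1
    m1 <- m1 * s
    r1 <- m1[pk_i]; t_peak <- lag[pk_i]
    vapply(seq_along(delays), function(d) {
      m2 <- colMeans(z_two[[d]][idx, , drop = FALSE]) * s
      target <- delays[d] + t_peak     # same latency after second pulse
      inw <- lag >= target - 0.05 & lag <= target + 0.05
      if (!any(inw) || r1 <= 0) return(NA_real_)
      r2 <- max(m2[inw])
      (r2 - r1) / r1
    }, numeric(1))
  }
  full <- delta_of(seq_len(nu))
  m1 <- colMeans(z_single)
  pk_i <- which(post)[which.max(abs(m1[post]))]
  s <- sign(m1[pk_i]); if (s == 0) s <- 1
  r1 <- (m1 * s)[pk_i]
  boot <- t(vapply(seq_len(n_boot), function(b)
    delta_of(sample.int(nu, nu, replace = TRUE)), numeric(length(delays))))
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(delay = delays, r1 = r1, r2 = r1 * (1 + full), delta = full,
             ci_lo = ci[1, ], ci_hi = ci[2, ],
             significant = ci[1, ] > 0)
}

#' z-score PETHs against a pre-event baseline window
#'
#' @param peths units x time matrix of event-aligned rates.
#' @param tt time grid (s).
#' @param baseline_win window for the mean/s.d. (default the 2 s before
#'   time zero).
#' @return z-scored matrix (rows with zero baseline s.d. become 0).
#' @export
zscore_peths <- function(peths, tt, baseline_win = c(-2, 0)) {
  inb <- tt >= baseline_win[1] & tt < baseline_win[2]
  mu <- rowMeans(peths[, inb, drop = FALSE])
  sd <- apply(peths[, inb, drop = FALSE], 1, stats::sd)
  z <- (peths - mu) / ifelse(sd > 0, sd, Inf)
  z
}

#' Fractions of significantly active units and activation latencies
#'
#' At every time point, the fraction of units in a group whose absolute
#' z-score exceeds 2.576 (two-sided P < 0.01 normal quantile), minus the
#' baseline fraction in \[-2, -1.8\] s. Latency is the earliest time
#' point after which, within a 100-ms window, for at least 80 ms: the
#' lower 95% CI of the fraction is above zero AND the mean fraction
#' exceeds `frac_threshold`. CIs come from bootstrapping units.
#'
#' @param z units x time z-score matrix (see [zscore_peths()]).
#' @param tt time grid (s), event (e.g. lick) at 0.
#' @param threshold z threshold (default `qnorm(1 - 0.01/2)` = 2.576).
#' @param baseline_win window whose mean fraction is subtracted.
#' @param frac_threshold latency criterion on the mean fraction
#'   (0.1 for subpopulations, 0.05 for the all-unit variant).
#' @param n_boot bootstrap repetitions (default 5000).
#' @param sustain_win,sustain_frac the 100-ms / 80-ms sustained rule.
#' @param seed optional integer seed.
#' @return list with `fraction` (baseline-subtracted time course),
#'   `ci_lo`, `ci_hi`, `latency` (s, `NA` when the rule is never met or
#'   the group has < 10 units).
#' @export
preparatory_fractions <- function(z, tt, threshold = stats::qnorm(0.995),
                                  baseline_win = c(-2, -1.8),
                                  frac_threshold = 0.1, n_boot = 5000,
                                  sustain_win = 0.1, sustain_frac = 0.8,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nu <- nrow(z)
  act <- abs(z) > threshold
  inb <- tt >= baseline_win[1] & tt < baseline_win[2]
  frac_of <- function(idx) {
    f <- colMeans(act[idx, , drop = FALSE])
    f - mean(f[inb])
  }
  f <- frac_of(seq_len(nu))
  boot <- t(vapply(seq_len(n_boot), function(b)
    frac_of(sample.int(nu, nu, replace = TRUE)), numeric(length(tt))))
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  latency <- NA_real_
  if (nu >= 10) {
    good <- ci[1, ] > 0 & f > frac_threshold
    dt <- stats::median(diff(tt))
    nwin <- max(1L, round(sustain_win / dt))
    for (i in seq_along(tt)) {
      jj <- i:min(length(tt), i + nwin - 1)
      if (length(jj) < nwin) break
      if (mean(good[jj]) >= sustain_frac) { latency <- tt[i]; break }
    }
  }
  list(fraction = f, ci_lo = ci[1, ], ci_hi = ci[2, ], latency = latency,
       time = tt)
}

#' Latency of a significant group difference in activation
#'
#' First time point where, within a 100-ms window for at least 80 ms,
#' the bootstrap CI of the difference in active fractions between two
#' groups stays above zero.
#'
#' @param z1,z2 z-score matrices of the two groups (shared time grid).
#' @param tt time grid (s).
#' @inheritParams preparatory_fractions
#' @return latency (s) or `NA`.
#' @export
group_difference_latency <- function(z1, z2, tt,
                                     threshold = stats::qnorm(0.995),
                                     baseline_win = c(-2, -1.8),
                                     n_boot = 5000, sustain_win = 0.1,
                                     sustain_frac = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inb <- tt >= baseline_win[1] & tt < baseline_win[2]
  fr <- function(z, idx) {
    f <- colMeans((abs(z) > threshold)[idx, , drop = FALSE])
    f - mean(f[inb])
  }
  n1 <- nrow(z1); n2 <- nrow(z2)
  boot <- t(vapply(seq_len(n_boot), function(b)
    fr(z1, sample.int(n1, n1, TRUE)) - fr(z2, sample.int(n2, n2, TRUE)),
    numeric(length(tt))))
  lo <- apply(boot, 2, stats::quantile, probs = 0.025)
  good <- lo > 0
  dt <- stats::median(diff(tt))
  nwin <- max(1L, round(sustain_win / dt))
  for (i in seq_along(tt)) {
    jj <- i:min(length(tt), i + nwin - 1)
    if (length(jj) < nwin) break
    if (mean(good[jj]) >= sustain_frac) return(tt[i])
  }
  NA_real_
}

#' Correlation between pulse responses and pre-lick activity
#'
#' Pearson correlation across units between the baseline-subtracted mean
#' rate after fast pulses (50-ms window around the population peak time)
#' and the baseline-subtracted mean rate in the \[-0.3, 0\] s before
#' early licks. CI and two-sided p-value by bootstrapping units.
#'
#' @param pulse_vec per-unit pulse-response values.
#' @param prep_vec per-unit pre-lick activity values.
#' @param n_boot bootstrap repetitions (default 10000).
#' @param seed optional integer seed.
#' @return list with `r`, `ci`, `p`.
#' @export
pulse_prep_alignment <- function(pulse_vec, prep_vec, n_boot = 10000,
                                 seed = NULL) {
  stopifnot(length(pulse_vec) == length(prep_vec))
  n <- length(pulse_vec)
  if (n < 10) stop("need at least 10 units")
  if (stats::sd(pulse_vec) == 0 || stats::sd(prep_vec) == 0)
    stop("zero-variance input vector")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(pulse_vec, prep_vec)
  boot <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    if (stats::sd(pulse_vec[ix]) == 0 || stats::sd(prep_vec[ix]) == 0)
      return(NA_real_)
    stats::cor(pulse_vec[ix], prep_vec[ix])
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  p <- 2 * min(mean(boot <= 0, na.rm = TRUE), mean(boot >= 0, na.rm = TRUE))
  list(r = r, ci = ci, p = p)
}

#' Intrinsic timescale from spike-count autocorrelation
#'
#' Pearson autocorrelation of 50-ms spike counts over inter-trial
#' windows, at lags 1-20 (= 1 s), followed by an exponential-decay fit
#' `A * exp(-lag/tau) + B` starting from the beginning of the monotonic
#' decay (the fit may be offset by up to 3 bins when the autocorrelation
#' rises initially).
#'
#' @param counts windows x bins matrix of 50-ms spike counts (e.g. the
#'   \[-2.5, -0.5\] s pre-trial epoch: 40 bins per window).
#' @param n_lags number of lags (default 20 = 1 s).
#' @param bin bin width, s.
#' @param max_offset maximum fit offset in bins (default 3).
#' @return list with `lag` (s), `r`, `tau` (s, `NA` when the
#'   autocorrelation does not decay), `offset_bins`, `fit`.
#' @export
intrinsic_timescale <- function(counts, n_lags = 20, bin = 0.05,
                                max_offset = 3) {
  stopifnot(ncol(counts) > n_lags)
  r <- vapply(seq_len(n_lags), function(k) {
    x <- as.numeric(counts[, 1:(ncol(counts) - k)])
    y <- as.numeric(counts[, (1 + k):ncol(counts)])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  lag_s <- seq_len(n_lags) * bin
  if (all(is.na(r)) || max(r, na.rm = TRUE) < 0.01)
    return(list(lag = lag_s, r = r, tau = NA_real_, offset_bins = NA,
                fit = NULL))
  # start the fit where monotonic decay begins
  off <- 0
  while (off < max_offset && off + 2 <= n_lags &&
         !is.na(r[off + 1]) && !is.na(r[off + 2]) &&
         r[off + 2] > r[off + 1]) off <- off + 1
  idx <- (off + 1):n_lags
  df <- data.frame(t = lag_s[idx], r = r[idx])
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ A * exp(-t / tau) + B, data = df,
                      start = list(A = max(df$r, 0.1), tau = 0.2, B = 0),
                      lower = c(1e-6, 1e-3, -1), upper = c(10, 50, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || stats::coef(fit)[["A"]] < 1e-5)
    return(list(lag = lag_s, r = r, tau = NA_real_, offset_bins = off,
                fit = NULL))
  list(lag = lag_s, r = r, tau = stats::coef(fit)[["tau"]],
       offset_bins = off, fit = fit)
}

#' Spike counts in pre-trial windows
#'
#' Convenience extractor building the windows x bins count matrix used by
#' [intrinsic_timescale()] from a simulated population.
#'
#' @param pop population from [simulate_population()].
#' @param unit_id unit to extract.
#' @param window pre-trial window relative to baseline onset (default
#'   \[-2.5, -0.5\] s).
#' @param bin bin width, s.
#' @return windows x bins integer matrix.
#' @export
pretrial_counts <- function(pop, unit_id, window = c(-2.5, -0.5),
                            bin = 0.05) {
  sp <- pop$spikes[pop$spikes$unit_id == unit_id, ]
  nb <- round((window[2] - window[1]) / bin)
  tt <- pop$trial_times
  out <- matrix(0L, nrow(tt), nb)
  ssp <- split(sp$t_trial, sp$trial_id)
  for (j in seq_len(nrow(tt))) {
    st <- ssp[[as.character(tt$trial_id[j])]]
    if (is.null(st)) next
    sel <- st >= window[1] & st < window[2]
    ix <- floor((st[sel] - window[1]) / bin) + 1
    if (length(ix)) out[j, ] <- tabulate(ix, nbins = nb)
  }
  out
}
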