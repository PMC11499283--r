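# Automatic curation of spike-sorted units: the seven quality criteria
# applied to full-session spike trains.

# Rolling mean firing rate over windows of `win` seconds advancing in
# 1-min steps; edge windows are truncated.
rolling_rate <- function(spike_times, duration, win, step = 60) {
  starts <- seq(0, max(duration - step, 0), by = step)
  vapply(starts, function(s) {
    e <- min(s + win, duration)
    if (e <= s) return(NA_real_)
    sum(spike_times >= s & spike_times < e) / (e - s)
  }, numeric(1))
}

#' Automatic unit quality filter
#'
#' Applies the seven curation criteria to a full-session spike train:
#' (1) mean firing rate above 0.5 Hz; (2-4) rolling 20/10/5-min average
#' rates never drop below 30/20/10% of the mean rate; (5) estimated
#' refractory-period contamination below 20% (inter-spike intervals
#' under 2 ms relative to the expectation under the unit's mean rate);
#' (6) if any ISIs fall in the first 5 ms, the ISI peak within 0-5 ms
#' must not lie within the first 2 ms; (7) the ISI histogram has no
#' sudden spikes (largest peak less than 4 times the second largest).
#'
#' @param spike_times spike times (s from session start), sorted.
#' @param session_duration session length, s.
#' @param refractory refractory period for the contamination estimate, s.
#' @param isi_max ISI histogram support for criterion 7, s.
#' @return list with `pass` (all seven) and a named logical `criteria`
#'   vector plus the measured statistics.
#' @export
unit_quality_filter <- function(spike_times, session_duration,
                                refractory = 0.002, isi_max = 0.1) {
  n <- length(spike_times)
  rate <- n / session_duration
  isi <- diff(spike_times)
  crit <- c(mean_rate = rate > 0.5,
            roll20 = TRUE, roll10 = TRUE, roll5 = TRUE,
            contamination = TRUE, isi_peak = TRUE, isi_spike = TRUE)
  for (w in list(c("roll20", 1200, 0.30), c("roll10", 600, 0.20),
                 c("roll5", 300, 0.10))) {
    rr <- rolling_rate(spike_times, session_duration, as.numeric(w[2]))
    crit[w[1]] <- all(rr >= as.numeric(w[3]) * rate, na.rm = TRUE)
  }
  # contamination: ISI violations vs the chance rate of a Poisson train
  # with the unit's mean rate
  viol <- sum(isi < refractory)
  expected <- length(isi) * (1 - exp(-rate * refractory))
  contamination <- if (expected > 0) viol / expected else 0
  crit["contamination"] <- contamination < 0.20
  # ISI peak location within the first 5 ms (1-ms bins)
  early <- isi[isi < 0.005]
  if (length(early)) {
    h <- tabulate(pmin(5L, floor(early / 0.001) + 1L), nbins = 5)
    crit["isi_peak"] <- which.max(h) > 2
  }
  # sudden spikes in the ISI histogram shape
  hh <- tabulate(floor(isi[isi < isi_max] / 0.001) + 1L,
                 nbins = round(isi_max / 0.001))
  if (sum(hh) >= 10) {
    srt <- sort(hh, decreasing = TRUE)
    crit["isi_spike"] <- srt[1] < 4 * max(srt[2], 1)
  }
  list(pass = all(crit), criteria = crit, mean_rate = rate,
       contamination = contamination)
}
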