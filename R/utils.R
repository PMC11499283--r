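# Internal numerical helpers shared across modules.

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector (may contain -Inf)
#' @return scalar log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible child seed from a parent seed and an index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483563) + 1L
}

# Gaussian smoothing of a time series sampled at dt, with kernel s.d. sd_s
# (both in seconds). Edges renormalised so that the kernel mass used is 1,
# which preserves the mean of interior samples exactly.
gauss_smooth <- function(x, dt, sd_s) {
  if (sd_s <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_s / dt))
  tt <- (-half:half) * dt
  k <- exp(-tt^2 / (2 * sd_s^2))
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(NA_real_, half), x, rep(NA_real_, half))
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- xp[i:(i + 2 * half)]
    ok <- !is.na(seg)
    out[i] <- sum(seg[ok] * k[ok]) / sum(k[ok])
  }
  out
}

# Rows of a matrix smoothed with gauss_smooth.
gauss_smooth_rows <- function(m, dt, sd_s) {
  t(apply(m, 1, gauss_smooth, dt = dt, sd_s = sd_s))
}

# Bin spike times into counts on a grid of left edges `edges` (half-open
# bins [e, e + dt)).
bin_spikes <- function(spike_times, edges, dt) {
  if (!length(spike_times)) return(numeric(length(edges)))
  idx <- floor((spike_times - edges[1]) / dt) + 1
  idx <- idx[idx >= 1 & idx <= length(edges)]
  tabulate(idx, nbins = length(edges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
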