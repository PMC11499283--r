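# Movement-onset estimation from the motion-energy trace.

#' Detect orofacial movement onset before each lick
#'
#' For each lick, the motion-energy values in a 2-s window centred on the
#' lick are fitted with a 3-component Gaussian mixture; the movement
#' threshold is the mean plus two standard deviations of the component
#' with the lowest mean (the noise floor). Scanning backward in time from
#' the lick, the sample preceding the first sub-threshold sample is taken
#' as the movement onset.
#'
#' @param trace data.frame with `t` and `energy` (session clock).
#' @param lick_times lick times on the same clock.
#' @param window half-width irrelevant: the window is `lick +/- 1` s.
#' @param n_components mixture size (default 3).
#' @return data.frame with `lick_time`, `onset` (`NA` when the trace never
#'   drops below threshold in the window), `threshold`, `undefined` flag.
#' @export
detect_motion_onset <- function(trace, lick_times, window = 1,
                                n_components = 3) {
  out <- data.frame(lick_time = lick_times, onset = NA_real_,
                    threshold = NA_real_, undefined = FALSE)
  for (i in seq_along(lick_times)) {
    lk <- lick_times[i]
    inw <- trace$t >= lk - window & trace$t <= lk + window
    v <- trace$energy[inw]; tv <- trace$t[inw]
    if (length(v) < 10) { out$undefined[i] <- TRUE; next }
    thr <- motion_threshold(v, n_components)
    out$threshold[i] <- thr
    pre <- which(tv <= lk)
    # no movement in progress at the lick itself: there is no burst whose
    # onset could be dated
    if (v[pre[length(pre)]] < thr) { out$undefined[i] <- TRUE; next }
    below <- pre[v[pre] < thr]
    if (!length(below)) { out$undefined[i] <- TRUE; next }
    last_below <- max(below)
    # the sample preceding the first sub-threshold sample, scanning
    # backward from the lick, marks the onset
    out$onset[i] <- if (last_below < length(tv)) tv[last_below + 1] else
      tv[last_below]
  }
  out
}

#' Noise-floor threshold from a Gaussian mixture
#'
#' Fits an `n_components` univariate Gaussian mixture (EM with k-means
#' initialisation, unequal variances) to the energy values and returns
#' `mu_low + 2 * sd_low` of the component with the lowest mean.
#'
#' @param values motion-energy samples.
#' @param n_components mixture size.
#' @return threshold value.
#' @export
motion_threshold <- function(values, n_components = 3) {
  fit <- fit_gmm1d(values, n_components)
  if (is.null(fit)) {  # degenerate windows: fall back to a robust floor
    mu <- stats::median(values); s <- stats::mad(values)
    return(mu + 2 * s)
  }
  k <- which.min(fit$mean)
  fit$mean[k] + 2 * fit$sd[k]
}

#' Univariate Gaussian-mixture EM
#'
#' Plain EM for a k-component 1-D Gaussian mixture with unequal
#' variances: k-means initialisation (deterministic given the data,
#' 25 starts), responsibility updates in log space, variances floored at
#' 1e-6 times the data variance. Returns `NULL` when the data are
#' (near-)degenerate.
#'
#' @param x samples.
#' @param k number of components.
#' @param max_iter,tol EM stopping rule.
#' @return list with `mean`, `sd`, `weight`, `loglik`, `iterations`, or
#'   `NULL` on degenerate input.
#' @export
fit_gmm1d <- function(x, k = 3, max_iter = 200, tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(x) < 5 * k || stats::sd(x) == 0) return(NULL)
  km <- tryCatch(suppressWarnings(stats::kmeans(x, k, nstart = 25)),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  mu <- as.numeric(km$centers)
  sd_ <- vapply(seq_len(k), function(j) {
    v <- stats::sd(x[km$cluster == j])
    if (!is.finite(v) || v == 0) stats::sd(x) / k else v
  }, numeric(1))
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / length(x)
  sd_floor <- 1e-3 * stats::sd(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sd_[j], log = TRUE),
      numeric(length(x)))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    r <- exp(lp - lse)
    nk <- colSums(r)
    w <- nk / length(x)
    mu <- colSums(r * x) / nk
    sd_ <- sqrt(colSums(r * (x - rep(mu, each = length(x)))^2) / nk)
    sd_ <- pmax(sd_, sd_floor)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mean = mu, sd = sd_, weight = w, loglik = ll, iterations = it)
}
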