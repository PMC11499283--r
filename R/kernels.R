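# Kernel summary metrics: peak time, FWHM, change-kernel ramping and the
# focality index of encoding across areas.

# First crossing time of `level` by linear interpolation on grid tt.
first_crossing <- function(tt, w, level) {
  above <- w >= level
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(tt[1])
  t0 <- tt[i - 1]; t1 <- tt[i]
  w0 <- w[i - 1]; w1 <- w[i]
  t0 + (level - w0) / (w1 - w0) * (t1 - t0)
}

#' Peak time and full width at half maximum of a TF kernel
#'
#' The peak is the largest absolute weight within `search` seconds of lag
#' zero; if that weight is negative the kernel is sign-flipped before
#' measuring the width. FWHM is found by linear interpolation at half
#' the peak on either side; a side that never drops below half extends
#' to the kernel edge. Ties at the peak break to the earliest lag.
#'
#' @param kernel weight vector on the 50-ms lag grid.
#' @param lag lag grid (s); defaults to `0, 0.05, ...`.
#' @param search peak search window (s, default 1).
#' @return list with `peak_time`, `peak`, `fwhm`, `flipped`; all `NA` for
#'   an all-zero kernel.
#' @export
kernel_metrics <- function(kernel, lag = (seq_along(kernel) - 1) * 0.05,
                           search = 1) {
  if (all(kernel == 0)) return(list(peak_time = NA_real_, peak = NA_real_,
                                    fwhm = NA_real_, flipped = NA))
  inw <- lag <= search
  p <- which(inw)[which.max(abs(kernel[inw]))]
  flipped <- kernel[p] < 0
  w <- if (flipped) -kernel else kernel
  half <- w[p] / 2
  # walk left / right from the peak to the half-maximum crossings
  left <- lag[1]
  for (i in seq(p, 1)) if (w[i] < half) {
    left <- lag[i] + (half - w[i]) / (w[i + 1] - w[i]) * (lag[i + 1] - lag[i])
    break
  }
  right <- lag[length(lag)]
  for (i in seq(p, length(w))) if (w[i] < half) {
    right <- lag[i - 1] + (w[i - 1] - half) / (w[i - 1] - w[i]) *
      (lag[i] - lag[i - 1])
    break
  }
  list(peak_time = lag[p], peak = w[p], fwhm = right - left,
       flipped = flipped)
}

# Rise time of a single mean change kernel: mean of the 33.33rd, 50th and
# 66.66th percentile-of-maximum crossing times.
kernel_rise_time <- function(kernel, lag) {
  m <- max(kernel)
  if (m <= 0) return(NA_real_)
  cr <- vapply(c(1 / 3, 0.5, 2 / 3), function(q)
    first_crossing(lag, kernel, q * m), numeric(1))
  if (any(is.na(cr))) return(NA_real_)
  mean(cr)
}

#' Ramping of change kernels versus change size
#'
#' For each change size, the mean change kernel across units (sign-
#' flipped per unit where `flip` says the unit's fast-pulse response is
#' negative) is reduced to a 50%-rise time: the mean of its 33.33rd,
#' 50th and 66.66th percentile-of-maximum crossings. The rise times are
#' regressed against log2 change size; the slope CI comes from
#' bootstrapping units.
#'
#' @param kernels list over change sizes of units x lags weight matrices.
#' @param magnitudes change sizes (Hz), same length as `kernels`.
#' @param lag lag grid (s).
#' @param flip logical per unit: negate that unit's kernels before
#'   averaging (default none).
#' @param n_boot bootstrap repetitions over units (default 10000).
#' @param seed optional integer seed.
#' @return list with `rise_times` (per magnitude; `NA`-dropped sizes are
#'   reported in `dropped`), `slope` (s per octave), `ci`, `boot_slopes`.
#' @export
change_kernel_ramp <- function(kernels, magnitudes, lag,
                               flip = NULL, n_boot = 10000, seed = NULL) {
  stopifnot(length(kernels) == length(magnitudes), length(magnitudes) >= 2)
  if (!is.null(seed)) set.seed(seed)
  nu <- nrow(kernels[[1]])
  flip <- flip %||% rep(FALSE, nu)
  sgn <- ifelse(flip, -1, 1)
  rise_of <- function(idx) {
    vapply(kernels, function(K) {
      mk <- colMeans(K[idx, , drop = FALSE] * sgn[idx])
      kernel_rise_time(mk, lag)
    }, numeric(1))
  }
  slope_of <- function(rt) {
    ok <- !is.na(rt)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(rt[ok] ~ log2(magnitudes[ok])))[2])
  }
  rt <- rise_of(seq_len(nu))
  boot <- vapply(seq_len(n_boot), function(b)
    slope_of(rise_of(sample.int(nu, nu, replace = TRUE))), numeric(1))
  list(rise_times = rt, dropped = magnitudes[is.na(rt)],
       slope = slope_of(rt),
       ci = stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE),
       boot_slopes = boot)
}

#' Focality index of encoding across areas
#'
#' `F = sum(p_a^2) / (sum(p_a))^2` over the per-area proportions of
#' encoding units: 1 when encoding is confined to one area, `1/N` when
#' perfectly distributed over `N` areas.
#'
#' @param p_a per-area proportions of encoding units (all >= 0, at least
#'   one positive).
#' @return the focality index.
#' @export
focality_from_proportions <- function(p_a) {
  if (all(p_a == 0)) return(NA_real_)
  sum(p_a^2) / sum(p_a)^2
}

#' Focality index from unit-level flags, with bootstrap CI
#'
#' @param coding logical per unit (encodes the variable?).
#' @param area area label per unit.
#' @param n_boot bootstrap repetitions over units (default 10000).
#' @param seed optional integer seed.
#' @return list with `F`, `p_a`, `ci`, `boot`.
#' @export
focality_index <- function(coding, area, n_boot = 10000, seed = NULL) {
  stopifnot(length(coding) == length(area))
  if (!is.null(seed)) set.seed(seed)
  areas <- sort(unique(area))
  prop <- function(idx) {
    vapply(areas, function(a) {
      sel <- area[idx] == a
      if (!any(sel)) 0 else mean(coding[idx][sel])
    }, numeric(1))
  }
  n <- length(coding)
  p_a <- prop(seq_len(n))
  boot <- vapply(seq_len(n_boot), function(b)
    focality_from_proportions(prop(sample.int(n, n, replace = TRUE))),
    numeric(1))
  list(F = focality_from_proportions(p_a), p_a = p_a,
       ci = stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE),
       boot = boot)
}
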