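# Outlier-detection decision agent: a null model in which a response is
# triggered when a single noisy sample of the log2-TF stimulus crosses a
# bound, followed by a stochastic shifted-log-logistic non-decision delay.
# All probability computations are done in log space on the 60-Hz video
# frame grid.

FRAME_DT <- 1 / 60

#' Expand a 50-ms pulse stream to the 60-Hz frame grid
#'
#' Each 50-ms pulse covers exactly 3 monitor frames; the log2-TF value is
#' held constant across its frames.
#'
#' @param log2_tf per-pulse log2-TF vector.
#' @param frames_per_pulse frames per pulse (default 3).
#' @return per-frame log2-TF vector; frame `i` covers time
#'   `((i-1) * dt, i * dt]` with `dt = 1/60` s.
#' @export
pulses_to_frames <- function(log2_tf, frames_per_pulse = 3) {
  rep(log2_tf, each = frames_per_pulse)
}

#' Agent parameter container
#'
#' @param sigma2 sensory noise variance (octaves^2), > 0.
#' @param bound_b decision bound (octaves).
#' @param alpha,beta,gamma shifted log-logistic delay parameters
#'   (location > 0, scale > 0, shape > 1).
#' @return validated list of class `agent_params`.
#' @export
agent_params <- function(sigma2, bound_b, alpha, beta, gamma) {
  stopifnot(sigma2 > 0, alpha > 0, beta > 0, gamma > 1)
  structure(list(sigma2 = sigma2, bound_b = bound_b,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "agent_params")
}

#' Decision-time distribution of the outlier-detection agent
#'
#' At each frame the noisy sensory sample is `Z_i = s_i + eps_i` with
#' `eps_i ~ N(0, sigma2)`. The decision occurs at the first frame where
#' `Z_i > b`; the per-frame non-crossing probability is
#' `Phi((b - s_i)/sigma)`, and the survivor function is the running
#' product of these terms. The distribution includes an atom at infinity
#' (bound never crossed before the stimulus ends).
#'
#' @param s_frames per-frame log2-TF stimulus (see [pulses_to_frames()]).
#' @param sigma2 sensory noise variance (octaves^2).
#' @param bound_b decision bound (octaves).
#' @return list with `t` (frame times, s), `log_pmf`, `pmf`,
#'   `log_survivor` (survivor through each frame) and `log_p_inf`
#'   (atom at infinity).
#' @export
decision_time_distribution <- function(s_frames, sigma2, bound_b) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (any(!is.finite(s_frames))) stop("non-finite stimulus")
  n <- length(s_frames)
  sigma <- sqrt(sigma2)
  log_phi <- stats::pnorm((bound_b - s_frames) / sigma, log.p = TRUE)
  log_cross <- stats::pnorm((bound_b - s_frames) / sigma, log.p = TRUE,
                            lower.tail = FALSE)
  log_surv <- cumsum(log_phi)
  log_pmf <- c(0, log_surv[-n]) + log_cross
  list(t = seq_len(n) * FRAME_DT, log_pmf = log_pmf, pmf = exp(log_pmf),
       log_survivor = log_surv, log_p_inf = log_surv[n])
}

#' Shifted log-logistic delay density and distribution
#'
#' Density is zero below the location `alpha`; with shape `gamma > 1` it is
#' bump-shaped above it.
#'
#' @param x delay values (s).
#' @param alpha,beta,gamma location (s), scale (s) and shape.
#' @param log return the log density?
#' @return density (or log density) at `x`.
#' @export
dloglogis <- function(x, alpha, beta, gamma, log = FALSE) {
  stopifnot(alpha > 0, beta > 0, gamma > 1)
  z <- (x - alpha) / beta
  out <- rep(-Inf, length(x))
  ok <- is.finite(z) & z > 0
  out[ok] <- log(gamma) + (gamma - 1) * log(z[ok]) - log(beta) -
    2 * log1p(z[ok]^gamma)
  if (log) out else exp(out)
}

#' @rdname dloglogis
#' @param lower.tail if `FALSE`, return the survival function.
#' @export
ploglogis <- function(x, alpha, beta, gamma, lower.tail = TRUE) {
  stopifnot(alpha > 0, beta > 0, gamma > 1)
  z <- pmax((x - alpha) / beta, 0)
  p <- ifelse(z > 0, 1 / (1 + z^(-gamma)), 0)
  if (lower.tail) p else 1 - p
}

#' @rdname dloglogis
#' @param n number of random draws.
#' @export
rloglogis <- function(n, alpha, beta, gamma) {
  stopifnot(alpha > 0, beta > 0, gamma > 1)
  u <- stats::runif(n)
  alpha + beta * (u / (1 - u))^(1 / gamma)
}

#' Response-time distribution (decision + delay convolution)
#'
#' The response time is `R = D + Delta` with independent decision time `D`
#' (discrete, on the frame grid) and delay `Delta` (continuous); its
#' density/CDF is the convolution `p_R(r) = sum_d p_D(d) p_Delta(r - d)`,
#' where terms with `d > r` vanish. Sums are computed in log space.
#'
#' @param decision output of [decision_time_distribution()].
#' @param alpha,beta,gamma delay parameters.
#' @param r_grid times at which to evaluate (defaults to the decision grid).
#' @return list with `r`, `pdf`, `cdf` (both include only finite decisions;
#'   the atom at infinity contributes mass `exp(decision$log_p_inf)` beyond
#'   any finite time).
#' @export
response_time_distribution <- function(decision, alpha, beta, gamma,
                                       r_grid = NULL) {
  r_grid <- r_grid %||% decision$t
  pdf <- vapply(r_grid, function(r)
    exp(log_pR_at(decision, r, alpha, beta, gamma)), numeric(1))
  cdf <- vapply(r_grid, function(r) {
    dx <- r - decision$t
    ok <- dx > 0
    if (!any(ok)) return(0)
    exp(logsumexp(decision$log_pmf[ok] +
                    log(pmax(ploglogis(dx[ok], alpha, beta, gamma), 1e-300))))
  }, numeric(1))
  list(r = r_grid, pdf = pdf, cdf = cdf, log_p_inf = decision$log_p_inf)
}

# log p_R(r) for a single response time r.
log_pR_at <- function(decision, r, alpha, beta, gamma) {
  dx <- r - decision$t
  ok <- dx > alpha
  if (!any(ok)) return(-Inf)
  logsumexp(decision$log_pmf[ok] + dloglogis(dx[ok], alpha, beta, gamma,
                                             log = TRUE))
}

# log(1 - F_R(t_end)): censored-likelihood term for miss trials. Includes
# the never-crossing atom and decisions whose delay extends past t_end.
log_survival_at <- function(decision, t_end, alpha, beta, gamma) {
  surv_delay <- ploglogis(t_end - decision$t, alpha, beta, gamma,
                          lower.tail = FALSE)
  logsumexp(c(decision$log_p_inf,
              decision$log_pmf + log(pmax(surv_delay, 1e-300))))
}

#' Fit the delay distribution to large-change hit reaction times
#'
#' Maximum likelihood for the shifted log-logistic delay, using reaction
#' times on hit trials with the largest change magnitude (where the
#' decision is assumed to occur at the change point, so the reaction time
#' approximates the delay). Constraints: `alpha > 0`, `gamma > 1`.
#' Bounded quasi-Newton optimisation with random multi-starts.
#'
#' @param rts reaction times, s; all must be positive.
#' @param n_starts number of random restarts.
#' @param seed optional integer seed for the restarts.
#' @return list with `alpha`, `beta`, `gamma`, `logLik`, `convergence`.
#' @export
fit_delay_distribution <- function(rts, n_starts = 10, seed = NULL) {
  if (any(rts <= 0)) stop("reaction times must be positive")
  if (length(rts) < 30) stop("need at least 30 reaction times")
  if (!is.null(seed)) set.seed(seed)
  rmin <- min(rts)
  nll <- function(p) {
    a <- p[1]; b <- p[2]; g <- p[3]
    if (a <= 0 || a >= rmin || b <= 0 || g <= 1) return(1e10)
    v <- -sum(dloglogis(rts, a, b, g, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- c(stats::runif(1, 0.05, 0.95) * rmin,
               stats::runif(1, 0.2, 2) * stats::sd(rts),
               stats::runif(1, 1.5, 6))
    fit <- try(stats::optim(start, nll, method = "L-BFGS-B",
                            lower = c(1e-6, 1e-6, 1 + 1e-6),
                            upper = c(rmin - 1e-6, Inf, Inf)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("delay fit failed to converge from any start")
  list(alpha = best$par[1], beta = best$par[2], gamma = best$par[3],
       logLik = -best$value, convergence = best$convergence)
}

# Marginal log likelihood of a behavioural dataset under (sigma2, b) with
# the delay fixed. `trials` is a list of lists with elements:
#   s_frames  per-frame log2-TF over the full trial,
#   outcome   "hit" / "early" / "miss" (aborts excluded upstream),
#   r         movement-onset time (s), NA for misses.
agent_loglik <- function(trials, sigma2, bound_b, alpha, beta, gamma) {
  ll <- 0
  for (tr in trials) {
    dec <- decision_time_distribution(tr$s_frames, sigma2, bound_b)
    ll <- ll + if (tr$outcome == "miss")
      log_survival_at(dec, length(tr$s_frames) * FRAME_DT, alpha, beta, gamma)
    else
      log_pR_at(dec, tr$r, alpha, beta, gamma)
  }
  ll
}

#' Fit the decision parameters (sensory noise and bound)
#'
#' Maximises the log marginal likelihood of observed responses with the
#' delay distribution held fixed: non-miss trials contribute the response
#' density at the observed movement-onset time, miss trials the
#' right-censored mass beyond the last time point. Coarse 2-D grid search
#' followed by Nelder-Mead refinement.
#'
#' @param trials list of trial records (see Details in
#'   [sample_agent_datasets()]): each has `s_frames`, `outcome`, `r`.
#' @param delay fitted delay parameters (list with `alpha`, `beta`,
#'   `gamma`).
#' @param sigma_grid,b_grid coarse search grids for sigma (octaves) and
#'   the bound (octaves).
#' @return list with `sigma2`, `bound_b`, `logLik`, `grid` (the coarse
#'   objective surface) and `boundary` flag (optimum on the grid edge).
#' @export
fit_decision_params <- function(trials, delay,
                                sigma_grid = exp(seq(log(0.1), log(1.2),
                                                     length.out = 7)),
                                b_grid = seq(0.4, 2.2, length.out = 7)) {
  if (all(vapply(trials, function(x) x$outcome, "") == "miss"))
    warning("all-miss dataset: decision parameters weakly identified")
  # the non-miss likelihood only reads frames before the observed
  # movement onset: truncate those stimuli once, up front
  trials <- lapply(trials, function(tr) {
    if (tr$outcome != "miss" && is.finite(tr$r))
      tr$s_frames <- tr$s_frames[seq_len(min(length(tr$s_frames),
                                             ceiling(tr$r * 60)))]
    tr
  })
  obj <- function(p) {
    sg <- exp(p[1]); b <- p[2]
    v <- -agent_loglik(trials, sg^2, b, delay$alpha, delay$beta, delay$gamma)
    if (!is.finite(v)) 1e10 else v
  }
  grid <- expand.grid(sigma = sigma_grid, b = b_grid)
  grid$nll <- vapply(seq_len(nrow(grid)),
                     function(i) obj(c(log(grid$sigma[i]), grid$b[i])),
                     numeric(1))
  i0 <- which.min(grid$nll)
  boundary <- grid$sigma[i0] %in% range(sigma_grid) ||
    grid$b[i0] %in% range(b_grid)
  fit <- stats::optim(c(log(grid$sigma[i0]), grid$b[i0]), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  list(sigma2 = exp(fit$par[1])^2, bound_b = fit$par[2],
       logLik = -fit$value, grid = grid, boundary = boundary)
}

#' Sample synthetic behavioural datasets from a fitted agent
#'
#' Each synthetic trial reuses the real (or generated) stimulus; stimulus
#' values that were never shown because the trial ended early are refilled
#' from the baseline distribution. A decision time is drawn by sampling
#' the per-frame crossings, a delay is drawn from the shifted log-logistic,
#' their sum is the movement onset, and the lick time adds a
#' movement-to-lick delay resampled with replacement from the supplied
#' pool. Outcomes are classified hit / early / miss from the lick time
#' against the change epoch.
#'
#' @param params `agent_params` (or any list with `sigma2`, `bound_b`,
#'   `alpha`, `beta`, `gamma`).
#' @param sessions stimulus sessions ([simulate_stimulus_sessions()]).
#' @param move_to_lick pool of movement-to-lick delays (s) resampled per
#'   trial; must be non-empty.
#' @param n_datasets number of synthetic datasets.
#' @param sigma_octaves baseline s.d. used to refill missing stimulus.
#' @param seed optional integer seed; dataset `k` derives its own seed so
#'   it is individually reproducible.
#' @return list of `n_datasets` behaviour data.frames (`trial_id`,
#'   `outcome`, `movement_onset`, `lick_time`, `change_onset`,
#'   `change_magnitude`).
#' @export
sample_agent_datasets <- function(params, sessions, move_to_lick,
                                  n_datasets = 1, sigma_octaves = 0.25,
                                  seed = NULL) {
  if (!length(move_to_lick)) stop("empty movement-to-lick delay pool")
  seed <- seed %||% 1L
  trials <- sessions$trials
  psplit <- split(sessions$pulses$log2_tf, sessions$pulses$trial_id)
  sframes <- lapply(trials$trial_id, function(id)
    pulses_to_frames(psplit[[as.character(id)]]))
  sigma <- sqrt(params$sigma2)
  out <- vector("list", n_datasets)
  for (k in seq_len(n_datasets)) {
    set.seed(derive_seed(seed, k))
    n_tr <- nrow(trials)
    movement <- rep(NA_real_, n_tr); lick <- rep(NA_real_, n_tr)
    outcome <- rep("miss", n_tr)
    for (j in seq_len(n_tr)) {
      s <- sframes[[j]]
      p_cross <- stats::pnorm((params$bound_b - s) / sigma,
                              lower.tail = FALSE)
      hit_i <- which(stats::runif(length(s)) < p_cross)
      if (!length(hit_i)) next
      d <- hit_i[1] * FRAME_DT
      r <- d + rloglogis(1, params$alpha, params$beta, params$gamma)
      l <- r + sample(move_to_lick, 1, replace = TRUE)
      movement[j] <- r; lick[j] <- l
      co <- trials$change_onset[j]; dur <- trials$change_duration[j]
      outcome[j] <- if (!is.na(co) && l >= co && l <= co + dur) "hit"
      else if ((!is.na(co) && l < co) ||
                 (is.na(co) && l <= trials$duration[j])) "early" else "miss"
      if (outcome[j] == "miss") { movement[j] <- NA; lick[j] <- NA }
    }
    out[[k]] <- data.frame(trial_id = trials$trial_id, outcome = outcome,
                           movement_onset = movement, lick_time = lick,
                           change_onset = trials$change_onset,
                           change_magnitude = trials$change_magnitude)
  }
  out
}

#' Reaction times on large-change hit trials
#'
#' Extracts the delay-fitting sample: movement-onset times relative to
#' the change point on hit trials with the largest change magnitude.
#' Reaction times at or below one video frame (1/60 s) are excluded --
#' the earliest possible post-change decision falls on the first change
#' frame, so faster "reactions" can only come from decisions taken
#' before the change and are not delay observations.
#'
#' @param behaviour behaviour table with `outcome`, `movement_onset`,
#'   `change_onset`, `change_magnitude`.
#' @param magnitude the large change magnitude (default the maximum
#'   present).
#' @param min_rt exclusion floor, s (default one frame).
#' @return numeric vector of reaction times (s).
#' @export
bigchange_hit_rts <- function(behaviour, magnitude = NULL, min_rt = 1 / 60) {
  magnitude <- magnitude %||% max(behaviour$change_magnitude, na.rm = TRUE)
  h <- behaviour[behaviour$outcome == "hit" &
                   !is.na(behaviour$change_magnitude) &
                   behaviour$change_magnitude == magnitude, ]
  rt <- h$movement_onset - h$change_onset
  rt[!is.na(rt) & rt > min_rt]
}

#' Assemble trial records for agent likelihood fitting
#'
#' Converts a stimulus session set plus a behaviour table into the list of
#' per-trial records ( `s_frames`, `outcome`, `r`) consumed by
#' [fit_decision_params()]. Abort trials are dropped. For responded
#' trials the stimulus is truncated at the movement-onset frame plus the
#' delay support is retained (full stimulus kept; the likelihood only
#' reads frames before `r`).
#'
#' @param sessions stimulus sessions.
#' @param behaviour behaviour table with `trial_id`, `outcome`,
#'   `movement_onset`.
#' @return list of trial records.
#' @export
agent_trials <- function(sessions, behaviour) {
  psplit <- split(sessions$pulses$log2_tf, sessions$pulses$trial_id)
  keep <- behaviour$outcome != "abort"
  lapply(which(keep), function(j) {
    id <- behaviour$trial_id[j]
    list(s_frames = pulses_to_frames(psplit[[as.character(id)]]),
         outcome = behaviour$outcome[j],
         r = behaviour$movement_onset[j])
  })
}
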