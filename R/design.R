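# Design-matrix construction for the Poisson encoding GLM: 19 task
# predictor groups, each temporally unfolded in 50-ms steps over its
# printed kernel window.

#' Default GLM design configuration
#'
#' The 19 predictor groups and their kernel windows (seconds relative to
#' the predictor event; a window `[lo, hi]` yields `(hi - lo)/0.05`
#' lagged columns): TF fluctuations 0-1.5 s; trial start 0-1 s;
#' time-since-baseline ramp (single column, rising linearly from 1 s
#' after trial start to the change onset); six change-onset kernels
#' 0-2 s (one per change size, with a catch-all slot for off-menu
#' sizes); lick preparation -1.25-0 s; lick execution 0-0.5 s; air-puff
#' 0-0.25 s; reward 0-0.4 s; abort -1.25-0.25 s; grating phase for
#' upward and downward drift (12 bins of 30 degrees each); motion energy
#' -0.05-0.8 s; wheel -0.05-0.8 s; pupil -0.75-0.75 s.
#'
#' @param groups optional character vector restricting which groups are
#'   built (default all 19).
#' @param change_sizes change magnitudes (Hz) given their own change
#'   kernel; any other magnitude falls into the catch-all group.
#' @return config list with `bin_dt`, `change_sizes` and per-group specs.
#' @export
glm_design_config <- function(groups = NULL,
                              change_sizes = c(1.25, 1.35, 1.5, 2, 4)) {
  specs <- list(
    tf          = list(type = "continuous", window = c(0, 1.5)),
    trial_start = list(type = "event", window = c(0, 1)),
    time_ramp   = list(type = "ramp", window = c(0, 0)),
    lick_prep   = list(type = "event", window = c(-1.25, 0)),
    lick_exec   = list(type = "event", window = c(0, 0.5)),
    air_puff    = list(type = "event", window = c(0, 0.25)),
    reward      = list(type = "event", window = c(0, 0.4)),
    abort       = list(type = "event", window = c(-1.25, 0.25)),
    phase_up    = list(type = "phase", window = c(0, 0)),
    phase_down  = list(type = "phase", window = c(0, 0)),
    motion      = list(type = "continuous", window = c(-0.05, 0.8)),
    wheel       = list(type = "continuous", window = c(-0.05, 0.8)),
    pupil       = list(type = "continuous", window = c(-0.75, 0.75))
  )
  for (i in seq_along(change_sizes))
    specs[[paste0("change_", change_sizes[i])]] <-
      list(type = "event", window = c(0, 2))
  specs$change_other <- list(type = "event", window = c(0, 2))
  if (!is.null(groups)) specs <- specs[groups]
  list(bin_dt = 0.05, change_sizes = change_sizes, specs = specs)
}

# Lag grid (seconds) for a group window on the 50-ms clock.
group_lags <- function(window, dt = 0.05) {
  if (window[2] <= window[1]) return(0)  # single-column groups
  seq(window[1], window[2] - dt, by = dt)
}

# Column of x shifted so that row i holds x[i - k] (k = lag in bins),
# restricted within a single trial (zeros elsewhere).
shift_within <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) {
    if (k < n) out[(k + 1):n] <- x[1:(n - k)]
  } else {
    if (-k < n) out[1:(n + k)] <- x[(1 - k):n]
  }
  out
}

#' Build the GLM design matrix
#'
#' Bins every trial at 50 ms from baseline onset to trial end and unfolds
#' each configured predictor group over its kernel window; shifts never
#' bleed across trials. Continuous signals are z-scored across the whole
#' session before unfolding. Grating phase advances with the
#' instantaneous TF (cycles = integral of TF in Hz) and is one-hot coded
#' into 12 30-degree bins, separately for upward and downward drift
#' trials.
#'
#' @param sessions stimulus sessions.
#' @param behaviour behaviour table (`trial_id`, `outcome`, `lick_time`,
#'   `movement_onset`, `change_onset`, `change_magnitude`; optional
#'   `abort_time`).
#' @param signals optional list of continuous traces, each a function of
#'   (trial_id, t_bins) or a long data.frame (`trial_id`, `t`, `value`)
#'   sampled on the 50-ms grid; names among "motion", "wheel", "pupil".
#'   Missing streams for configured groups are an error.
#' @param config design configuration from [glm_design_config()].
#' @return list of class `glm_design`: `X` (sparse dgCMatrix), `bins`
#'   (data.frame `trial_id`, `t`), `groups` (data.frame `name`, `first`,
#'   `last`, `n_cols`, `lag` list), `config`.
#' @export
build_design <- function(sessions, behaviour, signals = list(),
                         config = glm_design_config()) {
  dt <- config$bin_dt
  trials <- sessions$trials
  beh <- behaviour[match(trials$trial_id, behaviour$trial_id), ]
  psplit <- split(sessions$pulses, sessions$pulses$trial_id)
  nb <- trials$n_pulses
  bins <- data.frame(trial_id = rep(trials$trial_id, nb),
                     t = unlist(lapply(nb, function(n) (seq_len(n) - 1) * dt)))
  n_rows <- nrow(bins)
  sig_lookup <- function(nm) {
    s <- signals[[nm]]
    if (is.null(s)) stop("missing stream for configured group: ", nm)
    if (is.data.frame(s)) {
      key <- paste(bins$trial_id, round(bins$t / dt))
      skey <- paste(s$trial_id, round(s$t / dt))
      v <- s$value[match(key, skey)]
      v[is.na(v)] <- 0
      v
    } else s(bins$trial_id, bins$t)
  }
  base_streams <- list()
  for (nm in names(config$specs)) {
    sp <- config$specs[[nm]]
    if (sp$type == "continuous" && nm != "tf") {
      v <- sig_lookup(nm)
      z <- as.numeric(scale(v))  # z-score per session
      if (all(!is.finite(z))) z <- numeric(length(v))
      base_streams[[nm]] <- z
    }
  }
  # per-trial base indicator/value vectors
  ev_time <- function(nm, j) {
    co <- beh$change_onset[j]; mag <- beh$change_magnitude[j]
    switch(nm,
      trial_start = 0,
      lick_prep = beh$lick_time[j],
      lick_exec = beh$lick_time[j],
      air_puff = if (identical(beh$outcome[j], "early")) beh$lick_time[j] else NA,
      reward = if (identical(beh$outcome[j], "hit")) beh$lick_time[j] else NA,
      abort = if (identical(beh$outcome[j], "abort"))
        (beh$abort_time[j] %||% NA_real_) else NA,
      change_other = if (!is.na(co) && !is.na(mag) &&
                           !mag %in% config$change_sizes) co else NA,
      {
        if (startsWith(nm, "change_")) {
          sz <- as.numeric(sub("change_", "", nm))
          if (!is.na(co) && isTRUE(abs(mag - sz) < 1e-9)) co else NA
        } else NA
      })
  }
  blocks <- list()
  group_tab <- data.frame(name = character(), first = integer(),
                          last = integer(), n_cols = integer())
  col0 <- 0
  row_off <- c(0, cumsum(nb))
  for (nm in names(config$specs)) {
    sp <- config$specs[[nm]]
    lags <- group_lags(sp$window, dt)
    if (sp$type == "phase") {
      ncol_g <- 12
      M <- matrix(0, n_rows, ncol_g)
      dir_lab <- if (nm == "phase_up") "up" else "down"
      for (j in seq_len(nrow(trials))) {
        if (!identical(trials$drift_direction[j], dir_lab)) next
        pp <- psplit[[as.character(trials$trial_id[j])]]
        cyc <- cumsum(2^pp$log2_tf * dt)        # cycles elapsed
        ph <- (cyc %% 1)
        bin_ix <- pmin(12L, floor(ph * 12) + 1L)
        rows <- row_off[j] + seq_len(nb[j])
        M[cbind(rows, bin_ix)] <- 1
      }
    } else if (sp$type == "ramp") {
      ncol_g <- 1
      M <- matrix(0, n_rows, 1)
      for (j in seq_len(nrow(trials))) {
        rows <- row_off[j] + seq_len(nb[j])
        tt <- bins$t[rows]
        endt <- if (!is.na(beh$change_onset[j])) beh$change_onset[j] else
          trials$duration[j]
        r <- (tt - 1) / max(endt - 1, dt)
        r[r < 0] <- 0; r[r > 1] <- 1
        r[tt >= endt] <- 0
        M[rows, 1] <- r
      }
    } else {
      ncol_g <- length(lags)
      M <- matrix(0, n_rows, ncol_g)
      for (j in seq_len(nrow(trials))) {
        rows <- row_off[j] + seq_len(nb[j])
        base <- numeric(nb[j])
        if (sp$type == "continuous") {
          if (nm == "tf") {
            pp <- psplit[[as.character(trials$trial_id[j])]]
            base <- ifelse(pp$epoch == "baseline", pp$log2_tf, 0)
          } else base <- base_streams[[nm]][rows]
        } else {
          e <- ev_time(nm, j)
          if (!is.na(e)) {
            bi <- floor(e / dt + 1e-9) + 1
            if (bi >= 1 && bi <= nb[j]) base[bi] <- 1
          }
        }
        for (li in seq_along(lags))
          M[rows, li] <- shift_within(base, round(lags[li] / dt))
      }
    }
    blocks[[nm]] <- M
    group_tab <- rbind(group_tab,
                       data.frame(name = nm, first = col0 + 1,
                                  last = col0 + ncol_g, n_cols = ncol_g))
    col0 <- col0 + ncol_g
  }
  X <- Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
  colnames(X) <- unlist(lapply(names(config$specs), function(nm) {
    sp <- config$specs[[nm]]
    if (sp$type == "phase") paste0(nm, "_b", 1:12)
    else if (sp$type == "ramp") nm
    else paste0(nm, "_", format(group_lags(sp$window, dt), trim = TRUE))
  }))
  structure(list(X = X, bins = bins, groups = group_tab, config = config),
            class = "glm_design")
}

#' Bin a unit's spikes onto the design rows
#'
#' @param pop population from [simulate_population()] (or any list with
#'   `spikes` having `unit_id`, `trial_id`, `t_trial`).
#' @param unit_id which unit.
#' @param design a `glm_design`.
#' @return integer vector of 50-ms spike counts aligned with `design$X`
#'   rows.
#' @export
design_spike_counts <- function(pop, unit_id, design) {
  dt <- design$config$bin_dt
  sp <- pop$spikes[pop$spikes$unit_id == unit_id, ]
  y <- integer(nrow(design$bins))
  key_bins <- paste(design$bins$trial_id, round(design$bins$t / dt))
  ok <- sp$t_trial >= 0
  key_sp <- paste(sp$trial_id[ok], floor(sp$t_trial[ok] / dt + 1e-9))
  tb <- table(key_sp)
  m <- match(names(tb), key_bins)
  good <- !is.na(m)
  y[m[good]] <- as.integer(tb[good])
  y
}
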