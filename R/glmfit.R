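# Poisson ridge fitting with nested cross-validation, and the reduced-
# model significance test used to classify TF-responsive, lick-preparation
# and lick-execution units.

#' Ridge penalty grid
#'
#' 20 log-spaced values spanning 1e-3 to 1e3.
#' @return numeric vector, decreasing (as glmnet expects).
#' @export
glm_lambda_grid <- function() rev(exp(seq(log(1e-3), log(1e3), length.out = 20)))

#' Fit a Poisson ridge GLM with nested cross-validation
#'
#' Ten outer folds assigned by trial; within each training set the ridge
#' penalty is tuned by inner 10-fold cross-validation (also by trial)
#' over [glm_lambda_grid()], using cyclical coordinate descent
#' (`glmnet`, `alpha = 0`). Held-out predicted rates are assembled
#' across the outer folds.
#'
#' @param design a `glm_design`.
#' @param y spike counts per bin (non-negative integers).
#' @param n_folds outer folds (default 10).
#' @param seed seed for the fold assignment.
#' @return list of class `glm_fit`: `weights` (p x folds, no intercept),
#'   `intercepts`, `lambda` per fold, `cv_pred` (held-out predicted rate
#'   per bin, counts per 50-ms bin), `fold_of_trial`, `fold_rows`.
#' @export
fit_poisson_ridge <- function(design, y, n_folds = 10, seed = 1) {
  stopifnot(all(y >= 0), length(y) == nrow(design$X))
  X <- design$X
  trial_ids <- design$bins$trial_id
  utr <- unique(trial_ids)
  set.seed(seed)
  fold_of_trial <- sample(rep_len(seq_len(n_folds), length(utr)))
  names(fold_of_trial) <- utr
  fold_row <- fold_of_trial[as.character(trial_ids)]
  p <- ncol(X)
  W <- matrix(NA_real_, p, n_folds)
  b0 <- numeric(n_folds); lam <- numeric(n_folds)
  cv_pred <- numeric(length(y))
  lambda_grid <- glm_lambda_grid()
  for (k in seq_len(n_folds)) {
    tr <- fold_row != k
    tr_trials <- unique(trial_ids[tr])
    inner <- sample(rep_len(seq_len(10), length(tr_trials)))
    names(inner) <- tr_trials
    foldid <- inner[as.character(trial_ids[tr])]
    cvfit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                               family = "poisson", alpha = 0,
                               lambda = lambda_grid, foldid = foldid,
                               standardize = FALSE, thresh = 1e-5)
    lam[k] <- cvfit$lambda.min
    co <- stats::coef(cvfit, s = "lambda.min")
    b0[k] <- co[1]
    W[, k] <- co[-1]
    cv_pred[!tr] <- as.numeric(
      stats::predict(cvfit, newx = X[!tr, , drop = FALSE],
                     s = "lambda.min", type = "response"))
  }
  structure(list(weights = W, intercepts = b0, lambda = lam,
                 cv_pred = cv_pred, fold_of_trial = fold_of_trial,
                 fold_rows = fold_row, converged = TRUE),
            class = "glm_fit")
}

#' Extract the mean kernel of a predictor group
#'
#' @param fit a `glm_fit`.
#' @param design the `glm_design` it was fitted on.
#' @param group group name (e.g. "tf").
#' @return list with `lag` (s) and `weight` (mean across folds).
#' @export
glm_kernel <- function(fit, design, group) {
  g <- design$groups[design$groups$name == group, ]
  if (!nrow(g)) stop("unknown group: ", group)
  w <- rowMeans(fit$weights[g$first:g$last, , drop = FALSE])
  sp <- design$config$specs[[group]]
  list(lag = group_lags(sp$window, design$config$bin_dt), weight = w)
}

# Event-aligned PETH of an arbitrary per-bin vector. events: data.frame
# (trial_id, t). Returns mean over events at each lag of `window` (s),
# dropping events whose window leaves the trial.
vector_peth <- function(v, bins, events, window, dt = 0.05) {
  lags <- seq(window[1], window[2] - dt / 2, by = dt)
  nlag <- length(lags)
  row_of <- split(seq_len(nrow(bins)), bins$trial_id)
  acc <- numeric(nlag); nev <- 0
  for (i in seq_len(nrow(events))) {
    rows <- row_of[[as.character(events$trial_id[i])]]
    if (is.null(rows)) next
    b0 <- round(events$t[i] / dt)
    ix <- b0 + round(lags / dt) + 1
    if (any(ix < 1) || any(ix > length(rows))) next
    acc <- acc + v[rows[ix]]
    nev <- nev + 1
  }
  if (!nev) return(NULL)
  list(lag = lags, mean = acc / nev, n = nev)
}

#' Reduced-model significance test for one predictor of interest
#'
#' Classification uses two joint criteria, evaluated on event-aligned
#' PETHs computed per held-out fold: (1) the mean across folds of the
#' Pearson correlation between the full model's held-out prediction and
#' the actual PETH exceeds 0.2; (2) a t-test across the 10 folds of the
#' correlation between the actual PETH and the residual prediction (full
#' minus reduced prediction) is significant at P < 0.01. For the TF flag
#' the PETH is the fast-minus-slow pulse response.
#'
#' @param full,reduced `glm_fit` objects for the full model and the model
#'   without the predictor(s) of interest (same folds).
#' @param y actual spike counts per bin.
#' @param design the shared `glm_design`.
#' @param events event table (`trial_id`, `t`) for the PETH, or for TF a
#'   list `list(fast = ..., slow = ...)`.
#' @param window PETH window in seconds.
#' @param cor_threshold criterion-1 threshold (default 0.2).
#' @param p_threshold criterion-2 threshold (default 0.01).
#' @return list with `flag`, `mean_cor`, `p_residual`, per-fold stats.
#' @export
nested_model_test <- function(full, reduced, y, design, events,
                              window, cor_threshold = 0.2,
                              p_threshold = 0.01) {
  n_folds <- length(full$intercepts)
  if (n_folds < 10) stop("need 10 cross-validation folds")
  contrast <- is.list(events) && !is.data.frame(events)
  cor_full <- rep(NA_real_, n_folds)
  cor_resid <- rep(NA_real_, n_folds)
  for (k in seq_len(n_folds)) {
    test_trials <- as.numeric(names(full$fold_of_trial))[full$fold_of_trial == k]
    sel <- function(ev) ev[ev$trial_id %in% test_trials, , drop = FALSE]
    peth3 <- function(ev) {
      ev <- sel(ev)
      if (!nrow(ev)) return(NULL)
      a <- vector_peth(y, design$bins, ev, window)
      f <- vector_peth(full$cv_pred, design$bins, ev, window)
      r <- vector_peth(reduced$cv_pred, design$bins, ev, window)
      if (is.null(a) || is.null(f) || is.null(r)) return(NULL)
      list(a = a$mean, f = f$mean, r = r$mean)
    }
    if (contrast) {
      pf <- peth3(events$fast); ps <- peth3(events$slow)
      if (is.null(pf) || is.null(ps)) next
      a <- pf$a - ps$a; f <- pf$f - ps$f; r <- pf$r - ps$r
    } else {
      pp <- peth3(events)
      if (is.null(pp)) next
      a <- pp$a; f <- pp$f; r <- pp$r
    }
    if (stats::sd(a) > 0 && stats::sd(f) > 0)
      cor_full[k] <- stats::cor(a, f)
    resid <- f - r
    if (stats::sd(a) > 0 && stats::sd(resid) > 0)
      cor_resid[k] <- stats::cor(a, resid)
  }
  mean_cor <- mean(cor_full, na.rm = TRUE)
  ok <- !is.na(cor_resid)
  p_res <- if (sum(ok) >= 3 && stats::sd(cor_resid[ok]) > 0)
    stats::t.test(cor_resid[ok], mu = 0, alternative = "greater")$p.value
  else 1
  list(flag = isTRUE(mean_cor > cor_threshold) && p_res < p_threshold,
       mean_cor = mean_cor, p_residual = p_res,
       cor_full = cor_full, cor_resid = cor_resid)
}

#' Classify units as TF-responsive / preparation / execution
#'
#' Fits the full model and the three reduced models for each unit and
#' applies [nested_model_test()] with the standard event windows:
#' fast-minus-slow pulse response (-0.15 to 0.75 s; fast/slow at
#' +/-0.5 s.d. for event selection), pre-lick activity (-1.25 to 0 s)
#' and post-lick activity (0 to 0.25 s). The reduced models drop,
#' respectively: the TF group; the lick-preparation group; and the
#' execution, motion-energy and wheel groups.
#'
#' @param pop spike population.
#' @param design full `glm_design`.
#' @param sessions,behaviour the generating session/behaviour tables.
#' @param unit_ids units to classify (default all).
#' @param sigma_octaves baseline s.d. for pulse-event selection.
#' @param seed fold seed (shared across full/reduced fits).
#' @param flags which classifications to run (subset of "tf", "prep",
#'   "exec"); unrun flags come back `NA`.
#' @return data.frame per unit with flags and criterion statistics.
#' @export
classify_units <- function(pop, design, sessions, behaviour,
                           unit_ids = NULL, sigma_octaves = 0.25,
                           seed = 1, flags = c("tf", "prep", "exec")) {
  unit_ids <- unit_ids %||% pop$units$unit_id
  pl <- sessions$pulses
  base <- pl[pl$epoch == "baseline", ]
  ev_fast <- base[base$log2_tf > 0.5 * sigma_octaves, c("trial_id", "t")]
  ev_slow <- base[base$log2_tf < -0.5 * sigma_octaves, c("trial_id", "t")]
  lk <- behaviour[!is.na(behaviour$lick_time), ]
  ev_lick <- data.frame(trial_id = lk$trial_id, t = lk$lick_time)
  cfg <- design$config
  drop_groups <- function(gr) {
    keep <- setdiff(names(cfg$specs), gr)
    d2 <- design
    cols <- unlist(lapply(keep, function(nm) {
      g <- design$groups[design$groups$name == nm, ]
      g$first:g$last
    }))
    d2$X <- design$X[, cols, drop = FALSE]
    d2$groups <- NULL  # reduced designs are only used for fitting
    d2
  }
  red_designs <- list(
    tf = drop_groups("tf"),
    prep = drop_groups("lick_prep"),
    exec = drop_groups(intersect(c("lick_exec", "motion", "wheel"),
                                 names(cfg$specs)))
  )
  na_res <- list(flag = NA, mean_cor = NA_real_, p_residual = NA_real_)
  out <- lapply(unit_ids, function(u) {
    y <- design_spike_counts(pop, u, design)
    full <- fit_poisson_ridge(design, y, seed = seed)
    res <- list(tf = na_res, prep = na_res, exec = na_res)
    if ("tf" %in% flags) {
      red <- fit_poisson_ridge(red_designs$tf, y, seed = seed)
      res$tf <- nested_model_test(full, red, y, design,
                                  list(fast = ev_fast, slow = ev_slow),
                                  c(-0.15, 0.75))
    }
    if ("prep" %in% flags) {
      red <- fit_poisson_ridge(red_designs$prep, y, seed = seed)
      res$prep <- nested_model_test(full, red, y, design, ev_lick,
                                    c(-1.25, 0))
    }
    if ("exec" %in% flags) {
      red <- fit_poisson_ridge(red_designs$exec, y, seed = seed)
      res$exec <- nested_model_test(full, red, y, design, ev_lick,
                                    c(0, 0.25))
    }
    data.frame(unit_id = u,
               is_tf_responsive = res$tf$flag, tf_cor = res$tf$mean_cor,
               tf_p = res$tf$p_residual,
               is_prep = res$prep$flag, prep_cor = res$prep$mean_cor,
               prep_p = res$prep$p_residual,
               is_exec = res$exec$flag, exec_cor = res$exec$mean_cor,
               exec_p = res$exec$p_residual)
  })
  do.call(rbind, out)
}
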