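# Movement / movement-null population-subspace framework: pre-processing,
# PCA, the linear mapping onto an orofacial reference, null-space
# construction, occupancy, subpopulation contributions and pulse-response
# alignment.

#' Trial-averaged population rate matrix around an event
#'
#' Builds the units x time mean-rate matrix used by the subspace
#' analyses: spike counts in 10-ms bins aligned to a per-trial event,
#' averaged over trials, then smoothed with a two-sided Gaussian of
#' 30 ms s.d.
#'
#' @param pop spike population ([simulate_population()]).
#' @param events data.frame (`trial_id`, `t`) of alignment events
#'   (trial-relative times).
#' @param window time window around the event, s.
#' @param bin bin width, s (default 0.01).
#' @param smooth_sd Gaussian smoothing s.d., s (default 0.03).
#' @param min_trials units from sessions with fewer qualifying trials are
#'   dropped; with a single pooled population this applies to the whole
#'   matrix.
#' @return list with `rates` (units x time, Hz), `time` (bin centres,
#'   event at 0), `unit_ids`.
#' @export
population_peth <- function(pop, events, window = c(-2, 1.5), bin = 0.01,
                            smooth_sd = 0.03, min_trials = 10) {
  if (nrow(events) < min_trials)
    warning("fewer than ", min_trials, " qualifying trials")
  unit_ids <- sort(unique(pop$units$unit_id))
  nb <- round((window[2] - window[1]) / bin)
  tt <- window[1] + (seq_len(nb) - 0.5) * bin
  rates <- matrix(0, length(unit_ids), nb)
  sp_by_unit <- split(pop$spikes, pop$spikes$unit_id)
  for (ui in seq_along(unit_ids)) {
    sp <- sp_by_unit[[as.character(unit_ids[ui])]]
    acc <- numeric(nb)
    ssp <- if (!is.null(sp)) split(sp$t_trial, sp$trial_id) else list()
    for (j in seq_len(nrow(events))) {
      st <- ssp[[as.character(events$trial_id[j])]]
      if (is.null(st)) next
      rel <- st - events$t[j]
      sel <- rel >= window[1] & rel < window[2]
      ix <- floor((rel[sel] - window[1]) / bin) + 1
      if (length(ix)) acc <- acc + tabulate(ix, nbins = nb)
    }
    rates[ui, ] <- gauss_smooth(acc / (nrow(events) * bin), bin, smooth_sd)
  }
  list(rates = rates, time = tt, unit_ids = unit_ids)
}

#' Pre-process a population rate matrix
#'
#' Soft-normalisation `r' = r / (7 + max(r) - min(r))` per unit, then
#' mean-centering: each unit's mean across time is subtracted, then the
#' mean across units at every time point. After this every time column
#' has zero mean across units.
#'
#' @param rates units x time matrix (Hz).
#' @param soft_const soft-normalisation constant (default 7, roughly the
#'   20th percentile of rate ranges in the recordings this emulates).
#' @return list with `M` (pre-processed matrix), `norm` (per-unit
#'   divisors).
#' @export
preprocess_population <- function(rates, soft_const = 7) {
  rng <- apply(rates, 1, function(x) max(x) - min(x))
  M <- rates / (soft_const + rng)
  M <- M - rowMeans(M)
  M <- sweep(M, 2, colMeans(M))
  list(M = M, norm = soft_const + rng)
}

#' Principal-component projections of a population matrix
#'
#' SVD-based PCA of the pre-processed matrix `N = U S V'`; returns the
#' leading loadings and the projections `U' N`, with the initial state
#' (mean over `init_win`) subtracted from every projection.
#'
#' @param M pre-processed units x time matrix.
#' @param time time grid (s).
#' @param n_pc number of components (4 for target regions, 2 for the
#'   orofacial reference).
#' @param init_win window defining the initial state, s.
#' @return list with `U` (units x n_pc), `proj` (n_pc x time,
#'   initial-state zeroed), `svd`, `time`, `init_win`.
#' @export
population_pca <- function(M, time, n_pc = 4, init_win = c(-2, -1.5)) {
  sv <- svd(M)
  U <- sv$u[, seq_len(n_pc), drop = FALSE]
  proj <- t(U) %*% M
  ini <- time >= init_win[1] & time < init_win[2]
  proj <- proj - rowMeans(proj[, ini, drop = FALSE])
  list(U = U, proj = proj, d = sv$d, time = time, init_win = init_win)
}

#' Linear mapping from target projections onto the movement subspace
#'
#' Least-squares fit of `M_ref ~ W %*% N_target` over the fit window
#' (default \[-0.1, 1.5\] s around lick onset, the period containing the
#' reference population's movement-related activity). Regions with
#' R-squared below 0.8 should be excluded by the caller.
#'
#' @param target_proj n_pc x time projections of the target region
#'   (initial-state zeroed).
#' @param ref_proj 2 x time projections of the orofacial reference.
#' @param time shared time grid (s).
#' @param fit_win fit window, s.
#' @return list with `W` (2 x n_pc), `r_squared`, `excluded`
#'   (R-squared < 0.8), `fit_win`.
#' @export
fit_movement_mapping <- function(target_proj, ref_proj, time,
                                 fit_win = c(-0.1, 1.5)) {
  inw <- time >= fit_win[1] & time <= fit_win[2]
  Nf <- target_proj[, inw, drop = FALSE]
  Mf <- ref_proj[, inw, drop = FALSE]
  G <- Nf %*% t(Nf)
  if (rcond(G) < 1e-12) {
    warning("rank-deficient target projections")
    W <- Mf %*% t(Nf) %*% MASS_ginv(G)
  } else W <- Mf %*% t(Nf) %*% solve(G)
  resid <- Mf - W %*% Nf
  ss_tot <- sum((Mf - rowMeans(Mf))^2)
  r2 <- 1 - sum(resid^2) / ss_tot
  list(W = W, r_squared = r2, excluded = r2 < 0.8, fit_win = fit_win)
}

# Minimal Moore-Penrose pseudoinverse (degenerate mappings only).
MASS_ginv <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Movement-null basis with rotation and sign conventions
#'
#' `W_null` spans the null space of `W` (rows orthogonal to both rows of
#' `W`), scaled so its Frobenius norm equals that of `W`. The first null
#' dimension is rotated (closed-form, from the 2 x 2 covariance of the
#' null projections before lick onset) to capture the most pre-lick
#' variance. Signs: each movement dimension is flipped so the mean of
#' the reference projection over \[-2, 0.5\] s is positive; each null
#' dimension so the mean of the target's null projection over \[-2, 0\] s
#' is positive.
#'
#' @param W 2 x n_pc movement mapping.
#' @param target_proj n_pc x time target projections (initial-state
#'   zeroed).
#' @param ref_proj 2 x time reference projections (for the movement-sign
#'   convention).
#' @param time time grid (s).
#' @param prelick_win window whose variance the first null dimension
#'   maximises, s.
#' @return list with `W` (sign-fixed), `W_null`, `rotation_angle`,
#'   `sign_mov`, `sign_null`.
#' @export
null_space_basis <- function(W, target_proj, ref_proj, time,
                             prelick_win = c(-2, 0)) {
  sv <- svd(t(W), nu = ncol(W))
  K <- sv$u[, (nrow(W) + 1):ncol(W), drop = FALSE]  # orthonormal null basis
  normW <- sqrt(sum(W^2))
  W_null <- t(K) * (normW / sqrt(ncol(K)))
  # rotate the first null dimension onto the direction of maximal
  # pre-lick variance (closed form from the 2x2 covariance)
  inw <- time >= prelick_win[1] & time <= prelick_win[2]
  P <- W_null %*% target_proj[, inw, drop = FALSE]
  C <- stats::cov(t(P))
  if (all(abs(C) < 1e-15)) {
    theta <- 0
    warning("degenerate pre-lick activity; null basis left unrotated")
  } else theta <- 0.5 * atan2(2 * C[1, 2], C[1, 1] - C[2, 2])
  # first rotated dimension = (cos theta, sin theta), the principal
  # direction of the pre-lick covariance
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2,
              byrow = TRUE)
  W_null <- R %*% W_null
  # sign conventions
  mwin <- time >= -2 & time <= 0.5
  sign_mov <- sign(rowMeans(ref_proj[, mwin, drop = FALSE]))
  sign_mov[sign_mov == 0] <- 1
  W <- W * sign_mov
  nwin <- time >= -2 & time <= 0
  pn <- W_null %*% target_proj
  sign_null <- sign(rowMeans(pn[, nwin, drop = FALSE]))
  sign_null[sign_null == 0] <- 1
  W_null <- W_null * sign_null
  list(W = W, W_null = W_null, rotation_angle = theta,
       sign_mov = sign_mov, sign_null = sign_null)
}

#' Subspace occupancy
#'
#' Euclidean distances of the neural state from the initial state within
#' the movement (`E_m`) and movement-null (`E_null`) subspaces, and the
#' relative occupancy `O_R = (E_null - E_m)/(E_null + E_m)`: +1 when the
#' state moves only in the null subspace, -1 only in the movement
#' subspace. Peak-normalised occupancy `O = E / max(E)` is returned per
#' subspace.
#'
#' @param target_proj n_pc x time projections (initial-state zeroed).
#' @param W,W_null the subspace operators.
#' @param time time grid (s).
#' @param init_win initial-state window, s.
#' @return data.frame with `time`, `E_m`, `E_null`, `O_R` (`NA` where
#'   both distances are zero), `O_m`, `O_null`.
#' @export
subspace_occupancy <- function(target_proj, W, W_null, time,
                               init_win = c(-2, -1.5)) {
  pm <- W %*% target_proj
  pn <- W_null %*% target_proj
  ini <- time >= init_win[1] & time < init_win[2]
  pm <- pm - rowMeans(pm[, ini, drop = FALSE])
  pn <- pn - rowMeans(pn[, ini, drop = FALSE])
  E_m <- sqrt(colSums(pm^2))
  E_null <- sqrt(colSums(pn^2))
  tot <- E_null + E_m
  data.frame(time = time, E_m = E_m, E_null = E_null,
             O_R = ifelse(tot > 0, (E_null - E_m) / tot, NA_real_),
             O_m = E_m / max(E_m), O_null = E_null / max(E_null))
}

#' Decompose projections into flagged and complement contributions
#'
#' Splits the loadings `U` by unit identity (e.g. TF-responsive vs not):
#' `N_flag` uses the flagged units' loadings with zeros elsewhere, so
#' `N_flag + N_rest = U' N` exactly. The relative contribution of the
#' flagged set along each subspace at time `t` is the projection ratio
#' `w(t) = <x_flag(t), x(t)> / ||x(t)||^2`, which sums to 1 with the
#' complement wherever the projection is nonzero. The chance
#' distribution repeats the decomposition for random unit subsets of the
#' same size.
#'
#' @param U units x n_pc loadings.
#' @param M pre-processed units x time matrix.
#' @param flags logical per unit.
#' @param W,W_null subspace operators.
#' @param n_random random subsets for the chance distribution
#'   (default 2000).
#' @param seed optional integer seed.
#' @return list with `w_mov`, `w_null` (time series), `chance_mov`,
#'   `chance_null` (n_random x time matrices), and the split projections.
#' @export
decompose_contributions <- function(U, M, flags, W, W_null,
                                    n_random = 2000, seed = NULL) {
  if (!any(flags)) stop("empty flagged set")
  if (!is.null(seed)) set.seed(seed)
  proj_of <- function(f) {
    Uf <- U; Uf[!f, ] <- 0
    t(Uf) %*% M
  }
  N_all <- t(U) %*% M
  contrib <- function(f) {
    Nf <- proj_of(f)
    xm <- W %*% Nf; x <- W %*% N_all
    xn <- W_null %*% Nf; xa <- W_null %*% N_all
    list(mov = colSums(xm * x) / pmax(colSums(x^2), .Machine$double.eps),
         null = colSums(xn * xa) / pmax(colSums(xa^2), .Machine$double.eps))
  }
  main <- contrib(flags)
  nf <- sum(flags); nu <- length(flags)
  ch_m <- matrix(NA_real_, n_random, ncol(M))
  ch_n <- matrix(NA_real_, n_random, ncol(M))
  for (b in seq_len(n_random)) {
    f <- rep(FALSE, nu); f[sample.int(nu, nf)] <- TRUE
    cc <- contrib(f)
    ch_m[b, ] <- cc$mov; ch_n[b, ] <- cc$null
  }
  list(w_mov = main$mov, w_null = main$null,
       chance_mov = ch_m, chance_null = ch_n,
       N_flag = proj_of(flags), N_rest = proj_of(!flags), N_all = N_all)
}

#' Alignment of pulse responses with the subspace dimensions
#'
#' Projects a (pre-processed, same normalisation state) pulse-response
#' matrix with the hit-lick loadings `U`, maps into the 4-D
#' movement/movement-null coordinates, and evaluates the cosine between
#' the trajectory and each dimension at the time of maximal Euclidean
#' distance from the initial state within `search` seconds of pulse
#' onset.
#'
#' @param pulse_M pre-processed units x time pulse-response matrix.
#' @param U hit-lick loadings (units x n_pc).
#' @param W,W_null subspace operators.
#' @param time time grid (s, pulse onset at 0).
#' @param init_win initial-state window, s.
#' @param search window for the max-distance time, s (default 0.75).
#' @return list with `traj` (4 x time: movement dims then null dims),
#'   `t_peak`, `cosines` (length 4), `peak_null1` (projection on the
#'   first null dimension at `t_peak`).
#' @export
pulse_projection_alignment <- function(pulse_M, U, W, W_null, time,
                                       init_win = c(-0.5, 0),
                                       search = 0.75) {
  proj <- t(U) %*% pulse_M
  ini <- time >= init_win[1] & time < init_win[2]
  proj <- proj - rowMeans(proj[, ini, drop = FALSE])
  traj <- rbind(W %*% proj, W_null %*% proj)
  dist <- sqrt(colSums(traj^2))
  inw <- which(time >= 0 & time <= search)
  if (!length(inw) || all(dist[inw] == 0))
    return(list(traj = traj, t_peak = NA_real_,
                cosines = rep(NA_real_, 4), peak_null1 = NA_real_))
  ipk <- inw[which.max(dist[inw])]
  v <- traj[, ipk]
  list(traj = traj, t_peak = time[ipk], cosines = v / sqrt(sum(v^2)),
       peak_null1 = traj[3, ipk])
}

#' Cross-validated projections
#'
#' Repeatedly splits trials into equally sized fit and test halves (the
#' odd trial goes to the fit half), averages each half into a rate
#' matrix, pre-processes both, runs PCA on the fit half and projects the
#' test half onto the fit loadings (signs aligned to the full-data
#' loadings). Returns 2.5/97.5 percentile bands of the test projections
#' over repetitions.
#'
#' @param trial_rates units x time x trials array of binned rates.
#' @param time time grid (s).
#' @param n_pc components (default 4).
#' @param n_reps repetitions (default 2000).
#' @param init_win initial-state window, s.
#' @param smooth_sd Gaussian smoothing s.d. applied to each half's mean
#'   (s); 0 to skip.
#' @param seed optional integer seed.
#' @return list with `band_lo`, `band_hi`, `mean_test` (n_pc x time),
#'   `full_proj`, `n_reps`.
#' @export
crossval_projection <- function(trial_rates, time, n_pc = 4, n_reps = 2000,
                                init_win = c(-2, -1.5), smooth_sd = 0.03,
                                seed = NULL) {
  n_tr <- dim(trial_rates)[3]
  if (n_tr < 20) stop("need at least 20 trials")
  if (!is.null(seed)) set.seed(seed)
  dt <- stats::median(diff(time))
  mk <- function(idx) {
    m <- apply(trial_rates[, , idx, drop = FALSE], c(1, 2), mean)
    if (smooth_sd > 0) m <- gauss_smooth_rows(m, dt, smooth_sd)
    preprocess_population(m)$M
  }
  full <- population_pca(mk(seq_len(n_tr)), time, n_pc, init_win)
  n_fit <- ceiling(n_tr / 2)
  acc <- array(NA_real_, c(n_reps, n_pc, length(time)))
  for (b in seq_len(n_reps)) {
    fit_idx <- sample.int(n_tr, n_fit)
    test_idx <- setdiff(seq_len(n_tr), fit_idx)
    pf <- population_pca(mk(fit_idx), time, n_pc, init_win)
    # align eigenvector signs to the full-data solution
    sgn <- sign(colSums(pf$U * full$U))
    sgn[sgn == 0] <- 1
    Uf <- sweep(pf$U, 2, sgn, `*`)
    pr <- t(Uf) %*% mk(test_idx)
    ini <- time >= init_win[1] & time < init_win[2]
    pr <- pr - rowMeans(pr[, ini, drop = FALSE])
    acc[b, , ] <- pr
  }
  list(band_lo = apply(acc, c(2, 3), stats::quantile, probs = 0.025),
       band_hi = apply(acc, c(2, 3), stats::quantile, probs = 0.975),
       mean_test = apply(acc, c(2, 3), mean),
       full_proj = full$proj, n_reps = n_reps)
}
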