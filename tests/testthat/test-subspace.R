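test_that("pre-processing soft-normalises and centres exactly", {
  set.seed(90)
  rates <- matrix(runif(20 * 100, 0, 5), 20)
  rates[1, ] <- seq(0, 93, length.out = 100)   # range 93 Hz
  pp <- preprocess_population(rates)
  expect_equal(pp$norm[1], 100)
  expect_equal(diff(range(rates[1, ] / pp$norm[1])), 0.93)
  # every time column has zero mean across units
  expect_lt(max(abs(colMeans(pp$M))), 1e-12)
})

test_that("Gaussian smoothing conserves mass for interior activity", {
  set.seed(91)
  # signal supported away from the edges: total mass is conserved
  x <- numeric(500)
  x[100:400] <- abs(rnorm(301, 2))
  xs <- tfpulse:::gauss_smooth(x, 0.01, 0.03)
  expect_lt(abs(sum(xs) - sum(x)), 1e-9)
  # smoothing a constant is exact everywhere, including edges
  expect_equal(tfpulse:::gauss_smooth(rep(2, 50), 0.01, 0.03), rep(2, 50))
})

test_that("movement mapping is linear with R-squared ~ 1 on self-mapping", {
  fitd <- subspace_toy_fit()
  # reference mapped onto itself
  self <- fit_movement_mapping(fitd$prf$proj, fitd$prf$proj, fitd$toy$time)
  expect_gt(self$r_squared, 0.999)
  expect_equal(self$W, diag(2), tolerance = 1e-6)
  # doubling the reference doubles W
  dbl <- fit_movement_mapping(fitd$ptg$proj, 2 * fitd$prf$proj,
                              fitd$toy$time)
  expect_equal(dbl$W, 2 * fitd$map$W, tolerance = 1e-9)
  # the toy target embeds the reference motifs: good fit
  expect_gt(fitd$map$r_squared, 0.8)
  expect_false(fitd$map$excluded)
})

test_that("a region with independent dynamics maps poorly and is excluded", {
  toy <- subspace_toy(seed = 92)
  set.seed(93)
  # replace the target with slow dynamics unrelated to the reference
  alien <- 5 + outer(rnorm(30), sin(seq(0, 3 * pi, length.out = 350))) +
    outer(rnorm(30), cos(seq(0, 1 * pi, length.out = 350))) +
    matrix(rnorm(30 * 350, 0, 0.02), 30)
  ptg <- population_pca(preprocess_population(alien)$M, toy$time, 4)
  prf <- population_pca(preprocess_population(toy$ref)$M, toy$time, 2)
  map <- fit_movement_mapping(ptg$proj, prf$proj, toy$time)
  expect_lt(map$r_squared, 0.8)
  expect_true(map$excluded)
})

test_that("null basis satisfies the orthogonality, norm and rotation conventions", {
  fitd <- subspace_toy_fit()
  W <- fitd$nb$W; Wn <- fitd$nb$W_null
  expect_lt(max(abs(W %*% t(Wn))), 1e-12)
  expect_lt(abs(sqrt(sum(Wn^2)) - sqrt(sum(W^2))), 1e-12)
  # rotation maximises first-dimension pre-lick variance: grid oracle
  P <- Wn %*% fitd$ptg$proj
  inw <- fitd$toy$time <= 0
  v1 <- var(P[1, inw])
  angles <- seq(0, pi, by = pi / 1800)        # 0.1-degree grid
  vmax <- max(vapply(angles, function(a) {
    var(cos(a) * P[1, inw] + sin(a) * P[2, inw])
  }, numeric(1)))
  expect_gte(v1, vmax - 1e-9)
  # sign conventions: the flip factors make the reference projection
  # mean positive over [-2, 0.5] s and the null projections positive
  # over [-2, 0] s
  mwin <- fitd$toy$time >= -2 & fitd$toy$time <= 0.5
  expect_true(all(fitd$nb$sign_mov *
                    rowMeans(fitd$prf$proj[, mwin]) >= 0))
  nwin <- fitd$toy$time >= -2 & fitd$toy$time <= 0
  pn <- Wn %*% fitd$ptg$proj
  expect_true(all(rowMeans(pn[, nwin]) >= 0))
})

test_that("occupancy takes its closed-form values on toy trajectories", {
  W <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Wn <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  tt <- seq(-2, 1, by = 0.1)
  proj <- matrix(0, 4, length(tt))
  proj[3, tt > 0] <- 3                        # move only in the null space
  occ <- subspace_occupancy(proj, W, Wn, tt)
  expect_true(all(occ$O_R[tt > 0] == 1))
  proj2 <- matrix(0, 4, length(tt)); proj2[1, tt > 0] <- 2
  occ2 <- subspace_occupancy(proj2, W, Wn, tt)
  expect_true(all(occ2$O_R[tt > 0] == -1))
  # mixed: E_null = 3, E_m = 1 -> O_R = 0.5
  proj3 <- matrix(0, 4, length(tt)); proj3[1, 31] <- 1; proj3[3, 31] <- 3
  occ3 <- subspace_occupancy(proj3, W, Wn, tt)
  expect_equal(occ3$O_R[31], 0.5)
  expect_true(is.na(occ3$O_R[1]))             # zero state is undefined
})

test_that("contribution decomposition is exactly additive with sane chance levels", {
  fitd <- subspace_toy_fit()
  dec <- decompose_contributions(fitd$ptg$U, fitd$tgt$M, fitd$toy$flags,
                                 fitd$nb$W, fitd$nb$W_null,
                                 n_random = 200, seed = 94)
  # Eq.-style additivity of the split projections
  expect_lt(max(abs(dec$N_flag + dec$N_rest - dec$N_all)), 1e-12)
  # flagged + complement contributions sum to 1
  dec2 <- decompose_contributions(fitd$ptg$U, fitd$tgt$M, !fitd$toy$flags,
                                  fitd$nb$W, fitd$nb$W_null,
                                  n_random = 2, seed = 95)
  expect_lt(max(abs(dec$w_null + dec2$w_null - 1)), 1e-9)
  # full-population flags give w = 1 everywhere
  dall <- decompose_contributions(fitd$ptg$U, fitd$tgt$M,
                                  rep(TRUE, length(fitd$toy$flags)),
                                  fitd$nb$W, fitd$nb$W_null,
                                  n_random = 2, seed = 96)
  expect_lt(max(abs(dall$w_mov - 1)), 1e-9)
  expect_error(decompose_contributions(fitd$ptg$U, fitd$tgt$M,
                                       rep(FALSE, 40), fitd$nb$W,
                                       fitd$nb$W_null))
})

test_that("chance contributions centre on the flagged fraction for exchangeable loadings", {
  set.seed(97)
  U <- matrix(rnorm(60 * 4), 60)
  M <- matrix(rnorm(60 * 80), 60)
  W <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Wn <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  flags <- rep(c(TRUE, FALSE), 30)
  dec <- decompose_contributions(U, M, flags, W, Wn, n_random = 400,
                                 seed = 98)
  expect_lt(abs(mean(dec$chance_null) - 0.5), 0.05)
})

test_that("pulse-response alignment returns unit cosines for axis-aligned responses", {
  W <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Wn <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1))
  tt <- seq(-0.5, 1, by = 0.01)
  U <- diag(4)
  # response along the first null dimension (PC 3)
  M <- matrix(0, 4, length(tt))
  M[3, tt > 0 & tt < 0.5] <- 2
  out <- pulse_projection_alignment(M, U, W, Wn, tt)
  expect_equal(out$cosines, c(0, 0, 1, 0), tolerance = 1e-9)
  expect_equal(out$peak_null1, 2)
  # orthogonal response: cosine 0 on the null dimensions
  M2 <- matrix(0, 4, length(tt)); M2[1, tt > 0 & tt < 0.5] <- 2
  out2 <- pulse_projection_alignment(M2, U, W, Wn, tt)
  expect_equal(out2$cosines[3], 0, tolerance = 1e-9)
})

test_that("cross-validated projections honour the repetition count and cover the full projection", {
  set.seed(99)
  toy <- subspace_toy(n_flag = 15, n_rest = 15, nt = 200, seed = 100)
  n_tr <- 24
  arr <- array(0, c(30, 350, n_tr))
  for (k in seq_len(n_tr))
    arr[, , k] <- toy$rates + matrix(rnorm(30 * 350, 0, 0.3), 30)
  cv <- crossval_projection(arr, toy$time, n_pc = 2, n_reps = 60,
                            smooth_sd = 0, seed = 101)
  expect_equal(cv$n_reps, 60)
  cover <- mean(cv$full_proj[1, ] >= cv$band_lo[1, ] &
                  cv$full_proj[1, ] <= cv$band_hi[1, ])
  expect_gt(cover, 0.8)
  expect_error(crossval_projection(arr[, , 1:10], toy$time))
})
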