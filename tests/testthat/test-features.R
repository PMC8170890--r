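test_that("featurize reports exact values on constant ideal-helix frames", {
  h <- ideal_conf(8)
  tr <- trajectory(list(h, h, h), dt = 0.1)
  fs <- featurize(tr)
  expect_equal(fs$features$rmsd_from_helix$values, rep(0, 3), tolerance = 1e-6)
  expect_equal(fs$features$n_hbonds$values, rep(6, 3))
  expect_equal(fs$features$pp_count$values, rep(8, 3))
  expect_true(all(fs$hbonds$formed))
  expect_error(featurize(trajectory(list(h), dt = 0.1)))
  expect_error(featurize(tr, reference_helix = ideal_conf(5)))
})

test_that("ACF is normalized and rejects degenerate signals", {
  x <- feature_series("x", sin(1:200 / 7) + rnorm(200, 0, 0.1), dt = 0.1)
  a <- autocorrelation(x, max_lag = 5)
  expect_equal(a$value[1], 1)
  expect_true(all(diff(a$lag) > 0))
  expect_error(autocorrelation(feature_series("c", rep(1, 50) + 0 * 1:50, 0.1),
                               max_lag = 1),
               "zero variance")
  expect_error(autocorrelation(x, max_lag = 100))
})

test_that("telegraph-signal ACF matches the analytic two-state decay", {
  k1 <- 0.05; k2 <- 0.1
  K <- matrix(c(-k1, k1, k2, -k2), 2, 2, byrow = TRUE)
  lab <- gillespie_simulate(K, t_total = 1e5, dt = 1, seed = 101)
  a <- autocorrelation(as.numeric(lab), max_lag = 40, dt = 1)
  expect_lt(max(abs(a$value - exp(-(k1 + k2) * a$lag))), 0.05)
  # slow relaxation time from the biexponential fit
  bi <- fit_biexponential(a)
  expect_lt(abs(bi$tau_slow - 1 / (k1 + k2)) / (1 / (k1 + k2)), 0.15)
})

test_that("biexponential fits recover known generation parameters", {
  t <- seq(0, 10, by = 0.05)
  curve2 <- structure(list(lag = t, value = 0.5 * exp(-t / 0.5) +
                             0.5 * exp(-t / 2.0)),
                      class = "acf_curve")
  fit <- fit_biexponential(curve2)
  expect_lt(abs(fit$tau_fast - 0.5) / 0.5, 0.1)
  expect_lt(abs(fit$tau_slow - 2.0) / 2.0, 0.1)
  expect_lt(abs(fit$a1 + fit$a2 - 1), 0.05)
  # pure single exponential: tau_slow recovered within 5%
  curve1 <- structure(list(lag = t, value = exp(-t / 1.5)),
                      class = "acf_curve")
  fit1 <- fit_biexponential(curve1)
  expect_lt(abs(fit1$tau_slow - 1.5) / 1.5, 0.05)
  expect_true(min(fit1$a1, fit1$a2) < 0.05 ||
                abs(fit1$tau_fast - fit1$tau_slow) / fit1$tau_slow < 0.05)
})

test_that("biexponential recovery holds across seeded parameter draws", {
  set.seed(33)
  for (rep in 1:20) {
    tf <- runif(1, 0.1, 1)
    ts <- runif(1, 2, 10)
    a1 <- runif(1, 0.2, 0.8)
    t <- seq(0, 5 * ts, length.out = 400)
    curve <- structure(list(lag = t,
                            value = a1 * exp(-t / tf) +
                              (1 - a1) * exp(-t / ts)),
                       class = "acf_curve")
    fit <- fit_biexponential(curve)
    expect_lt(abs(fit$tau_slow - ts) / ts, 0.1)
    expect_lt(abs(fit$tau_fast - tf) / tf, 0.1)
  }
})

test_that("hydrogen-bond populations estimate known marginals", {
  # deterministic extremes
  all_on <- helixkin:::new_hbond_matrix(matrix(3.0, 50, 4), 0.1)
  expect_equal(hbond_population_profile(all_on)$population, rep(1, 4))
  all_off <- helixkin:::new_hbond_matrix(matrix(4.5, 50, 4), 0.1)
  expect_equal(hbond_population_profile(all_off)$population, rep(0, 4))
  # iid Bernoulli(0.3) bond formation, binomial 3 sigma band
  set.seed(5)
  nf <- 4000
  L <- matrix(ifelse(runif(nf * 4) < 0.3, 3.0, 4.5), nf, 4)
  prof <- hbond_population_profile(helixkin:::new_hbond_matrix(L, 0.1))
  expect_true(all(abs(prof$population - 0.3) < 3 * sqrt(0.3 * 0.7 / nf)))
  expect_true(all(prof$lo <= prof$population & prof$population <= prof$hi))
})

test_that("heat map rows obey the counting identity", {
  # crafted: only HB1 formed
  L <- matrix(4.5, 10, 4)
  L[, 1] <- 3.0
  hm <- hbond_heatmap(helixkin:::new_hbond_matrix(L, 0.1))
  expect_equal(unname(hm$P[2, ]), c(1, 0, 0, 0))
  # all-helix frames fill the top row with ones
  hm2 <- hbond_heatmap(helixkin:::new_hbond_matrix(matrix(3, 5, 4), 0.1))
  expect_equal(unname(hm2$P[5, ]), rep(1, 4))
  # random data: populated row m sums to m, empty rows are NA
  set.seed(9)
  L3 <- matrix(ifelse(runif(600 * 4) < 0.4, 3, 4.5), 600, 4)
  hm3 <- hbond_heatmap(helixkin:::new_hbond_matrix(L3, 0.1))
  for (m in 0:4) {
    if (hm3$frames[m + 1] > 0)
      expect_equal(sum(hm3$P[m + 1, ]), m)
    else
      expect_true(all(is.na(hm3$P[m + 1, ])))
  }
})

test_that("neighbor correlations separate coupled from independent bonds", {
  set.seed(21)
  base <- rnorm(500)
  L <- cbind(base, base, rnorm(500), rnorm(500)) + 3.3
  colnames(L) <- NULL
  cp <- neighbor_correlation(helixkin:::new_hbond_matrix(L, 0.1))
  expect_equal(cp$R[1, 2], 1.0)
  expect_true(all(abs(cp$R - t(cp$R)) < 1e-12))
  expect_equal(unname(diag(cp$R)), rep(1, 4))
  # independent white noise: correlations vanish at 1e4 frames
  Lw <- matrix(rnorm(1e4 * 4), ncol = 4) + 3.3
  cpw <- neighbor_correlation(helixkin:::new_hbond_matrix(Lw, 0.1))
  off <- cpw$R[upper.tri(cpw$R)]
  expect_lt(max(abs(off)), 0.05)
  expect_error(neighbor_correlation(helixkin:::new_hbond_matrix(Lw[1:5, ], 0.1)))
  expect_warning(neighbor_correlation(
    helixkin:::new_hbond_matrix(cbind(Lw[, 1:3], 3.0), 0.1)))
})

test_that("cooperative simulations couple neighboring bonds", {
  sim <- helix_coil_simulate(8, s = 1.4618, sigma = 0.01, t_total = 400,
                             dt = 0.5, seed = 7)
  traj <- render_helix_coil(sim)
  fs <- featurize(traj)
  cp <- neighbor_correlation(fs$hbonds)
  r1 <- cp$profile$mean_r[cp$profile$separation == 1]
  r3 <- cp$profile$mean_r[cp$profile$separation == 3]
  expect_gt(r1, r3)
  expect_gt(r1, 0.2)
})
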