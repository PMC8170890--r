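# small trajectory with three well-separated conformational groups and
# within-group jitter, used for clustering oracles
three_group_traj <- function() {
  spec <- peptide_spec(6)
  set.seed(77)
  jitter_conf <- function(phi, psi, sd = 2) {
    build_conformation(spec, dihedral_set(phi + rnorm(6, 0, sd),
                                          psi + rnorm(6, 0, sd)))
  }
  frames <- c(
    lapply(1:5, function(i) jitter_conf(rep(-62, 6), rep(-41, 6))),
    lapply(1:5, function(i) jitter_conf(rep(-140, 6), rep(150, 6))),
    lapply(1:5, function(i) jitter_conf(rep(-75, 6), rep(150, 6))))
  ord <- order(rep(1:5, 3))  # interleave groups along the "time" axis
  tr <- trajectory(frames[ord], dt = 0.1)
  attr(tr, "group") <- rep(1:3, each = 5)[ord]
  tr
}

test_that("leader clustering matches brute-force grouping at a separating radius", {
  tr <- three_group_traj()
  # brute-force pairwise CA RMSD
  D <- outer(1:15, 1:15, Vectorize(function(i, j)
    ca_rmsd(tr$frames[[i]], tr$frames[[j]])))
  groups <- lapply(1:3, function(g) which(attr(tr, "group") == g))
  within_max <- max(sapply(groups, function(g) max(D[g, g])))
  between_min <- min(sapply(1:2, function(a)
    min(D[groups[[a]], unlist(groups[(a + 1):3])])))
  expect_lt(within_max, between_min)   # radius regime exists
  radius <- (within_max + between_min) / 2
  cl <- cluster_leader(tr, radius)
  expect_identical(cl$n_clusters, 3L)
  for (g in groups)
    expect_length(unique(cl$assignment[g]), 1L)
  # determinism
  cl2 <- cluster_leader(tr, radius)
  expect_identical(cl$assignment, cl2$assignment)
  expect_identical(cl$centers, cl2$centers)
})

test_that("leader clustering honors its radius extremes", {
  tr <- three_group_traj()
  expect_identical(cluster_leader(tr, 100)$n_clusters, 1L)
  tiny <- cluster_leader(tr, 1e-6)
  expect_identical(tiny$n_clusters, 15L)
  expect_error(cluster_leader(tr, 0))
})

test_that("core assignment inherits the last visited core", {
  tr <- three_group_traj()
  cl <- cluster_leader(tr, 3)
  # crafted clustering with known distances: frame 2 sits between cores
  fake <- structure(list(
    centers = c(1L, 3L), radius = 5, assignment = c(1L, 1L, 2L),
    n_clusters = 2L,
    dist = rbind(c(0, 6), c(2.4, 2.5), c(6, 0)),
    dt = 0.1), class = "msm_clustering")
  asg <- assign_cores(NULL, fake, R_c = 1)
  expect_identical(asg$labels, c(1L, 1L, 2L))
  expect_identical(asg$in_core, c(TRUE, FALSE, TRUE))
  # back-fill before the first core entry
  fake2 <- fake
  fake2$dist <- rbind(c(2.4, 2.5), c(0, 6), c(6, 0))
  fake2$assignment <- c(1L, 1L, 2L)
  expect_identical(assign_cores(NULL, fake2, R_c = 1)$labels, c(1L, 1L, 2L))
  # R_c equal to the radius with all frames in core reduces to nearest-center
  asg3 <- assign_cores(tr, cl, R_c = 3)
  if (all(asg3$in_core))
    expect_identical(asg3$labels, cl$assignment)
  expect_error(assign_cores(NULL, fake, R_c = 10))
})

test_that("transition counting reproduces crafted label statistics", {
  alt <- rep(c(1L, 2L), 50)
  tm <- count_transitions(alt, lag = 1, dt = 1)
  expect_equal(tm$T, matrix(c(0, 1, 1, 0), 2, 2))
  const <- rep(1L, 20)
  tmc <- count_transitions(const, lag = 1, dt = 1)
  expect_equal(tmc$T, matrix(1, 1, 1))
  expect_error(count_transitions(alt, lag = 0.5, dt = 1))
  expect_error(count_transitions(alt, lag = 200, dt = 1))
  expect_equal(rowSums(tm$T), c(1, 1))
})

test_that("sampled transition matrices converge to the matrix exponential", {
  rk <- random_reversible_K(3, seed = 2, scale = 0.3)
  lab <- gillespie_simulate(rk$K, t_total = 2e4, dt = 0.5, seed = 12)
  tm <- count_transitions(lab, lag = 0.5, dt = 0.5)
  Texp <- expm_eigen(rk$K, 0.5)
  expect_lt(max(abs(tm$T - Texp)), 0.02)
})

test_that("generator estimation and implied timescales follow the spectrum", {
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  tm <- structure(list(counts = Tm * 100, T = Tm, lag = 1,
                       states = 1:2, reversible = TRUE),
                  class = "transition_model")
  km <- estimate_rate_matrix(tm)
  expect_equal(km$K, matrix(c(-0.1, 0.1, 0.2, -0.2), 2, 2, byrow = TRUE))
  expect_equal(km$timescales, 1 / 0.3)
  expect_equal(sum(km$pi), 1)
  expect_equal(as.vector(km$pi %*% km$K), c(0, 0), tolerance = 1e-12)
  # identity transition matrix gives the zero generator
  tmi <- structure(list(T = diag(2), lag = 1, states = 1:2),
                   class = "transition_model")
  expect_equal(estimate_rate_matrix(tmi)$K, matrix(0, 2, 2))
  # 2-state rate matrix: single timescale 1/(k12 + k21)
  K2 <- matrix(c(-0.156, 0.156, 0.3, -0.3), 2, 2, byrow = TRUE)
  expect_equal(implied_timescales(rate_matrix_model(K2)), 1 / 0.456)
  # dense eigensolver oracle on a reversible 3-state chain
  rk <- random_reversible_K(3, seed = 8)
  ev <- sort(eigen(rk$K, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(implied_timescales(rate_matrix_model(rk$K)),
               -1 / ev[-1], tolerance = 1e-10)
  expect_lte(length(implied_timescales(rate_matrix_model(rk$K))), 2L)
})

test_that("conservation laws hold on sampled kinetic models", {
  rk <- random_reversible_K(4, seed = 5, scale = 0.2)
  lab <- gillespie_simulate(rk$K, t_total = 5e3, dt = 0.5, seed = 6)
  tm <- count_transitions(lab, lag = 0.5, dt = 0.5)
  km <- estimate_rate_matrix(tm)
  expect_lt(max(abs(rowSums(tm$T) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(km$K))), 1e-10)
  expect_equal(sum(km$pi), 1, tolerance = 1e-10)
})

test_that("core-radius calibration selects the closest achieved timescale", {
  tr <- three_group_traj()
  cl <- cluster_leader(tr, 3)
  one <- suppressWarnings(
    calibrate_core_radius(tr, cl, target_tau2 = 1, grid = 2))
  expect_identical(one$R_c, 2)
  expect_true(!is.null(attr(one, "mismatch")))
  # target equal to one candidate's achieved timescale selects it
  sim <- helix_coil_simulate(6, s = 1.5, sigma = 0.05, t_total = 300,
                             dt = 0.5, seed = 3)
  traj <- render_helix_coil(sim)
  cls <- cluster_leader(traj, 3)
  got <- suppressWarnings(
    calibrate_core_radius(traj, cls, target_tau2 = 5,
                          grid = c(1.5, 2.2, 3)))
  taus <- attr(got, "grid_tau2")
  sel <- suppressWarnings(
    calibrate_core_radius(traj, cls,
                          target_tau2 = taus[which.max(is.finite(taus))],
                          grid = c(1.5, 2.2, 3)))
  expect_equal(attr(sel, "achieved_tau2"),
               unname(taus[which.max(is.finite(taus))]))
  expect_error(calibrate_core_radius(traj, cls, 1, grid = numeric(0)))
  expect_error(calibrate_core_radius(traj, cls, 1, grid = 99))
})
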