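test_that("PCCA+ recovers blocks of an exactly lumpable generator", {
  lk <- lumpable_K4()
  km <- rate_matrix_model(lk$K)
  memb <- pcca_plus(km, 2)
  expect_equal(rowSums(memb$chi), rep(1, 4))
  # crisp blocks match {1,2} vs {3,4} (brute-force block structure)
  expect_length(unique(memb$assignment[1:2]), 1L)
  expect_length(unique(memb$assignment[3:4]), 1L)
  expect_false(memb$assignment[1] == memb$assignment[3])
  # memberships are essentially crisp for this weakly coupled system
  expect_gt(min(apply(memb$chi, 1, max)), 0.99)
  expect_error(pcca_plus(km, 1))
  expect_error(pcca_plus(km, 5))
})

test_that("PCCA+ at N equal to the state count is a permutation", {
  rk <- random_reversible_K(3, seed = 4)
  memb <- pcca_plus(rate_matrix_model(rk$K), 3)
  expect_identical(sort(memb$assignment), 1:3)
  expect_equal(memb$chi[cbind(1:3, memb$assignment)], rep(1, 3),
               tolerance = 1e-8)
})

test_that("ODR returns the analytic rates of a lumpable system", {
  lk <- lumpable_K4()
  km <- rate_matrix_model(lk$K)
  memb <- pcca_plus(km, 2)
  red <- odr_fit(km, memb)
  # map aggregate order onto the analytic (A, B) order via populations
  iA <- red$assignment[1]
  iB <- red$assignment[3]
  expect_equal(red$R[iA, iB], lk$R_analytic[1, 2], tolerance = 1e-6)
  expect_equal(red$R[iB, iA], lk$R_analytic[2, 1], tolerance = 1e-6)
  # population conservation within optimizer tolerance
  PiA <- sum(km$pi[1:2])
  expect_equal(red$populations[iA], PiA, tolerance = 1e-6)
  expect_true(all(red$lifetimes > 0))
})

test_that("ODR is a fixed point on an exact two-state generator", {
  K2 <- matrix(c(-0.03, 0.03, 0.4, -0.4), 2, 2, byrow = TRUE)
  km <- rate_matrix_model(K2)
  red <- odr_fit(km, c(1L, 2L))
  expect_equal(red$R, K2, tolerance = 1e-8)
  # dG from off-diagonal rates equals dG from populations
  dg_rates <- free_energy_from_rates(red$R[2, 1], red$R[1, 2], 300)
  dg_pop <- -R_GAS * 300 * log(red$populations[1] / red$populations[2])
  expect_equal(dg_rates, dg_pop, tolerance = 1e-6)
})

test_that("ODR reproduces the slow spectrum of a metastable chain", {
  K <- metastable_K9()
  km <- rate_matrix_model(K)
  memb <- pcca_plus(km, 3)
  # three basins of three consecutive states
  expect_identical(length(unique(memb$assignment[1:3])), 1L)
  expect_identical(length(unique(memb$assignment[4:6])), 1L)
  expect_identical(length(unique(memb$assignment[7:9])), 1L)
  red <- odr_fit(km, memb)
  expect_lt(red$fidelity$rel_dev[1], 0.30)
  expect_lt(red$fidelity$rel_dev[2], 0.30)
  # aggregated stationary distribution preserved
  Pi_true <- as.vector(tapply(km$pi, memb$assignment, sum))
  expect_equal(red$populations, Pi_true, tolerance = 1e-3)
})

test_that("set classification labels helix, coil and intermediates", {
  spec <- peptide_spec(6)
  set.seed(19)
  helixish <- function() build_conformation(spec,
    dihedral_set(rep(-62, 6) + rnorm(6, 0, 2), rep(-41, 6) + rnorm(6, 0, 2)))
  coilish <- function() build_conformation(spec,
    dihedral_set(runif(6, -170, -60), runif(6, 100, 170)))
  frames <- c(replicate(6, helixish(), simplify = FALSE),
              replicate(8, coilish(), simplify = FALSE))
  tr <- trajectory(frames, dt = 0.1)
  cl <- cluster_leader(tr, 2.5)
  # aggregate 1: clusters whose center is helix-like; aggregate 2: rest
  is_helix_center <- sapply(cl$centers, function(i)
    count_helical_hbonds(tr$frames[[i]]) >= 3)
  assign <- ifelse(is_helix_center, 1L, 2L)
  sets <- classify_sets(assign, cl, tr)
  expect_identical(sets$sets$label[1], "helix")
  expect_identical(sets$sets$label[2], "coil")
  expect_identical(sum(sets$sets$label == "intermediate"), 0L)
  # three sets: exactly one intermediate
  assign3 <- assign
  assign3[which(assign == 2L)[1]] <- 3L
  if (length(unique(assign3)) == 3L) {
    sets3 <- classify_sets(assign3, cl, tr)
    expect_identical(sum(sets3$sets$label == "intermediate"), 1L)
    expect_identical(sum(sets3$sets$label == "helix"), 1L)
    expect_identical(sum(sets3$sets$label == "coil"), 1L)
  }
  expect_error(classify_sets(rep(1L, cl$n_clusters), cl, tr))
})

test_that("representative structures follow population with index tie-break", {
  spec <- peptide_spec(6)
  f <- build_conformation(spec, ideal_dihedrals(spec, "helix"))
  g <- build_conformation(spec, ideal_dihedrals(spec, "extended"))
  tr <- trajectory(c(replicate(10, f, simplify = FALSE),
                     replicate(3, g, simplify = FALSE)), dt = 0.1)
  cl <- cluster_leader(tr, 2)
  expect_identical(cl$n_clusters, 2L)
  rep1 <- representative_structure(c(1L, 2L), cl, tr)
  expect_identical(count_helical_hbonds(rep1), 4L)  # 10 > 3 frames
  # equal populations: lowest cluster index wins
  tr2 <- trajectory(c(replicate(3, f, simplify = FALSE),
                      replicate(3, g, simplify = FALSE)), dt = 0.1)
  cl2 <- cluster_leader(tr2, 2)
  rep2 <- representative_structure(c(1L, 2L), cl2, tr2)
  expect_identical(count_helical_hbonds(rep2), 4L)
  expect_error(representative_structure(integer(0), cl, tr))
})

test_that("set inhomogeneity averages pairwise center distances", {
  A <- ca_only_conf(cbind(c(0, 1, 2), 0, 0))
  B <- ca_only_conf(cbind(c(0, 2, 4), 0, 0))
  tr <- trajectory(list(A, B, A), dt = 0.1)
  cl <- structure(list(centers = c(1L, 2L), radius = 1,
                       assignment = c(1L, 2L, 1L), n_clusters = 2L,
                       dist = rbind(c(0, 1), c(1, 0), c(0, 1)), dt = 0.1),
                  class = "msm_clustering")
  # hand Kabsch: centered (-1,0,1) vs (-2,0,2) -> rmsd sqrt(2/3)
  inh <- set_inhomogeneity(list(c(1L, 2L)), cl, tr)
  expect_equal(inh$within[1], sqrt(2 / 3))
  inh2 <- set_inhomogeneity(list(1L, 2L), cl, tr)
  expect_equal(inh2$within, c(0, 0), ignore_attr = TRUE)
  expect_true(all(attr(inh2$within, "singleton")))
  expect_equal(inh2$between[1, 2], sqrt(2 / 3))
})

test_that("reduced-model free energies order inversely to populations", {
  expect_equal(model_free_energies(c(0.5, 0.5)), c(0, 0))
  dg <- model_free_energies(c(0.9, 0.1), T = 300)
  expect_equal(dg[1], 0)
  expect_equal(dg[2], -1.9872e-3 * 300 * log(0.1 / 0.9))
  p <- c(0.5, 0.3, 0.15, 0.05)
  expect_identical(order(model_free_energies(p)), order(-p))
  expect_error(model_free_energies(c(0.4, 0)))
})
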