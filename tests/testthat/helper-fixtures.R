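# Shared fixtures and independent oracles used across the test files.
# Everything here is generated in code; oracles are deliberately naive
# (enumeration, dense eigensolvers, Monte Carlo) and independent of the
# package's computational paths.

ideal_conf <- function(n, kind = "helix") {
  spec <- peptide_spec(n)
  build_conformation(spec, ideal_dihedrals(spec, kind))
}

# bare conformation carrying only CA atoms (for hand-computable RMSD
# and inhomogeneity cases)
ca_only_conf <- function(ca_xyz, n = nrow(ca_xyz)) {
  helixkin:::new_conformation(as.matrix(ca_xyz),
                              rep("CA", nrow(ca_xyz)),
                              seq_len(nrow(ca_xyz)),
                              peptide_spec(max(n, 2L)))
}

# random reversible generator on `n` states with detailed balance
random_reversible_K <- function(n, seed, scale = 1) {
  set.seed(seed)
  pi <- stats::runif(n, 0.2, 1)
  pi <- pi / sum(pi)
  Fl <- matrix(0, n, n)
  Fl[upper.tri(Fl)] <- stats::runif(n * (n - 1) / 2, 0.1, 1) * scale
  Fl <- Fl + t(Fl)
  K <- Fl / pi
  diag(K) <- -rowSums(K)
  list(K = K, pi = pi)
}

# exactly lumpable two-block 4-state generator with the analytic
# lumped rates (A -> B at eps, B -> A at 2 eps)
lumpable_K4 <- function(eps = 1e-2) {
  K <- matrix(0, 4, 4)
  K[1, 2] <- 1.0; K[2, 1] <- 0.5
  K[3, 4] <- 0.8; K[4, 3] <- 0.4
  K[1, 3] <- eps; K[2, 4] <- eps
  K[3, 1] <- 2 * eps; K[4, 2] <- 2 * eps
  diag(K) <- -rowSums(K)
  list(K = K, blocks = list(1:2, 3:4),
       R_analytic = matrix(c(-eps, eps, 2 * eps, -2 * eps), 2, 2,
                           byrow = TRUE))
}

# 9-state chain with three metastable basins (fast intra, slow inter)
metastable_K9 <- function(fast = 1.0, slow = 0.01) {
  K <- matrix(0, 9, 9)
  for (i in 1:8) {
    r <- if (i %in% c(3, 6)) slow else fast
    K[i, i + 1] <- r
    K[i + 1, i] <- r * ifelse(i %% 2 == 0, 1.3, 0.8)
  }
  diag(K) <- -rowSums(K)
  K
}

# dense matrix exponential by eigendecomposition (oracle)
expm_eigen <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# enumeration oracle: Zimm-Bragg statistics of all 2^n configurations
zb_enumerate <- function(n, s, sigma) {
  cfg <- t(sapply(0:(2^n - 1),
                  function(a) as.integer(bitwAnd(a, 2^(0:(n - 1))) > 0)))
  w <- apply(cfg, 1, function(x)
    s^sum(x) * sigma^sum(diff(c(0, x)) == 1))
  list(cfg = cfg, w = w, Z = sum(w),
       profile = colSums(cfg * w) / sum(w),
       mean_helicity = sum(rowSums(cfg) * w) / (n * sum(w)))
}

# exact single-flip Metropolis master-equation generator of the
# Zimm-Bragg chain over all 2^n configurations (oracle for pipeline
# parameter recovery)
zb_master_K <- function(n, s, sigma, nu = 1) {
  en <- zb_enumerate(n, s, sigma)
  N <- 2^n
  K <- matrix(0, N, N)
  for (a in seq_len(N)) for (i in seq_len(n)) {
    y <- en$cfg[a, ]
    y[i] <- 1L - y[i]
    b <- sum(y * 2^(0:(n - 1))) + 1L
    wb <- s^sum(y) * sigma^sum(diff(c(0, y)) == 1)
    K[a, b] <- nu * min(1, wb / en$w[a])
  }
  diag(K) <- -rowSums(K)
  list(K = K, pi = en$w / en$Z, cfg = en$cfg)
}

# first-passage Monte Carlo committor oracle: probability of hitting
# `sink` before `source_set` from `from`, by naive jump simulation
mc_committor <- function(K, from, sink, source_set, nruns, seed) {
  set.seed(seed)
  n <- nrow(K)
  exit <- -diag(K)
  cum <- lapply(seq_len(n), function(i) {
    p <- K[i, ]; p[i] <- 0
    cumsum(p / exit[i])
  })
  hits <- 0L
  for (r in seq_len(nruns)) {
    s <- from
    repeat {
      s <- findInterval(stats::runif(1L), cum[[s]]) + 1L
      if (s %in% sink) { hits <- hits + 1L; break }
      if (s %in% source_set) break
    }
  }
  hits / nruns
}
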