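# Kinetic coarse-graining: PCCA+ metastable lumping of the microstate
# rate matrix, optimal reduced rate matrices fitted by propagator
# matching, aggregate-set classification and diagnostics.

# pi-weighted eigen-decomposition of a reversible generator:
# K = D^{-1/2} V L V' D^{1/2} with D = diag(pi), V orthonormal
reversible_eigen <- function(K, pi) {
  d <- sqrt(pi)
  S <- (K * (d %o% (1 / d)) + t(K) * ((1 / d) %o% d)) / 2  # symmetrize
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, V = e$vectors, d = d)
}

# propagator exp(K t) from a reversible_eigen decomposition
propagator <- function(re, t) {
  (re$V %*% (exp(re$values * t) * t(re$V))) * ((1 / re$d) %o% re$d)
}

#' PCCA+ metastable memberships
#'
#' Lumps the microstates of a reversible rate-matrix model into `N`
#' metastable aggregates using the simplex structure of the dominant
#' right eigenvectors (inner-simplex vertex selection by the standard
#' farthest-point rule, lowest index on ties; eigenvectors sorted by
#' eigenvalue with the sign of the first element fixed positive, so the
#' result is deterministic). Membership rows are clipped to `[0, 1]`
#' and renormalized to sum to 1.
#'
#' @param model a [rate_matrix_model()] (reversible).
#' @param N number of aggregates, `2 <= N <=` number of states.
#' @return an object of class `"pcca_membership"`: matrix `chi`
#'   (states x N), crisp `assignment` (argmax per row), and the spectral
#'   gap diagnostics.
#' @export
pcca_plus <- function(model, N) {
  K <- model$K
  nc <- nrow(K)
  if (N < 2L || N > nc) stop("need 2 <= N <= number of states")
  re <- reversible_eigen(K, model$pi)
  ord <- order(re$values, decreasing = TRUE)
  X <- (1 / re$d) * re$V[, ord[seq_len(N)], drop = FALSE]
  for (j in seq_len(N)) if (X[1L, j] < 0) X[, j] <- -X[, j]
  X[, 1L] <- 1  # stationary eigenvector is constant; remove round-off
  ev <- re$values[ord]
  if (N < nc && abs(ev[N] - ev[N + 1L]) < 1e-12)
    warning("no spectral gap after the first N eigenvalues; proceeding")

  # inner-simplex vertex search (farthest-point)
  vertices <- integer(N)
  Y <- X
  vertices[1L] <- which.max(rowSums(Y^2))
  Y <- sweep(Y, 2L, X[vertices[1L], ])
  for (j in seq_len(N)[-1L]) {
    vertices[j] <- which.max(rowSums(Y^2))
    v <- Y[vertices[j], ]
    v <- v / sqrt(sum(v^2))
    Y <- Y - (Y %*% v) %*% t(v)
  }
  chi <- X %*% solve(X[vertices, , drop = FALSE])
  chi[chi < 0] <- 0
  chi[chi > 1] <- 1
  chi <- chi / rowSums(chi)
  structure(list(chi = chi, assignment = max.col(chi, "first"),
                 vertices = vertices, eigenvalues = ev),
            class = "pcca_membership")
}

#' @export
print.pcca_membership <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = seq_len(ncol(x$chi))))
  cat(sprintf("PCCA+ membership: %d microstates -> %d aggregates (sizes %s)\n",
              nrow(x$chi), ncol(x$chi), paste(tab, collapse = ", ")))
  invisible(x)
}

# crisp assignment vector from a membership or assignment input
crisp_assignment <- function(membership, nstates) {
  if (inherits(membership, "pcca_membership")) return(membership$assignment)
  a <- as.integer(membership)
  if (length(a) != nstates) stop("membership length mismatch")
  a
}

#' Optimal reduced rate matrix (ODR fit)
#'
#' Fits an `N x N` reduced rate matrix `R` whose propagators `exp(R t)`
#' best match the population-weighted aggregation of the full-model
#' propagators `exp(K t)` over a set of lag times, under generator and
#' detailed-balance constraints with the aggregate populations pinned
#' to the lumped stationary distribution. Optimization is over the
#' logarithms of the symmetric exchange fluxes (positivity for free),
#' starting from the naive lumped rates
#' `R0_IJ = sum(pi_i K_ij; i in I, j in J) / Pi_I`.
#'
#' @param model a [rate_matrix_model()].
#' @param membership a [pcca_plus()] membership (crisp assignment used)
#'   or an integer assignment vector.
#' @param lags lag times (ns) for propagator matching; default
#'   `c(1, 2, 5, 10, 20, 50)` times the shortest mean residence time of
#'   the full model.
#' @return an object of class `"reduced_model"`: `R` (1/ns),
#'   `populations`, `timescales` (ns), `lifetimes` (`-1/R_ii`, ns),
#'   `assignment`, `lags`, `objective`, and a `fidelity` data.frame
#'   comparing reduced and full relaxation times (deviations beyond 50%
#'   are flagged).
#' @export
odr_fit <- function(model, membership, lags = NULL) {
  K <- model$K
  pi <- model$pi
  nc <- nrow(K)
  assign <- crisp_assignment(membership, nc)
  N <- max(assign)
  if (any(tabulate(assign, N) == 0L)) stop("empty aggregate in membership")
  if (is.null(lags)) {
    tau0 <- 1 / max(abs(diag(K)))
    lags <- c(1, 2, 5, 10, 20, 50) * tau0
  }
  Pi <- as.vector(tapply(pi, assign, sum))
  A <- matrix(0, N, nc)   # population-weighted aggregation
  B <- matrix(0, nc, N)   # membership indicator
  for (i in seq_len(nc)) {
    A[assign[i], i] <- pi[i] / Pi[assign[i]]
    B[i, assign[i]] <- 1
  }
  re <- reversible_eigen(K, pi)
  Pagg <- lapply(lags, function(t) A %*% propagator(re, t) %*% B)

  ut <- which(upper.tri(matrix(0, N, N)))
  flux_to_R <- function(f) {
    Fm <- matrix(0, N, N)
    Fm[ut] <- f
    Fm <- Fm + t(Fm)
    R <- Fm / Pi
    diag(R) <- -rowSums(R)
    R
  }
  red_eigen <- function(R) reversible_eigen(R, Pi)
  objective <- function(x) {
    R <- flux_to_R(exp(x))
    rr <- red_eigen(R)
    s <- 0
    for (k in seq_along(lags)) {
      PR <- propagator(rr, lags[k])
      s <- s + sum(Pi * (Pagg[[k]] - PR)^2)
    }
    s
  }
  # naive lumped initialization (symmetrized flux)
  F0 <- matrix(0, N, N)
  for (I in seq_len(N)) for (J in seq_len(N)) if (I != J)
    F0[I, J] <- sum(pi[assign == I] *
                      rowSums(K[assign == I, assign == J, drop = FALSE]))
  F0 <- (F0 + t(F0)) / 2
  f0 <- pmax(F0[ut], max(F0) * 1e-10 + 1e-300)
  opt <- stats::optim(log(f0), objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0 && opt$value > objective(log(f0)))
    stop(sprintf("ODR optimizer did not converge (code %d, obj %.3g)",
                 opt$convergence, opt$value))
  R <- flux_to_R(exp(opt$par))
  rts <- rate_matrix_model(R, pi = Pi)$timescales
  kts <- model$timescales
  nshow <- min(length(rts), length(kts), 2L)
  fid <- data.frame(mode = seq_len(nshow),
                    reduced = rts[seq_len(nshow)],
                    full = kts[seq_len(nshow)])
  fid$rel_dev <- abs(fid$reduced - fid$full) / fid$full
  if (any(fid$rel_dev > 0.5))
    warning("reduced relaxation times deviate by more than 50% from the full model")
  structure(list(R = R, populations = Pi, timescales = rts,
                 lifetimes = -1 / diag(R), assignment = assign,
                 lags = lags, objective = opt$value, fidelity = fid),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  N <- nrow(x$R)
  cat(sprintf("Reduced kinetic model: N = %d aggregate states\n", N))
  cat("  populations:", paste(signif(x$populations, 3), collapse = ", "), "\n")
  cat("  lifetimes (ns):", paste(signif(x$lifetimes, 3), collapse = ", "), "\n")
  if (length(x$timescales))
    cat("  relaxation times (ns):",
        paste(signif(x$timescales, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Representative structure of an aggregate set
#'
#' The center conformation of the member cluster to which the most
#' frames are assigned (ties to the lowest cluster index).
#'
#' @param members integer vector of member cluster indices.
#' @param clustering an [cluster_leader()] result.
#' @param traj the clustered [trajectory()].
#' @return a `"conformation"`.
#' @export
representative_structure <- function(members, clustering, traj) {
  if (!length(members)) stop("empty aggregate set")
  sizes <- tabulate(clustering$assignment, clustering$n_clusters)[members]
  best <- members[which.max(sizes)]
  traj$frames[[clustering$centers[best]]]
}

#' Classify aggregate sets as helix, coil and intermediates
#'
#' The helix set is the one whose representative structure lies closest
#' (CA RMSD) to the ideal helix, with the larger formed-hydrogen-bond
#' count breaking ties; the coil set is the one containing the largest
#' number of member clusters among the remaining sets (lowest index on
#' ties); anything left is an intermediate.
#'
#' @param membership a [pcca_plus()] membership or assignment vector
#'   over the clusters.
#' @param clustering an [cluster_leader()] result.
#' @param traj the clustered [trajectory()].
#' @param reference_helix optional ideal-helix `"conformation"`.
#' @param reduced optional [odr_fit()] model supplying populations and
#'   lifetimes.
#' @param T temperature (K) for per-set free energies.
#' @return an object of class `"aggregate_sets"`: data.frame `sets`
#'   (label, n_clusters, population, lifetime, delta_g, rmsd_from_helix,
#'   n_hbonds) plus member lists and representative conformations.
#' @export
classify_sets <- function(membership, clustering, traj,
                          reference_helix = NULL, reduced = NULL,
                          T = 300) {
  assign <- crisp_assignment(membership, clustering$n_clusters)
  N <- max(assign)
  if (N < 2L) stop("need >= 2 aggregate sets to classify")
  spec <- traj$spec
  if (is.null(reference_helix))
    reference_helix <- build_conformation(spec, ideal_dihedrals(spec, "helix"))
  members <- lapply(seq_len(N), function(I) which(assign == I))
  reps <- lapply(members, representative_structure, clustering, traj)
  rmsd <- vapply(reps, ca_rmsd, numeric(1L), reference_helix)
  nhb <- vapply(reps, count_helical_hbonds, numeric(1L))
  ncl <- lengths(members)
  helix <- which(rmsd == min(rmsd))
  if (length(helix) > 1L) helix <- helix[which.max(nhb[helix])]
  rest <- setdiff(seq_len(N), helix)
  coil <- rest[which.max(ncl[rest])]
  label <- rep("intermediate", N)
  label[helix] <- "helix"
  label[coil] <- "coil"
  # frame-count populations unless a reduced model provides them
  pop <- if (!is.null(reduced)) reduced$populations else {
    fr <- tabulate(assign[clustering$assignment], N)
    fr / sum(fr)
  }
  lifetime <- if (!is.null(reduced)) reduced$lifetimes else rep(NA_real_, N)
  dg <- -R_GAS * T * log(pop / max(pop))
  structure(list(
    sets = data.frame(set = seq_len(N), label = label, n_clusters = ncl,
                      population = pop, lifetime = lifetime, delta_g = dg,
                      rmsd_from_helix = rmsd, n_hbonds = nhb),
    members = members, representatives = reps),
    class = "aggregate_sets")
}

#' @export
print.aggregate_sets <- function(x, ...) {
  cat("Aggregate sets:\n")
  print(x$sets, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Within- and between-set structural inhomogeneity
#'
#' Mean pairwise CA RMSD of the member cluster centers within each
#' aggregate set, and between every pair of sets. Singleton sets report
#' a within-set value of 0 and are flagged.
#'
#' @param sets an [classify_sets()] result (or list of member vectors).
#' @param clustering an [cluster_leader()] result.
#' @param traj the clustered [trajectory()].
#' @return list with `within` (vector, flagged via the `singleton`
#'   attribute) and `between` (matrix), in Angstrom.
#' @export
set_inhomogeneity <- function(sets, clustering, traj) {
  members <- if (inherits(sets, "aggregate_sets")) sets$members else sets
  centers_ca <- lapply(clustering$centers,
                       function(i) ca_coords(traj$frames[[i]]))
  N <- length(members)
  pair_mean <- function(ma, mb, same) {
    if (same) {
      if (length(ma) < 2L) return(0)
      pairs <- utils::combn(ma, 2L)
      mean(vapply(seq_len(ncol(pairs)), function(k)
        kabsch_rmsd(centers_ca[[pairs[1L, k]]], centers_ca[[pairs[2L, k]]]),
        numeric(1L)))
    } else {
      mean(vapply(ma, function(a) vapply(mb, function(b)
        kabsch_rmsd(centers_ca[[a]], centers_ca[[b]]), numeric(1L)),
        numeric(length(mb))))
    }
  }
  within <- vapply(members, function(m) pair_mean(m, m, TRUE), numeric(1L))
  attr(within, "singleton") <- lengths(members) < 2L
  between <- matrix(NA_real_, N, N)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    between[a, b] <- if (a == b) within[a]
    else pair_mean(members[[a]], members[[b]], FALSE)
  }
  list(within = within, between = between)
}

#' Per-set free energies of a reduced model
#'
#' `dG_I = -R T ln(Pi_I / Pi_max)`, relative to the most stable set.
#'
#' @param model a [odr_fit()] reduced model (or a population vector).
#' @param T temperature in kelvin.
#' @return numeric vector of free energies in kcal/mol (0 for the most
#'   stable set).
#' @export
model_free_energies <- function(model, T = 300) {
  p <- if (inherits(model, "reduced_model")) model$populations else model
  if (any(p <= 0)) stop("populations must be positive")
  -R_GAS * T * log(p / max(p))
}
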