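# Microstate kinetic models: CA-RMSD leader clustering, core-based
# trajectory discretization, transition counting, generator estimation,
# implied timescales and core-radius calibration.

# list of per-frame CA coordinate matrices
traj_ca <- function(traj) lapply(traj$frames, ca_coords)

#' Leader clustering of a trajectory under CA RMSD
#'
#' Deterministic single-pass leader (threshold) clustering in frame
#' order: a frame farther than `radius` from every existing cluster
#' center becomes a new center; afterwards every frame is assigned to
#' its nearest center (ties to the lowest-index center). Cluster
#' centers are actual trajectory frames, so they double as microstate
#' representative conformations.
#'
#' @param traj a [trajectory()].
#' @param radius cluster radius in Angstrom (> 0).
#' @return an object of class `"msm_clustering"`: `centers` (frame
#'   indices), `radius`, `assignment` (per frame), `n_clusters`, and
#'   the trajectory's CA coordinates cached for reuse.
#' @export
cluster_leader <- function(traj, radius) {
  if (radius <= 0) stop("radius must be positive")
  ca <- lapply(traj_ca(traj), center_coords)
  nf <- length(ca)
  if (nf == 0L) stop("empty trajectory")
  centers <- 1L
  # growing frame x center distance cache, reused for assignment and
  # for core discretization at any radius
  dist <- matrix(NA_real_, nf, 16L)
  dist[1L, 1L] <- 0
  for (i in seq_len(nf)[-1L]) {
    d <- vapply(centers, function(c) kabsch_core(ca[[i]], ca[[c]]),
                numeric(1L))
    dist[i, seq_along(centers)] <- d
    if (all(d > radius)) {
      centers <- c(centers, i)
      if (length(centers) > ncol(dist))
        dist <- cbind(dist, matrix(NA_real_, nf, ncol(dist)))
      dist[i, length(centers)] <- 0
    }
  }
  dist <- dist[, seq_along(centers), drop = FALSE]
  # fill distances to centers discovered after each frame was first seen
  for (j in seq_along(centers)) {
    todo <- which(is.na(dist[, j]))
    for (i in todo) dist[i, j] <- kabsch_core(ca[[i]], ca[[centers[j]]])
  }
  assignment <- max.col(-dist, "first")  # nearest center, lowest index on ties
  structure(list(centers = centers, radius = radius,
                 assignment = assignment,
                 n_clusters = length(centers),
                 dist = dist, ca = ca, dt = traj$dt),
            class = "msm_clustering")
}

#' @export
print.msm_clustering <- function(x, ...) {
  cat(sprintf("Leader clustering: N_c = %d clusters at radius %.2f A over %d frames\n",
              x$n_clusters, x$radius, length(x$assignment)))
  invisible(x)
}

#' Core-based trajectory discretization
#'
#' A frame is given the label of a microstate core when it lies within
#' the core radius `R_c` of that cluster center; frames in transit
#' (outside every core) inherit the label of the last visited core, and
#' frames before the first core entry are back-filled from the first
#' core entered. This transition-based assignment suppresses
#' recrossing noise at the core boundaries.
#'
#' @param traj a [trajectory()] (the one that was clustered).
#' @param clustering an [cluster_leader()] result.
#' @param R_c core radius in Angstrom, `0 < R_c <= clustering$radius`.
#' @return an object of class `"core_assignment"` with per-frame core
#'   labels, `R_c` and the per-frame in-core indicator.
#' @export
assign_cores <- function(traj, clustering, R_c) {
  if (R_c <= 0 || R_c > clustering$radius)
    stop("R_c must satisfy 0 < R_c <= clustering radius")
  dist <- clustering$dist
  nf <- nrow(dist)
  j <- clustering$assignment
  dmin <- dist[cbind(seq_len(nf), j)]
  in_core <- dmin <= R_c
  raw <- ifelse(in_core, j, NA_integer_)
  if (!any(in_core)) stop("no frame lies within any core")
  labels <- raw
  first <- which(in_core)[1L]
  if (first > 1L) labels[seq_len(first - 1L)] <- raw[first]
  for (i in seq_len(nf)) {
    if (i > first && is.na(labels[i])) labels[i] <- labels[i - 1L]
  }
  structure(list(labels = labels, R_c = R_c, in_core = in_core,
                 n_states = clustering$n_clusters, dt = clustering$dt),
            class = "core_assignment")
}

#' @export
print.core_assignment <- function(x, ...) {
  cat(sprintf("Core assignment: R_c = %.2f A, %d/%d frames in core, %d states visited\n",
              x$R_c, sum(x$in_core), length(x$labels),
              length(unique(x$labels))))
  invisible(x)
}

# largest strongly connected set of states under symmetrized counts
connected_states <- function(C) {
  A <- (C + t(C)) > 0
  diag(A) <- TRUE
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- vapply(seq_len(cur), function(k) {
    idx <- which(comp == k)
    sum(C[idx, idx, drop = FALSE])   # weight by observed counts
  }, numeric(1L))
  which(comp == which.max(sizes))
}

#' Count core transitions and estimate a transition matrix
#'
#' Sliding-window transition counts of the core label sequence at the
#' given lag, with reversible (symmetrized counts) maximum-likelihood
#' row normalization by default. The transition matrix is restricted to
#' the largest connected set of visited states.
#'
#' @param cores an [assign_cores()] result (or a bare integer label
#'   sequence, in which case `dt` must be given).
#' @param lag lag time in ns; must be a positive multiple of the
#'   sampling interval and below the trajectory duration.
#' @param reversible symmetrize counts as `(C + t(C))/2` before
#'   normalizing (detailed balance at equilibrium).
#' @param dt sampling interval for bare label input.
#' @return an object of class `"transition_model"` with `counts`, `T`
#'   (row-stochastic), `lag` (ns), `states` (original state ids kept).
#' @export
count_transitions <- function(cores, lag = NULL, reversible = TRUE,
                              dt = NULL) {
  if (inherits(cores, "core_assignment")) {
    labels <- cores$labels; dt <- cores$dt
  } else {
    labels <- as.integer(cores)
    if (is.null(dt)) stop("dt required for bare label input")
  }
  if (is.null(lag)) lag <- dt
  steps <- lag / dt
  if (abs(steps - round(steps)) > 1e-8 || steps < 1)
    stop("lag must be a positive multiple of the sampling interval")
  steps <- as.integer(round(steps))
  nf <- length(labels)
  if (steps >= nf) stop("lag must be below the trajectory duration")
  states <- sort(unique(labels))
  idx <- match(labels, states)
  ns <- length(states)
  from <- idx[seq_len(nf - steps)]
  to <- idx[seq_len(nf - steps) + steps]
  C <- matrix(as.numeric(tabulate((to - 1L) * ns + from, ns * ns)),
              ns, ns)
  keep <- connected_states(C)
  C <- C[keep, keep, drop = FALSE]
  states <- states[keep]
  Csym <- if (reversible) (C + t(C)) / 2 else C
  Tm <- Csym / rowSums(Csym)
  structure(list(counts = C, T = Tm, lag = lag, states = states,
                 reversible = reversible),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Transition model: %d states, lag = %g ns, %d counted transitions\n",
              nrow(x$T), x$lag, sum(x$counts)))
  invisible(x)
}

# stationary distribution of a row-stochastic matrix (leading left
# eigenvector); for reversible T this is real and positive
stationary_of_T <- function(Tm) {
  e <- eigen(t(Tm))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Estimate the microstate rate matrix
#'
#' Generator approximation `K = (T - I) / lag` on the connected state
#' set, with the stationary distribution taken from the leading left
#' eigenvector of `T`. The linearization avoids the branch and
#' negative-rate pathologies of the matrix logarithm at short lags.
#'
#' @param tm a [count_transitions()] model (rows of `T` summing to 1).
#' @return an object of class `"rate_matrix_model"` with `K` (1/ns),
#'   `pi`, `eigenvalues`, `timescales` (sorted descending, ns) and
#'   `states`.
#' @export
estimate_rate_matrix <- function(tm) {
  Tm <- tm$T
  if (max(abs(rowSums(Tm) - 1)) > 1e-8)
    stop("rows of T must sum to 1")
  K <- (Tm - diag(nrow(Tm))) / tm$lag
  rate_matrix_model(K, pi = stationary_of_T(Tm), states = tm$states)
}

#' Construct a rate-matrix model
#'
#' Wraps a generator matrix (off-diagonals >= 0, rows summing to zero)
#' with its stationary distribution and implied timescales.
#'
#' @param K square generator matrix in 1/ns.
#' @param pi optional stationary distribution; computed from the
#'   eigendecomposition when omitted.
#' @param states optional state labels.
#' @return an object of class `"rate_matrix_model"`.
#' @export
rate_matrix_model <- function(K, pi = NULL, states = NULL) {
  K <- as.matrix(K)
  if (any(K[row(K) != col(K)] < -1e-12))
    stop("off-diagonal rates must be nonnegative")
  if (max(abs(rowSums(K))) > 1e-8)
    stop("rows of a generator must sum to zero")
  e <- eigen(K)
  if (max(abs(Im(e$values))) > 1e-8 * max(1, max(abs(Re(e$values)))))
    stop("complex eigenvalues beyond tolerance: input is not reversible")
  ev <- sort(Re(e$values), decreasing = TRUE)
  if (is.null(pi)) {
    el <- eigen(t(K))
    i <- which.min(abs(el$values))
    v <- abs(Re(el$vectors[, i]))
    pi <- v / sum(v)
  }
  nz <- ev[-1L]
  ts <- sort(-1 / nz[nz < -1e-14], decreasing = TRUE)
  structure(list(K = K, pi = pi, eigenvalues = ev, timescales = ts,
                 states = if (is.null(states)) seq_len(nrow(K)) else states),
            class = "rate_matrix_model")
}

#' @export
print.rate_matrix_model <- function(x, ...) {
  cat(sprintf("Rate matrix model: %d states\n", nrow(x$K)))
  if (length(x$timescales))
    cat("  implied timescales (ns):",
        paste(signif(utils::head(x$timescales, 5L), 4), collapse = ", "),
        "\n")
  invisible(x)
}

#' Implied relaxation timescales
#'
#' For a rate matrix, `-1/lambda` over the nonzero eigenvalues; for a
#' transition matrix at lag tau, `-tau / log(lambda)` over eigenvalues
#' in (0, 1). Sorted descending; the stationary eigenvalue is excluded.
#'
#' @param model a `"rate_matrix_model"` or `"transition_model"`.
#' @return numeric vector of timescales in ns.
#' @export
implied_timescales <- function(model) {
  if (inherits(model, "rate_matrix_model")) return(model$timescales)
  if (inherits(model, "transition_model")) {
    ev <- eigen(model$T, only.values = TRUE)$values
    if (max(abs(Im(ev))) > 1e-8)
      stop("complex eigenvalues beyond tolerance: input is not reversible")
    ev <- sort(Re(ev), decreasing = TRUE)[-1L]
    ev <- ev[ev > 0 & ev < 1]
    return(sort(-model$lag / log(ev), decreasing = TRUE))
  }
  stop("model must be a rate_matrix_model or transition_model")
}

#' Calibrate the core radius against a target relaxation time
#'
#' Builds a core discretization and microstate rate model for each
#' candidate core radius and returns the one whose slowest implied
#' timescale is closest to the target (e.g. the relaxation time
#' measured directly from the trajectory ACF). Achieved timescales are
#' expected to grow with `R_c` (larger cores allow more recrossing); a
#' violation triggers a warning, not an error.
#'
#' @param traj a [trajectory()].
#' @param clustering an [cluster_leader()] result.
#' @param target_tau2 target slowest relaxation time in ns.
#' @param grid candidate core radii in Angstrom, within
#'   `(0, clustering$radius]`.
#' @param lag lag time for transition counting (default: sampling
#'   interval).
#' @return the selected [assign_cores()] result, with attributes
#'   `achieved_tau2`, `mismatch` (relative), `grid_tau2` and `R_c`.
#' @export
calibrate_core_radius <- function(traj, clustering, target_tau2, grid,
                                  lag = NULL) {
  if (!length(grid) || any(grid <= 0) || any(grid > clustering$radius))
    stop("grid must be a nonempty set of radii within (0, radius]")
  grid <- sort(grid)
  achieved <- rep(NA_real_, length(grid))
  assigns <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    res <- tryCatch({
      asg <- assign_cores(traj, clustering, grid[g])
      tm <- count_transitions(asg, lag = lag)
      km <- estimate_rate_matrix(tm)
      list(asg = asg, tau = if (length(km$timescales))
        km$timescales[1L] else NA_real_)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      assigns[[g]] <- res$asg
      achieved[g] <- res$tau
    }
  }
  if (all(is.na(achieved)))
    stop("no candidate core radius produced a connected kinetic model")
  ok <- which(is.finite(achieved))
  if (any(diff(achieved[ok]) < 0))
    warning("achieved timescale is not non-decreasing in R_c")
  best <- ok[which.min(abs(achieved[ok] - target_tau2))]
  out <- assigns[[best]]
  attr(out, "achieved_tau2") <- achieved[best]
  attr(out, "mismatch") <- abs(achieved[best] - target_tau2) / target_tau2
  attr(out, "grid_tau2") <- stats::setNames(achieved, grid)
  out
}
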