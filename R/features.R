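# Per-frame feature extraction and time-series analysis: global helicity
# features, autocorrelation functions, biexponential relaxation fits and
# hydrogen-bond statistics (per-bond populations, P(HBi, NHB) heat maps,
# neighbor-bond correlations).

#' Per-frame feature series
#'
#' @param name feature name.
#' @param values numeric vector, one value per frame (finite, length >= 2).
#' @param dt sampling interval in ns.
#' @return an object of class `"feature_series"`.
#' @export
feature_series <- function(name, values, dt) {
  if (length(values) < 2L || !all(is.finite(values)))
    stop("feature series must hold >= 2 finite values")
  if (dt <= 0) stop("dt must be positive")
  structure(list(name = name, values = as.numeric(values), dt = dt),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("Feature '%s': %d frames, dt = %g ns, mean = %.4g\n",
              x$name, length(x$values), x$dt, mean(x$values)))
  invisible(x)
}

# internal constructor for the frames x bonds O...N length matrix
new_hbond_matrix <- function(lengths, dt) {
  colnames(lengths) <- paste0("bond_", seq_len(ncol(lengths)))
  structure(list(lengths = lengths, formed = lengths < .HB_CUTOFF,
                 dt = dt),
            class = "hbond_matrix")
}

#' @export
print.hbond_matrix <- function(x, ...) {
  cat(sprintf("H-bond matrix: %d frames x %d bonds, dt = %g ns\n",
              nrow(x$lengths), ncol(x$lengths), x$dt))
  cat(sprintf("  mean bonds formed per frame: %.3f\n",
              mean(rowSums(x$formed))))
  invisible(x)
}

#' Featurize a trajectory
#'
#' Computes the per-frame global helicity features used for relaxation
#' analysis — CA RMSD from the ideal helix, radius of gyration, number
#' of formed helical hydrogen bonds and the helical-residue (dihedral)
#' count — together with the per-bond O...N length matrix.
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param reference_helix reference `"conformation"`; defaults to the
#'   ideal helix built for the trajectory's peptide spec.
#' @return a list with class `"feature_set"`: elements `features` (named
#'   list of [feature_series()]: `rmsd_from_helix`, `radius_of_gyration`,
#'   `n_hbonds`, `pp_count`) and `hbonds` (an `"hbond_matrix"`).
#' @export
featurize <- function(traj, reference_helix = NULL) {
  if (length(traj$frames) < 2L)
    stop("dynamics operations need >= 2 frames")
  spec <- traj$spec
  if (is.null(reference_helix))
    reference_helix <- build_conformation(spec, ideal_dihedrals(spec, "helix"))
  if (reference_helix$spec$n_residues != spec$n_residues)
    stop("reference helix does not match the trajectory's peptide spec")
  ref_ca <- ca_coords(reference_helix)
  nf <- length(traj$frames)
  nb <- spec$n_residues - 2L
  rmsd <- rg <- nhb <- ppc <- numeric(nf)
  hb <- matrix(NA_real_, nf, nb)
  for (i in seq_len(nf)) {
    f <- traj$frames[[i]]
    rmsd[i] <- kabsch_rmsd(ca_coords(f), ref_ca)
    rg[i] <- radius_of_gyration(f)
    hl <- hbond_lengths(f)
    hb[i, ] <- hl
    nhb[i] <- sum(hl < .HB_CUTOFF)
    ppc[i] <- helical_residue_count(backbone_dihedrals(f))
  }
  structure(list(
    features = list(
      rmsd_from_helix = feature_series("rmsd_from_helix", rmsd, traj$dt),
      radius_of_gyration = feature_series("radius_of_gyration", rg, traj$dt),
      n_hbonds = feature_series("n_hbonds", nhb, traj$dt),
      pp_count = feature_series("pp_count", ppc, traj$dt)),
    hbonds = new_hbond_matrix(hb, traj$dt)),
    class = "feature_set")
}

#' Normalized autocorrelation function
#'
#' Mean-subtracted, variance-normalized ACF of a feature series, using
#' the biased estimator (sum divided by the total frame count), so that
#' ACF(0) = 1 and large-lag noise is damped.
#'
#' @param series a [feature_series()] (or bare numeric vector with `dt`).
#' @param max_lag largest lag in ns (must be below the series duration).
#' @param dt sampling interval when `series` is a bare vector.
#' @return an object of class `"acf_curve"` with `lag` (ns) and `value`.
#' @export
autocorrelation <- function(series, max_lag, dt = NULL) {
  if (inherits(series, "feature_series")) {
    x <- series$values; dt <- series$dt
  } else {
    x <- as.numeric(series)
    if (is.null(dt)) stop("dt required for a bare numeric series")
  }
  if (stats::var(x) == 0)
    stop("degenerate signal: series has zero variance")
  nlag <- floor(max_lag / dt)
  if (nlag < 1L || nlag >= length(x))
    stop("max_lag must cover >= 1 lag and be below the series duration")
  a <- stats::acf(x, lag.max = nlag, plot = FALSE, demean = TRUE,
                  type = "correlation")
  structure(list(lag = dt * (0:nlag), value = as.numeric(a$acf)),
            class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("ACF: %d lags up to %g ns\n", length(x$lag) - 1L,
              max(x$lag)))
  invisible(x)
}

#' @export
plot.acf_curve <- function(x, ...) {
  graphics::plot(x$lag, x$value, type = "l", xlab = "lag (ns)",
                 ylab = "ACF", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Fit a two-exponential decay to an ACF
#'
#' Nonlinear least squares of `a1 exp(-t/tau_fast) + a2 exp(-t/tau_slow)`
#' over a deterministic multi-start grid of timescale pairs spanning the
#' lag range in decades. The fit window runs up to the first crossing of
#' 0.02 (or the last lag, whichever comes first); timescales are bounded
#' by ten times the window (longer components are not identifiable from
#' the data). Ties between starts are broken by the lowest residual
#' norm, then the smallest `tau_slow`. `tau_slow` — the global
#' relaxation time — is the slowest component carrying at least
#' `min_amplitude` of the normalized decay, so that a near-zero
#' amplitude tail cannot masquerade as the global time.
#'
#' @param acf an [autocorrelation()] curve (>= 6 lag points in window).
#' @param floor_value fit-window cutoff on the ACF value (default 0.02).
#' @param min_amplitude smallest amplitude considered a real component.
#' @return an object of class `"biexp_fit"` with fields `a1`, `a2`,
#'   `tau_fast`, `tau_slow`, `resid_norm`.
#' @export
fit_biexponential <- function(acf, floor_value = 0.02,
                              min_amplitude = 0.05) {
  t <- acf$lag; y <- acf$value
  below <- which(y < floor_value)
  end <- if (length(below)) max(below[1L], 6L) else length(t)
  end <- min(end, length(t))
  t <- t[seq_len(end)]; y <- y[seq_len(end)]
  if (length(t) < 6L) stop("need >= 6 lag points in the fit window")
  tmin <- max(t[2L], 1e-6); tmax <- max(t)
  taus <- 10^seq(log10(tmin / 2), log10(tmax * 2), length.out = 6L)
  starts <- expand.grid(tf = taus, ts = taus)
  starts <- starts[starts$tf <= starts$ts, ]
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-t / tf) + a2 * exp(-t / ts),
        start = list(a1 = 0.5, a2 = 0.5,
                     tf = starts$tf[r], ts = starts$ts[r]),
        lower = c(0, 0, 1e-9, 1e-9),
        upper = c(2, 2, 10 * tmax, 10 * tmax),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    cf <- stats::coef(fit)
    amp <- c(cf[["a1"]], cf[["a2"]])
    tau <- c(cf[["tf"]], cf[["ts"]])
    ord <- order(tau)   # sort so that a1/tau_fast is the faster pair
    amp <- amp[ord]; tau <- tau[ord]
    # the reported global time ignores negligible-amplitude tails
    real <- which(amp >= min_amplitude)
    ts_rep <- if (length(real)) max(tau[real]) else tau[2L]
    if (is.null(best) || rn < best$resid_norm - 1e-12 ||
        (abs(rn - best$resid_norm) <= 1e-12 && ts_rep < best$tau_slow)) {
      best <- list(a1 = amp[1L], a2 = amp[2L],
                   tau_fast = min(tau[1L], ts_rep), tau_slow = ts_rep,
                   resid_norm = rn)
    }
  }
  if (is.null(best))
    stop("biexponential fit failed to converge from any grid start")
  structure(best, class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "Biexponential fit: %.3f exp(-t/%.4g ns) + %.3f exp(-t/%.4g ns)\n",
    x$a1, x$tau_fast, x$a2, x$tau_slow))
  cat(sprintf("  global relaxation time tau_slow = %.4g ns (resid %.3g)\n",
              x$tau_slow, x$resid_norm))
  invisible(x)
}

# moving-block bootstrap of a per-frame statistic matrix: returns 2.5/97.5
# percentiles of the column means across resamples
block_bootstrap_ci <- function(mat, block, n_boot = 200L, seed = 1L) {
  nf <- nrow(mat)
  block <- max(1L, min(block, nf))
  nblocks <- ceiling(nf / block)
  starts_max <- nf - block + 1L
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  means <- matrix(NA_real_, n_boot, ncol(mat))
  for (b in seq_len(n_boot)) {
    st <- sample.int(starts_max, nblocks, replace = TRUE)
    idx <- as.vector(outer(0:(block - 1L), st, `+`))[seq_len(nf)]
    means[b, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  apply(means, 2L, stats::quantile, probs = c(0.025, 0.975))
}

#' Per-bond hydrogen-bond populations
#'
#' Mean of the formed indicator for each helical bond position, with
#' moving-block bootstrap 95% confidence intervals (block length of ten
#' times the estimated relaxation time of the total bond count, 200
#' resamples, fixed seed).
#'
#' @param hb an `"hbond_matrix"`.
#' @param block block length in frames; by default estimated from the
#'   integrated ACF of the total-bond-count series.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return a data.frame with columns `bond`, `population`, `lo`, `hi`.
#' @export
hbond_population_profile <- function(hb, block = NULL, n_boot = 200L,
                                     seed = 1L) {
  formed <- hb$formed * 1
  pop <- colMeans(formed)
  if (is.null(block)) {
    nhb <- rowSums(formed)
    block <- if (stats::var(nhb) > 0) {
      a <- stats::acf(nhb, lag.max = min(nrow(formed) - 1L, 1000L),
                      plot = FALSE)
      # integrated autocorrelation time in frames, x10 per design
      ceiling(10 * max(1, sum(pmax(a$acf, 0))))
    } else 1L
  }
  ci <- if (nrow(formed) >= 4L)
    block_bootstrap_ci(formed, block, n_boot, seed)
  else rbind(pop, pop)
  data.frame(bond = seq_along(pop), population = unname(pop),
             lo = unname(ci[1L, ]), hi = unname(ci[2L, ]))
}

#' Hydrogen-bond heat map P(HBi, NHB)
#'
#' For each total number of formed bonds NHB = m, the fraction of frames
#' with exactly m bonds in which bond i is formed. Rows with no frames
#' are reported as `NA` and flagged in the `frames` count. On every
#' populated row the entries sum to m.
#'
#' @param hb an `"hbond_matrix"`.
#' @return an object of class `"hbond_heatmap"`: matrix `P` with rows
#'   `NHB = 0..n-2` and columns `bond_1..bond_{n-2}`, plus per-row frame
#'   counts.
#' @export
hbond_heatmap <- function(hb) {
  formed <- hb$formed * 1
  nb <- ncol(formed)
  nhb <- rowSums(formed)
  P <- matrix(NA_real_, nb + 1L, nb,
              dimnames = list(paste0("NHB_", 0:nb), colnames(hb$lengths)))
  counts <- integer(nb + 1L)
  for (m in 0:nb) {
    sel <- nhb == m
    counts[m + 1L] <- sum(sel)
    if (any(sel)) P[m + 1L, ] <- colMeans(formed[sel, , drop = FALSE])
  }
  structure(list(P = P, frames = counts), class = "hbond_heatmap")
}

#' @export
print.hbond_heatmap <- function(x, ...) {
  cat(sprintf("P(HBi, NHB) heat map: %d bond positions, %d populated rows\n",
              ncol(x$P), sum(x$frames > 0L)))
  invisible(x)
}

#' @export
plot.hbond_heatmap <- function(x, ...) {
  P <- x$P
  P[is.na(P)] <- 0
  graphics::image(x = seq_len(ncol(P)), y = 0:(nrow(P) - 1L), z = t(P),
                  xlab = "hydrogen bond i", ylab = "NHB",
                  col = grDevices::hcl.colors(64, "Blue-Red"), ...)
  invisible(x)
}

#' Neighbor hydrogen-bond correlation profile
#'
#' Pearson correlations between the O...N length fluctuation series of
#' every bond pair, summarized as the mean correlation per neighbor
#' separation k (k = 1 nearest neighbors, k = 2 next-nearest, ...).
#' Zero-variance bonds are excluded with a warning.
#'
#' @param hb an `"hbond_matrix"` (>= 10 frames).
#' @return an object of class `"correlation_profile"` with the full
#'   correlation matrix and a data.frame `profile` (`separation`,
#'   `mean_r`).
#' @export
neighbor_correlation <- function(hb) {
  L <- hb$lengths
  if (nrow(L) < 10L) stop("need >= 10 frames for correlations")
  v <- apply(L, 2L, stats::var)
  keep <- v > 0
  if (!all(keep))
    warning(sprintf("excluding %d zero-variance bond(s)", sum(!keep)))
  if (sum(keep) < 2L) stop("fewer than two bonds with variance")
  R <- stats::cor(L[, keep, drop = FALSE])
  idx <- which(keep)
  seps <- sort(unique(as.vector(abs(outer(idx, idx, `-`)))))
  seps <- seps[seps > 0L]
  mean_r <- vapply(seps, function(k) {
    pair <- abs(outer(idx, idx, `-`)) == k
    mean(R[pair])
  }, numeric(1L))
  structure(list(R = R, bonds = idx,
                 profile = data.frame(separation = seps, mean_r = mean_r)),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("Neighbor h-bond correlation profile:\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}
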