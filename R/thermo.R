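# Two-state helix folding thermodynamics and kinetics. Energies are in
# kcal/mol, rates in 1/ns, temperatures in kelvin.

#' Gas constant in kcal/(mol K)
#' @export
R_GAS <- 1.9872e-3

#' Folding free energy from the helix fraction
#'
#' `dG = -R T ln(f / (1 - f))`: negative when the helix is the majority
#' species.
#'
#' @param f helix fraction, strictly inside (0, 1).
#' @param T temperature in kelvin.
#' @return an object of class `"thermo_result"` with `f`, `T` and
#'   `delta_g` (kcal/mol).
#' @export
folding_free_energy <- function(f, T = 300) {
  if (!is.numeric(f) || any(f <= 0) || any(f >= 1))
    stop("helix fraction must be strictly inside (0, 1)")
  if (T <= 0) stop("temperature must be positive")
  structure(list(f = f, T = T, delta_g = -R_GAS * T * log(f / (1 - f))),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Helix fraction %.4g at %g K: dG = %.3f kcal/mol\n",
              x$f, x$T, x$delta_g))
  invisible(x)
}

#' Folding/unfolding rates from helix fraction and relaxation time
#'
#' Standard two-state decomposition: `k_f = f / tau2` and
#' `k_u = (1 - f) / tau2`, so that `k_f + k_u = 1/tau2` and
#' `k_f / k_u = f / (1 - f)`.
#'
#' @param f helix fraction in (0, 1).
#' @param tau2 global relaxation time in ns.
#' @return an object of class `"rate_pair"` with `k_f`, `k_u` (1/ns)
#'   and `tau2`.
#' @export
rates_from_fraction_and_tau <- function(f, tau2) {
  if (f <= 0 || f >= 1) stop("helix fraction must be inside (0, 1)")
  if (tau2 <= 0) stop("tau2 must be positive")
  structure(list(k_f = f / tau2, k_u = (1 - f) / tau2, tau2 = tau2),
            class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("k_f = %.4g 1/ns, k_u = %.4g 1/ns (tau2 = %.4g ns)\n",
              x$k_f, x$k_u, x$tau2))
  invisible(x)
}

#' Folding free energy from a rate pair
#'
#' `dG = -R T ln(k_f / k_u)`, the detailed-balance companion of
#' [folding_free_energy()].
#'
#' @param k_f,k_u folding and unfolding rates in 1/ns (> 0).
#' @param T temperature in kelvin.
#' @return free energy in kcal/mol.
#' @export
free_energy_from_rates <- function(k_f, k_u, T = 300) {
  if (any(k_f <= 0) || any(k_u <= 0)) stop("rates must be positive")
  -R_GAS * T * log(k_f / k_u)
}

#' Two-state relaxation time
#'
#' `tau2 = 1 / (k_f + k_u)`, the relaxation time of the non-stationary
#' eigenmode of the 2 x 2 rate matrix.
#'
#' @param k_f,k_u rates in 1/ns (> 0).
#' @return relaxation time in ns.
#' @export
two_state_relaxation_time <- function(k_f, k_u) {
  if (any(k_f <= 0) || any(k_u <= 0)) stop("rates must be positive")
  1 / (k_f + k_u)
}

#' Free-energy increment per residue from enthalpy and entropy
#'
#' `dG/dn = dH/dn - T dS/dn`, the per-residue helix stabilization at
#' temperature `T`.
#'
#' @param dH enthalpy increment, kcal/mol per residue.
#' @param dS entropy increment, kcal/(mol K) per residue.
#' @param T temperature in kelvin.
#' @return kcal/mol per residue.
#' @export
delta_g_per_residue <- function(dH, dS, T = 300) {
  dH - T * dS
}

#' Free-energy-versus-length trend
#'
#' Ordinary least-squares slope of folding free energy against peptide
#' length.
#'
#' @param points data.frame (or 2-column matrix) with columns `n`
#'   (residue count) and `delta_g` (kcal/mol); >= 2 distinct `n`.
#' @return an object of class `"length_trend"` with `slope`
#'   (kcal/mol per residue), `intercept`, `points` and the `lm` fit.
#' @export
free_energy_slope <- function(points) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("n", "delta_g")
  if (length(unique(pts$n)) < 2L)
    stop("need >= 2 distinct peptide lengths")
  fit <- stats::lm(delta_g ~ n, data = pts)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 points = pts, fit = fit),
            class = "length_trend")
}

#' @export
print.length_trend <- function(x, ...) {
  cat(sprintf(
    "dG vs length over n = %s: slope %.3f kcal/mol per residue\n",
    paste(sort(unique(x$points$n)), collapse = ", "), x$slope))
  invisible(x)
}

#' @export
plot.length_trend <- function(x, ...) {
  graphics::plot(x$points$n, x$points$delta_g, xlab = "residues n",
                 ylab = "dG (kcal/mol)", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}
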