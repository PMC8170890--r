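# The fitting front end: a single entry point running featurization,
# relaxation analysis, clustering, core discretization, rate-matrix
# estimation, PCCA+ lumping, ODR reduction, set classification and
# committor analysis, returning one classed model object; plus the
# configuration-driven pipeline runner that writes the artifact bundle.

#' Fit a coarse-grained helix-folding kinetic model
#'
#' Runs the full analysis chain on a conformational trajectory:
#' \enumerate{
#'   \item per-frame features and hydrogen-bond matrix ([featurize()]);
#'   \item ACF of a global feature and biexponential fit giving the
#'     trajectory relaxation time tau2 ([fit_biexponential()]);
#'   \item CA-RMSD leader clustering into microstates
#'     ([cluster_leader()]);
#'   \item core-radius calibration against tau2 and core
#'     discretization ([calibrate_core_radius()]);
#'   \item transition counting and generator estimation
#'     ([estimate_rate_matrix()]);
#'   \item PCCA+ lumping into `n_states` aggregates ([pcca_plus()]);
#'   \item ODR reduced rate matrix ([odr_fit()]);
#'   \item helix/coil/intermediate classification ([classify_sets()]);
#'   \item committor analysis between the helix and coil microstate
#'     sets ([committor()]).
#' }
#' Two-state thermodynamics (helix fraction, folding/unfolding rates,
#' folding free energy) are derived from the reduced model: for
#' `n_states = 2` the rates are the off-diagonals of `R`, otherwise
#' they come from the helix-set population and tau2.
#'
#' @param traj a [trajectory()].
#' @param cluster_radius microstate cluster radius in Angstrom.
#' @param core_grid candidate core radii; default
#'   `cluster_radius * c(0.3, 0.5, 0.7, 1)`.
#' @param n_states number of aggregate states N (2-5 typical).
#' @param lag transition-counting lag in ns (default: sampling
#'   interval).
#' @param acf_feature feature used for the relaxation-time fit.
#' @param max_lag ACF maximum lag in ns (default: a quarter of the
#'   trajectory duration).
#' @param T temperature in kelvin.
#' @return an object of class `"helix_kinetics"`, with `print`,
#'   `summary`, `coef`, `plot` and [simulate.helix_kinetics()] methods.
#' @export
fit_helix_kinetics <- function(traj, cluster_radius, core_grid = NULL,
                               n_states = 2L, lag = NULL,
                               acf_feature = "rmsd_from_helix",
                               max_lag = NULL, T = 300) {
  stage <- "featurize"
  out <- tryCatch({
    fs <- featurize(traj)

    stage <- "relaxation"
    dur <- traj$dt * (length(traj$frames) - 1L)
    if (is.null(max_lag)) max_lag <- dur / 4
    acf <- autocorrelation(fs$features[[acf_feature]], max_lag)
    bi <- fit_biexponential(acf)
    tau2 <- bi$tau_slow

    stage <- "clustering"
    cl <- cluster_leader(traj, cluster_radius)
    if (n_states > cl$n_clusters)
      stop(sprintf("n_states = %d exceeds N_c = %d clusters",
                   n_states, cl$n_clusters))

    stage <- "core calibration"
    if (is.null(core_grid)) core_grid <- cluster_radius * c(0.3, 0.5, 0.7, 1)
    cores <- calibrate_core_radius(traj, cl, tau2, core_grid, lag = lag)

    stage <- "rate matrix"
    tm <- count_transitions(cores, lag = lag)
    km <- estimate_rate_matrix(tm)

    stage <- "PCCA+"
    memb <- pcca_plus(km, n_states)

    stage <- "ODR"
    red <- odr_fit(km, memb)

    stage <- "classification"
    # PCCA+ operates on the connected microstates kept in the rate
    # model; map the aggregate assignment back onto all clusters, with
    # unvisited clusters following their nearest visited cluster
    assign_clusters <- rep(NA_integer_, cl$n_clusters)
    assign_clusters[km$states] <- memb$assignment
    if (anyNA(assign_clusters)) {
      for (j in which(is.na(assign_clusters))) {
        d <- cl$dist[cl$centers[j], km$states]
        assign_clusters[j] <- memb$assignment[which.min(d)]
      }
    }
    sets <- classify_sets(assign_clusters, cl, traj, reduced = red, T = T)

    stage <- "committor"
    helix_set <- which(sets$sets$label == "helix")
    coil_set <- which(sets$sets$label == "coil")
    micro_of <- function(I) which(memb$assignment == I)
    q <- committor(km, micro_of(helix_set), micro_of(coil_set))

    stage <- "thermodynamics"
    f <- sets$sets$population[helix_set]
    if (n_states == 2L) {
      k_f <- red$R[coil_set, helix_set]
      k_u <- red$R[helix_set, coil_set]
    } else {
      rp <- rates_from_fraction_and_tau(f, tau2)
      k_f <- rp$k_f; k_u <- rp$k_u
    }
    structure(list(
      features = fs, acf = acf, biexp = bi, tau2_md = tau2,
      clustering = cl, cores = cores, transition = tm, rate_model = km,
      membership = memb, reduced = red, sets = sets, committor = q,
      helix_fraction = f, k_f = k_f, k_u = k_u,
      delta_g = free_energy_from_rates(k_f, k_u, T),
      T = T, n_states = n_states, spec = traj$spec),
      class = "helix_kinetics")
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  out
}

#' @export
print.helix_kinetics <- function(x, ...) {
  cat(sprintf("Helix-folding kinetic model for ALA%d\n",
              x$spec$n_residues))
  cat(sprintf("  N_c = %d microstates -> N = %d aggregate states\n",
              x$clustering$n_clusters, x$n_states))
  cat(sprintf("  tau2 (trajectory ACF) = %.4g ns; slowest model time = %.4g ns\n",
              x$tau2_md,
              if (length(x$rate_model$timescales))
                x$rate_model$timescales[1L] else NA_real_))
  cat(sprintf("  helix fraction f = %.3f, k_f = %.4g 1/ns, k_u = %.4g 1/ns\n",
              x$helix_fraction, x$k_f, x$k_u))
  cat(sprintf("  folding free energy dG = %.3f kcal/mol at %g K\n",
              x$delta_g, x$T))
  invisible(x)
}

#' @export
summary.helix_kinetics <- function(object, ...) {
  print(object)
  cat("\nAggregate sets:\n")
  print(object$sets$sets, row.names = FALSE, digits = 4)
  cat("\nReduced rate matrix R (1/ns):\n")
  print(signif(object$reduced$R, 4))
  cat("\nODR fidelity (reduced vs full relaxation times):\n")
  print(object$reduced$fidelity, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.helix_kinetics <- function(object, ...) {
  c(k_f = object$k_f, k_u = object$k_u,
    tau2 = two_state_relaxation_time(object$k_f, object$k_u),
    f = object$helix_fraction, delta_g = object$delta_g)
}

#' Simulate from a fitted reduced model
#'
#' Gillespie realization of the fitted aggregate-state jump process,
#' sampled at the trajectory's interval.
#'
#' @param object a [fit_helix_kinetics()] model.
#' @param nsim number of sampled frames.
#' @param seed RNG seed.
#' @param ... unused.
#' @return integer aggregate-state series with attribute `dt`.
#' @export
simulate.helix_kinetics <- function(object, nsim = 1000L, seed = 1L, ...) {
  dt <- object$features$features[[1L]]$dt
  gillespie_simulate(object$reduced$R, t_total = (nsim - 1L) * dt,
                     dt = dt, init = which.max(object$reduced$populations),
                     seed = seed)
}

#' @export
plot.helix_kinetics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$acf, main = "global ACF")
  tt <- seq(0, max(x$acf$lag), length.out = 200L)
  graphics::lines(tt, x$biexp$a1 * exp(-tt / x$biexp$tau_fast) +
                    x$biexp$a2 * exp(-tt / x$biexp$tau_slow),
                  col = 2, lty = 2)
  dg <- x$sets$sets$delta_g
  graphics::plot(seq_along(dg), dg, pch = 19, xaxt = "n",
                 xlab = "", ylab = "dG (kcal/mol)",
                 main = "aggregate free energies")
  graphics::axis(1, at = seq_along(dg), labels = x$sets$sets$label)
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles and validates the parameters of a full pipeline run.
#'
#' @param n_residues peptide length.
#' @param input path to a multi-model PDB trajectory, or `NULL` to
#'   simulate synthetically.
#' @param synthetic list of [helix_coil_simulate()] arguments used when
#'   `input` is `NULL` (s, sigma, nu, t_total, dt).
#' @param cluster_radius microstate cluster radius (Angstrom).
#' @param core_grid candidate core radii (Angstrom).
#' @param n_states aggregate state count N (>= 2).
#' @param lag transition lag in ns (`NULL`: sampling interval).
#' @param temperature kelvin.
#' @param seed integer seed governing simulation and rendering.
#' @param outdir output directory for the artifact bundle.
#' @return a validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(n_residues, input = NULL, synthetic = NULL,
                            cluster_radius = 1.5, core_grid = NULL,
                            n_states = 2L, lag = NULL, temperature = 300,
                            seed = 1L, outdir = tempfile("helixkin_")) {
  if (!is.null(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  if (is.null(input) && is.null(synthetic))
    stop("either an input trajectory or synthetic parameters are required")
  if (n_states < 2L) stop("n_states must be >= 2")
  structure(list(n_residues = as.integer(n_residues), input = input,
                 synthetic = synthetic, cluster_radius = cluster_radius,
                 core_grid = core_grid, n_states = as.integer(n_states),
                 lag = lag, temperature = temperature,
                 seed = as.integer(seed), outdir = outdir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys match [analysis_config()] arguments.
#' @return an `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes simulation/ingestion, fitting via [fit_helix_kinetics()]
#' and writes the artifact bundle (feature table, ACF, cluster and core
#' assignments, kinetic matrices, reduced model, set classification and
#' committor as CSV/JSON, plus a manifest recording inputs, parameters
#' and seeds). Outputs are deterministic for a fixed configuration.
#'
#' @param config an [analysis_config()] (or a YAML path).
#' @return the fitted `"helix_kinetics"` model, invisibly, with the
#'   manifest attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)

  if (!is.null(config$input)) {
    traj <- read_pdb_trajectory(config$input)
  } else {
    syn <- config$synthetic
    sim <- helix_coil_simulate(
      config$n_residues,
      s = syn$s %||% .ZB_PRESET$s,
      sigma = syn$sigma %||% .ZB_PRESET$sigma,
      nu = syn$nu %||% 1,
      t_total = syn$t_total %||% 1000,
      dt = syn$dt %||% 0.1,
      seed = config$seed)
    traj <- render_helix_coil(sim)
    utils::write.csv(sim$indicators * 1, p("indicators.csv"),
                     row.names = FALSE)
  }
  fit <- fit_helix_kinetics(traj, config$cluster_radius,
                            core_grid = config$core_grid,
                            n_states = config$n_states, lag = config$lag,
                            T = config$temperature)

  write_feature_table(fit$features, p("features.csv"))
  utils::write.csv(data.frame(lag_ns = fit$acf$lag, acf = fit$acf$value),
                   p("acf.csv"), row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(fit$clustering$assignment),
                              cluster = fit$clustering$assignment,
                              core = fit$cores$labels),
                   p("discretization.csv"), row.names = FALSE)
  write_model_json(fit$rate_model, p("rate_matrix.json"))
  write_model_json(fit$reduced, p("reduced_model.json"))
  utils::write.csv(fit$sets$sets, p("aggregate_sets.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(state = seq_along(fit$committor$q),
                              q = fit$committor$q),
                   p("committor.csv"), row.names = FALSE)
  write_kinetic_dot(fit$reduced, p("kinetic_scheme.dot"), sets = fit$sets)
  for (I in seq_len(fit$n_states))
    write_pdb(fit$sets$representatives[[I]],
              p(sprintf("representative_set%d_%s.pdb", I,
                        fit$sets$sets$label[I])))

  manifest <- list(
    package = "helixkin",
    version = as.character(utils::packageVersion("helixkin")),
    stages = c("simulate/ingest", "featurize", "relaxation", "clustering",
               "core calibration", "rate matrix", "PCCA+", "ODR",
               "classification/committor"),
    parameters = config[setdiff(names(config), "outdir")],
    tau2_md_ns = fit$tau2_md,
    coefficients = as.list(coef(fit)))
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  attr(fit, "manifest") <- manifest
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
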