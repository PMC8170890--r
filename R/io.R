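# Tabular and JSON input/output: feature tables round trip through CSV,
# kinetic matrices through JSON with explicit labels, and reduced
# kinetic schemes through DOT graph text.

#' Write a feature set to CSV
#'
#' Columns: `time_ns`, one column per named feature series, then
#' `bond_1..bond_{n-2}` O...N lengths.
#'
#' @param fs a [featurize()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fs, path) {
  nf <- length(fs$features[[1L]]$values)
  dt <- fs$features[[1L]]$dt
  df <- data.frame(time_ns = (seq_len(nf) - 1L) * dt)
  for (s in fs$features) df[[s$name]] <- s$values
  df <- cbind(df, as.data.frame(fs$hbonds$lengths))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]: requires a `time_ns` column with
#' uniform spacing; `bond_*` columns become the hydrogen-bond length
#' matrix, all other columns named feature series.
#'
#' @param path CSV path.
#' @return a `"feature_set"` list with `features` and `hbonds`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) < 2L) stop("feature table needs >= 2 rows")
  if (!"time_ns" %in% names(df)) stop("missing time_ns column")
  dts <- diff(df$time_ns)
  if (any(abs(dts - dts[1L]) > 1e-9 * max(1, abs(dts[1L]))))
    stop("non-uniform sampling in time_ns column")
  dt <- dts[1L]
  bond_cols <- grep("^bond_", names(df), value = TRUE)
  feat_cols <- setdiff(names(df), c("time_ns", bond_cols))
  features <- lapply(feat_cols, function(nm)
    feature_series(nm, df[[nm]], dt))
  names(features) <- feat_cols
  hb <- NULL
  if (length(bond_cols)) {
    bond_cols <- bond_cols[order(as.integer(sub("^bond_", "", bond_cols)))]
    hb <- new_hbond_matrix(as.matrix(df[bond_cols]), dt)
  }
  structure(list(features = features, hbonds = hb), class = "feature_set")
}

#' Write a kinetic model to JSON
#'
#' Serializes rate/transition matrices with explicit row and column
#' labels, shapes and units.
#'
#' @param model a `"rate_matrix_model"`, `"transition_model"` or
#'   `"reduced_model"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "rate_matrix_model")) {
    list(type = "rate_matrix", units = "1/ns",
         states = model$states, shape = dim(model$K),
         K = model$K, pi = model$pi, timescales_ns = model$timescales)
  } else if (inherits(model, "transition_model")) {
    list(type = "transition_matrix", lag_ns = model$lag,
         states = model$states, shape = dim(model$T),
         T = model$T, counts = model$counts)
  } else if (inherits(model, "reduced_model")) {
    list(type = "reduced_rate_matrix", units = "1/ns",
         shape = dim(model$R), R = model$R,
         populations = model$populations,
         lifetimes_ns = model$lifetimes,
         timescales_ns = model$timescales,
         assignment = model$assignment, lags_ns = model$lags)
  } else stop("unsupported model type")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' Export a reduced kinetic scheme as a DOT graph
#'
#' One node per aggregate set (labeled with population and lifetime),
#' one edge per nonzero off-diagonal rate.
#'
#' @param reduced an [odr_fit()] model.
#' @param sets optional [classify_sets()] result supplying labels.
#' @param path output DOT path.
#' @return `path`, invisibly.
#' @export
write_kinetic_dot <- function(reduced, path, sets = NULL) {
  N <- nrow(reduced$R)
  labels <- if (!is.null(sets)) sets$sets$label else paste0("set", seq_len(N))
  lines <- c("digraph kinetic_scheme {", "  rankdir=LR;")
  for (i in seq_len(N))
    lines <- c(lines, sprintf(
      "  s%d [label=\"%s\\npop %.3f\\ntau %.3g ns\"];",
      i, labels[i], reduced$populations[i], reduced$lifetimes[i]))
  for (i in seq_len(N)) for (j in seq_len(N))
    if (i != j && reduced$R[i, j] > 0)
      lines <- c(lines, sprintf("  s%d -> s%d [label=\"%.3g/ns\"];",
                                i, j, reduced$R[i, j]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
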