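# Folding-pathway statistics: committor probabilities on the microstate
# rate matrix, transition-state candidates and helix-initiation profiles
# from the hydrogen-bond heat map.

#' Committor probabilities
#'
#' Probability `q_i` of reaching the helix set before the coil set when
#' starting from microstate i, obtained from the linear boundary-value
#' problem `sum_j K_ij q_j = 0` on the interior states with `q = 1` on
#' the helix boundary and `q = 0` on the coil boundary.
#'
#' @param model a [rate_matrix_model()] (connected).
#' @param helix_states,coil_states disjoint nonempty index sets (sink
#'   and source).
#' @return an object of class `"committor_field"`: vector `q`, the
#'   boundary sets and the interior residual norm.
#' @export
committor <- function(model, helix_states, coil_states) {
  K <- model$K
  n <- nrow(K)
  helix_states <- unique(as.integer(helix_states))
  coil_states <- unique(as.integer(coil_states))
  if (!length(helix_states) || !length(coil_states))
    stop("boundary sets must be nonempty")
  if (length(intersect(helix_states, coil_states)))
    stop("helix and coil boundary sets overlap")
  if (any(c(helix_states, coil_states) < 1L) ||
      any(c(helix_states, coil_states) > n))
    stop("boundary state index out of range")
  q <- rep(NA_real_, n)
  q[helix_states] <- 1
  q[coil_states] <- 0
  interior <- setdiff(seq_len(n), c(helix_states, coil_states))
  if (length(interior)) {
    Kii <- K[interior, interior, drop = FALSE]
    rhs <- -K[interior, helix_states, drop = FALSE] %*%
      rep(1, length(helix_states))
    qi <- tryCatch(solve(Kii, rhs),
                   error = function(e)
                     stop("interior system is singular (disconnected interior)"))
    q[interior] <- as.vector(qi)
    resid <- max(abs(K[interior, , drop = FALSE] %*% q))
  } else resid <- 0
  q <- pmin(pmax(q, 0), 1)   # clamp round-off at the boundaries
  structure(list(q = q, helix_states = helix_states,
                 coil_states = coil_states, interior = interior,
                 residual = resid),
            class = "committor_field")
}

#' @export
print.committor_field <- function(x, ...) {
  cat(sprintf("Committor field over %d states (%d interior), residual %.2g\n",
              length(x$q), length(x$interior), x$residual))
  invisible(x)
}

#' Transition-state candidate microstates
#'
#' Interior states whose committor falls inside `window`, ranked by
#' distance from q = 0.5. An empty result is allowed (short peptides
#' may not resolve transition-state-like microstates).
#'
#' @param q a [committor()] field.
#' @param window numeric `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return data.frame with columns `state`, `q`, ordered by
#'   `|q - 0.5|`.
#' @export
transition_state_candidates <- function(q, window = c(0.4, 0.6)) {
  if (length(window) != 2L || window[1L] < 0 || window[2L] > 1 ||
      window[1L] >= window[2L])
    stop("window must be c(lo, hi) with 0 <= lo < hi <= 1")
  cand <- intersect(x = q$interior,
                    y = which(q$q >= window[1L] & q$q <= window[2L]))
  out <- data.frame(state = cand, q = q$q[cand])
  out[order(abs(out$q - 0.5), out$state), , drop = FALSE]
}

#' Helix-initiation profile
#'
#' The normalized NHB = 1 row of the hydrogen-bond heat map: among the
#' frames with exactly one formed helical bond, the probability that it
#' is bond i. Also reports the terminal-versus-central contrast (mean
#' probability of the first and last bond minus the mean over interior
#' bonds), positive when initiation at the chain ends is favored.
#'
#' @param hm an [hbond_heatmap()].
#' @return an object of class `"initiation_profile"` with `p` (per-bond
#'   probabilities summing to 1) and `terminal_contrast`.
#' @export
initiation_profile <- function(hm) {
  row1 <- hm$P[2L, ]   # NHB = 1
  if (hm$frames[2L] == 0L || all(is.na(row1)))
    stop("no frames with exactly one formed bond (NHB = 1 row empty)")
  p <- row1 / sum(row1)
  nb <- length(p)
  contrast <- if (nb > 2L)
    mean(p[c(1L, nb)]) - mean(p[2:(nb - 1L)])
  else NA_real_
  structure(list(p = unname(p), terminal_contrast = contrast),
            class = "initiation_profile")
}

#' @export
print.initiation_profile <- function(x, ...) {
  cat("Helix initiation profile (NHB = 1):\n  ",
      paste(sprintf("%.3f", x$p), collapse = " "), "\n")
  if (is.finite(x$terminal_contrast))
    cat(sprintf("  terminal contrast: %+.3f\n", x$terminal_contrast))
  invisible(x)
}
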