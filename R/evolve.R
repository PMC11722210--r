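# Deterministic evolution of a population of cells under a network.
#
# The ODEs couple species within a cell, never across cells, so a
# population is integrated cell by cell. The default integrator is the
# package's compiled adaptive Dormand-Prince 5(4) scheme, which keeps
# GMM estimation (millions of cell trajectories) tractable; "lsoda"
# delegates to deSolve's stiff-capable solver and is useful as a slow
# reference or for unusually stiff rate regimes.

#' Evolve a population of cells to time t
#'
#' @param network a [reaction_network()].
#' @param rates full rate vector `(theta_1, theta_2, theta_3)` filling
#'   the network's free slots.
#' @param initial_states N x n matrix of strictly positive abundances,
#'   one row per cell, columns in network species order.
#' @param t final time in seconds (integration starts at 0).
#' @param rtol,atol relative and absolute integration tolerances.
#' @param method `"dopri"` (compiled adaptive Runge-Kutta, default) or
#'   `"lsoda"` (deSolve, stiff-capable).
#' @param max_steps per-cell step budget for `"dopri"`.
#' @return N x n matrix of abundances at time `t`. Tiny negative
#'   undershoots within `100 * atol` of zero are clipped to zero with a
#'   warning; larger negatives raise an error naming the offending row.
#' @export
evolve_cells <- function(network, rates, initial_states, t,
                         rtol = 1e-8, atol = 1e-10,
                         method = c("dopri", "lsoda"),
                         max_steps = 200000L) {
  method <- match.arg(method)
  x0 <- as.matrix(initial_states)
  ns <- length(network$species)
  if (ncol(x0) != ns) {
    stop_data("initial_states has ", ncol(x0), " columns, expected ", ns)
  }
  if (any(!is.finite(x0)) || any(x0 <= 0)) {
    stop_data("initial states must be finite and strictly positive")
  }
  if (!is.finite(t) || t < 0) stop_data("t must be >= 0")
  if (t == 0) {
    colnames(x0) <- network$species
    return(x0)
  }
  k <- resolved_rate_constants(network, rates)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop_data("resolved rate constants must be finite and >= 0")
  }

  if (method == "dopri") {
    res <- dopri_evolve_cpp(x0, t, network$reactant_stoich,
                            network$net_stoich, k, rtol, atol,
                            as.integer(max_steps))
    bad <- which(res$status != 0L)
    if (length(bad)) {
      why <- c("step budget exhausted", "step size collapsed")[res$status[bad[1]]]
      stop_numeric("integration failed for cell (row) ", bad[1], ": ", why,
                   " [rates = ", paste(signif(k, 6), collapse = ", "), "]")
    }
    out <- res$states
  } else {
    rhs <- function(tt, y, parms) {
      flux <- k * apply(network$reactant_stoich, 1,
                        function(s) prod(pmax(y, 0)[s > 0]^s[s > 0]))
      list(drop(t(network$net_stoich) %*% flux))
    }
    out <- matrix(NA_real_, nrow(x0), ns)
    for (j in seq_len(nrow(x0))) {
      sol <- try(deSolve::ode(y = x0[j, ], times = c(0, t), func = rhs,
                              parms = NULL, method = "lsoda",
                              rtol = rtol, atol = atol), silent = TRUE)
      if (inherits(sol, "try-error") || nrow(sol) < 2) {
        stop_numeric("lsoda failed for cell (row) ", j)
      }
      out[j, ] <- sol[2, -1]
    }
  }

  neg <- out < 0
  if (any(neg)) {
    worst <- min(out)
    if (worst < -100 * atol) {
      row <- which(apply(out, 1, min) == worst)[1]
      stop_numeric("negative abundance ", signif(worst, 4),
                   " beyond undershoot tolerance in cell (row) ", row)
    }
    warning("clipped ", sum(neg), " integrator undershoot(s) in [",
            signif(worst, 3), ", 0) to zero", call. = FALSE)
    out[neg] <- 0
  }
  colnames(out) <- network$species
  out
}
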