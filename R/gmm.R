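# Generalized method of moments: candidate free parameters are chosen
# so that the first and second moments of the evolved candidate pool
# match those of the observed snapshot, in a weighted least-squares
# sense. Optimization runs over log10 rates (rates span orders of
# magnitude and must stay positive) with seeded Latin-hypercube
# multi-starts.

#' Compute sample moments of a snapshot
#'
#' @param data a [tss_dataset()] or an N x n abundance matrix.
#' @param include which moment blocks to use: any subset of
#'   `"means"`, `"variances"`, `"covariances"` (all three by default,
#'   27 conditions for six proteins). Variances and covariances use the
#'   N - 1 denominator.
#' @return an object of class `moment_set` with `means`, `variances`,
#'   `covariances` (upper triangle, row-major), the block selection,
#'   and the snapshot timestamp (when known).
#' @export
compute_moments <- function(data,
                            include = c("means", "variances", "covariances")) {
  include <- match.arg(include, several.ok = TRUE,
                       choices = c("means", "variances", "covariances"))
  a <- if (inherits(data, "tss_dataset")) data$abundances else as.matrix(data)
  ts <- if (inherits(data, "tss_dataset")) data$timestamp else NA_real_
  if (nrow(a) < 2) stop_data("need at least 2 cells to compute moments")
  n <- ncol(a)
  nm <- colnames(a)
  if (is.null(nm)) nm <- paste0("P", seq_len(n))
  V <- cov(a)
  ut <- which(upper.tri(V), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]  # row-major
  N <- nrow(a)
  # Delta-method sampling variances of each moment estimate; these
  # drive the default inverse-variance GMM weights.
  xc <- sweep(a, 2, colMeans(a))
  m4 <- colMeans(xc^4)
  v <- diag(V)
  sv_means <- v / N
  sv_vars <- pmax(m4 - v^2, 0) / N
  sv_covs <- vapply(seq_len(nrow(ut)), function(r) {
    w <- xc[, ut[r, 1]] * xc[, ut[r, 2]]
    max(mean(w^2) - mean(w)^2, 0) / N
  }, numeric(1))
  cov_names <- paste0("cov_", nm[ut[, 1]], "_", nm[ut[, 2]])
  structure(list(
    means = stats::setNames(colMeans(a), nm),
    variances = stats::setNames(v, nm),
    covariances = stats::setNames(V[ut], cov_names),
    sampling_var = list(means = stats::setNames(sv_means, nm),
                        variances = stats::setNames(sv_vars, nm),
                        covariances = stats::setNames(sv_covs, cov_names)),
    include = include, timestamp = ts, n_cells = nrow(a)),
    class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat("Moment set (", paste(x$include, collapse = " + "), ") from ",
      x$n_cells, " cells at t = ", x$timestamp, " s\n", sep = "")
  print(signif(x$means, 5))
  invisible(x)
}

#' Stack the selected moment blocks into one vector
#'
#' @param ms a [compute_moments()] result.
#' @return named numeric vector in block order means, variances,
#'   covariances (restricted to `ms$include`).
#' @export
stack_moments <- function(ms) {
  out <- numeric(0)
  if ("means" %in% ms$include) out <- c(out, ms$means)
  if ("variances" %in% ms$include) out <- c(out, ms$variances)
  if ("covariances" %in% ms$include) out <- c(out, ms$covariances)
  out
}

#' Diagonal GMM weights
#'
#' The default `"invvar"` mode weights each moment by the inverse of
#' its delta-method sampling variance in the target sample, so every
#' moment condition contributes on the scale of its own statistical
#' information: precisely measured moments (the large means) count
#' strongly, while weak-signal covariances whose targets are mostly
#' sampling noise cannot dominate the objective. `"relative"` weights
#' by `1 / max(target^2, eps)` (differences relative to the target's
#' magnitude) and `"unit"` uses 1; both are kept as switches because
#' `"relative"` lets near-zero covariance targets - pure noise - swamp
#' the fit and degrade parameter recovery.
#'
#' @param target the target [compute_moments()] set.
#' @param mode `"invvar"`, `"relative"` or `"unit"`.
#' @param eps floor applied to squared targets / sampling variances.
#' @return named positive weight vector aligned with
#'   [stack_moments()] of the target.
#' @export
gmm_weights <- function(target, mode = c("invvar", "relative", "unit"),
                        eps = 1e-12) {
  mode <- match.arg(mode)
  tv <- stack_moments(target)
  if (mode == "unit") return(stats::setNames(rep(1, length(tv)), names(tv)))
  if (mode == "relative") return(1 / pmax(tv^2, eps))
  sv <- numeric(0)
  for (block in target$include) sv <- c(sv, target$sampling_var[[block]])
  1 / pmax(sv, eps * pmax(max(sv), 1))
}

#' GMM objective for one candidate at given free parameters
#'
#' Evolves the candidate pool to the target's timestamp under
#' `resolve_rates(model, free_params)`, computes the same moment blocks
#' as the target, and returns the weighted sum of squared differences.
#'
#' @param free_params strictly positive free-parameter vector.
#' @param model a [candidate_model()].
#' @param candidate_pool a time-0 [tss_dataset()].
#' @param target target [compute_moments()] (must carry a timestamp).
#' @param weights positive weight vector aligned with the stacked
#'   target; defaults to [gmm_weights()] in inverse-variance mode.
#' @param max_steps per-cell step budget handed to [evolve_cells()];
#'   the optimizer uses a reduced budget so that pathologically stiff
#'   rate combinations fail fast instead of burning time.
#' @param rtol,atol integration tolerances handed to [evolve_cells()]
#'   (the optimizer's search stage relaxes them).
#' @return scalar >= 0; exactly zero iff all matched moments agree.
#' @export
gmm_objective <- function(free_params, model, candidate_pool, target,
                          weights = NULL, max_steps = 200000L,
                          rtol = 1e-8, atol = 1e-10) {
  if (is.null(weights)) weights <- gmm_weights(target)
  if (is.na(target$timestamp)) stop_data("target moments lack a timestamp")
  rates <- resolve_rates(model, free_params)
  evolved <- tryCatch(
    evolve_cells(model$network, rates, candidate_pool$abundances,
                 target$timestamp, rtol = rtol, atol = atol,
                 max_steps = max_steps),
    error = function(e) {
      stop_numeric("ODE evolution failed at free_params = (",
                   paste(signif(free_params, 6), collapse = ", "), "): ",
                   conditionMessage(e))
    })
  m <- compute_moments(evolved, include = target$include)
  d <- stack_moments(m) - stack_moments(target)
  if (length(weights) != length(d)) {
    stop_data("weights length ", length(weights),
              " does not match stacked moment vector length ", length(d))
  }
  sum(weights * d^2)
}

#' Estimate a candidate's free parameters by GMM
#'
#' Multi-start bounded minimization of [gmm_objective()] over log10
#' free parameters. Starts come from a seeded Latin hypercube over
#' `[lower, upper]` on the log scale; each start is refined on a seeded
#' subsample of the candidate pool (`search_size` cells) and the best
#' start is then polished on the full pool at tight tolerance. The
#' procedure is deterministic given `seed`.
#'
#' @inheritParams gmm_objective
#' @param n_starts number of Latin-hypercube starts.
#' @param seed seed for starts and the search subsample.
#' @param lower,upper box bounds on each free rate.
#' @param search_size pool subsample size used during the multi-start
#'   search stage (the polish stage always uses the full pool).
#' @return an object of class `gmm_fit` with `theta_tilde`,
#'   `objective_value`, `converged`, `n_starts`, `best_start_index`,
#'   and the per-start search table.
#' @export
estimate_parameters <- function(model, candidate_pool, target,
                                weights = NULL, n_starts = 8, seed = 1L,
                                lower = 1e-8, upper = 1e2,
                                search_size = 500L) {
  if (n_starts < 1) stop_config("n_starts must be >= 1")
  if (is.null(weights)) weights <- gmm_weights(target)
  p <- model$n_free
  llo <- log10(lower); lhi <- log10(upper)

  npool <- nrow(candidate_pool$abundances)
  sub_pool <- candidate_pool
  if (is.finite(search_size) && search_size < npool) {
    set.seed(derive_seed(seed, "gmm-subsample"))
    sub_pool <- tss_subset(candidate_pool,
                           sort(sample.int(npool, search_size)))
  }

  set.seed(derive_seed(seed, paste0("gmm-starts-", model$id)))
  grid <- lhs::randomLHS(n_starts, p)
  starts <- llo + grid * (lhi - llo)

  # The raw objective spans many orders of magnitude (and integration
  # fails outright in very stiff corners of the box), so the optimizer
  # works on log(objective + tiny): a monotone transform with the same
  # minimizer but far better conditioning for finite-difference
  # gradients. Failed evaluations get a bounded penalty.
  safe_obj <- function(lp, pool, max_steps, rtol, atol) {
    v <- tryCatch(gmm_objective(10^lp, model, pool, target, weights,
                                max_steps = max_steps,
                                rtol = rtol, atol = atol),
                  error = function(e) NA_real_)
    if (!is.finite(v)) v <- 1e6
    log(v + 1e-16)
  }

  # Search stage: subsampled pool, relaxed integration tolerance and a
  # small step budget (stiff corners of the box fail fast into the
  # penalty). Polish stage: full pool at full tolerance.
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      optim(starts[s, ], safe_obj, pool = sub_pool, max_steps = 1000L,
            rtol = 1e-6, atol = 1e-8, method = "L-BFGS-B",
            lower = rep(llo, p), upper = rep(lhi, p),
            control = list(maxit = 40, factr = 1e9)),
      error = function(e) list(par = starts[s, ], value = Inf, convergence = 99))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals)) || all(vals >= log(1e6))) {
    stop_numeric("all ", n_starts, " GMM starts failed for candidate ",
                 model$id)
  }
  best <- which.min(vals)
  polish <- optim(fits[[best]]$par, safe_obj, pool = candidate_pool,
                  max_steps = 50000L, rtol = 1e-8, atol = 1e-10,
                  method = "L-BFGS-B",
                  lower = rep(llo, p), upper = rep(lhi, p),
                  control = list(maxit = 60, factr = 1e6))

  theta <- stats::setNames(10^polish$par, paste0("phi", seq_len(p)))
  structure(list(
    model_id = model$id, n_free = p,
    theta_tilde = theta,
    objective_value = max(exp(polish$value) - 1e-16, 0),
    converged = polish$convergence == 0,
    n_starts = n_starts, best_start_index = best,
    seed = as.integer(seed),
    search_values = pmax(exp(vals) - 1e-16, 0),
    rates = resolve_rates(model, theta)),
    class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("GMM fit for candidate", x$model_id, "(", x$n_free, "free parameter(s) )\n")
  cat("  theta_tilde:", paste(signif(x$theta_tilde, 6), collapse = ", "), "\n")
  cat("  resolved rates:", paste(signif(x$rates, 6), collapse = ", "), "\n")
  cat("  objective:", format(x$objective_value, digits = 6),
      " converged:", x$converged,
      " (best of", x$n_starts, "starts: #", x$best_start_index, ")\n")
  invisible(x)
}

#' @export
coef.gmm_fit <- function(object, ...) object$theta_tilde
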