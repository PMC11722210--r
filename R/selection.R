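# Model selection: rank candidates by approximate cross-entropy (the
# sample average of -log predictive density over held-out observed
# cells), cross-check with an approximate small-sample AICc on mean
# differences, and quantify support by bootstrap selection
# probabilities.

#' Approximate cross-entropy of a fitted density on held-out cells
#'
#' The sample average `(1/N) * sum_j -log h(y_j)` over the evaluation
#' cells. Minimizing it over candidates is equivalent to minimizing KL
#' divergence to the (unknown) truth, since the truth's entropy is
#' candidate-independent.
#'
#' @param eval_cells a [tss_dataset()] of held-out observed cells at
#'   the same time as the density's training sample.
#' @param model a [fit_joint_density()] result.
#' @return scalar cross-entropy in nats (finite by construction).
#' @export
approximate_cross_entropy <- function(eval_cells, model) {
  a <- if (inherits(eval_cells, "tss_dataset")) eval_cells$abundances
       else as.matrix(eval_cells)
  if (ncol(a) != length(model$marginals)) {
    stop_data("evaluation data has ", ncol(a),
              " proteins but the density model has ",
              length(model$marginals))
  }
  if (inherits(eval_cells, "tss_dataset") && !is.na(model$timestamp) &&
      !isTRUE(all.equal(eval_cells$timestamp, model$timestamp))) {
    stop_data("evaluation snapshot time ", eval_cells$timestamp,
              " differs from the density's training time ", model$timestamp)
  }
  mean(-joint_log_density(model, a))
}

#' Approximate AICc on observed-minus-predicted mean abundances
#'
#' Models the vector of per-protein mean differences as independent
#' zero-mean normals with variance `s_j^2 = var(obs_j)/N_y +
#' var(pred_j)/N_x` (the squared standard error of the mean
#' difference), sums the corresponding log-likelihood, and applies the
#' small-sample-corrected Akaike penalty with sample size `n` equal to
#' the number of proteins and `k` the number of freely varying
#' parameters. Requires `n - k - 1 > 0`; with more parameters than
#' that, the correction's denominator is zero or negative and the
#' criterion is undefined.
#'
#' @param observed observed [tss_dataset()] (or matrix) at time t.
#' @param predicted candidate-evolved [tss_dataset()] (or matrix) at
#'   time t, same protein columns.
#' @param k number of freely varying parameters (>= 1).
#' @param s2_mode `"se"` (default, standard errors of the mean
#'   difference) or `"pooled"` (pooled per-protein variance).
#' @return the approximate AICc value.
#' @export
approximate_aicc <- function(observed, predicted, k,
                             s2_mode = c("se", "pooled")) {
  s2_mode <- match.arg(s2_mode)
  ao <- if (inherits(observed, "tss_dataset")) observed$abundances
        else as.matrix(observed)
  ap <- if (inherits(predicted, "tss_dataset")) predicted$abundances
        else as.matrix(predicted)
  if (ncol(ao) != ncol(ap)) stop_data("observed/predicted protein columns differ")
  n <- ncol(ao)
  if (k < 1) stop_data("k must be >= 1")
  if (n - k - 1 <= 0) {
    stop_data("approximate AICc requires more proteins than free ",
              "parameters: n - k - 1 = ", n - k - 1,
              " is zero or negative (n = ", n, ", k = ", k, ")")
  }
  delta <- colMeans(ao) - colMeans(ap)
  vo <- apply(ao, 2, var)
  vp <- apply(ap, 2, var)
  s2 <- switch(s2_mode,
               se = vo / nrow(ao) + vp / nrow(ap),
               pooled = ((nrow(ao) - 1) * vo + (nrow(ap) - 1) * vp) /
                        (nrow(ao) + nrow(ap) - 2))
  logL <- sum(-0.5 * log(2 * pi * s2) - delta^2 / (2 * s2))
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Argmin with ties broken toward parsimony (fewest free parameters),
# then lowest id. Exact-equality ties only.
select_min <- function(values, n_free, ids) {
  ok <- which(is.finite(values))
  if (length(ok) == 0) return(NA_integer_)
  m <- min(values[ok])
  tied <- ok[values[ok] == m]
  tied <- tied[order(n_free[tied], ids[tied])]
  ids[tied[1]]
}

#' Run entropy-based model selection on a scenario bundle
#'
#' For each candidate: estimate the free parameters by GMM against the
#' moments of the 20% estimation split, evolve the candidate pool to
#' time t under the estimate, fit the copula-KDE joint density, and
#' compute ACE on the 80% evaluation split plus the approximate AICc on
#' evaluation vs evolved-pool means. The candidate minimizing each
#' criterion is selected (ties toward fewer free parameters).
#'
#' @param bundle a [generate_scenario()] result (or hand-built bundle
#'   with the same fields).
#' @param candidates list of [candidate_model()]s.
#' @param moments moment blocks used as GMM targets.
#' @param weights_mode [gmm_weights()] mode.
#' @param n_starts,search_size,lower,upper GMM search settings
#'   (see [estimate_parameters()]).
#' @param cdf_clip copula-argument clipping (see [fit_joint_density()]).
#' @param seed master seed for estimation sub-draws; defaults to the
#'   bundle's simulation seed.
#' @param keep_densities keep the fitted [fit_joint_density()] objects
#'   in the report (larger object; off by default).
#' @param verbose print per-candidate progress.
#' @return an object of class `selection_report`.
#' @export
run_model_selection <- function(bundle, candidates = nk_candidate_models(),
                                moments = c("means", "variances",
                                            "covariances"),
                                weights_mode = "invvar",
                                n_starts = 8, search_size = 500L,
                                lower = 1e-8, upper = 1e2,
                                cdf_clip = 1e-6,
                                seed = bundle$config$seed,
                                keep_densities = FALSE,
                                verbose = FALSE) {
  est_data <- tss_subset(bundle$observed, bundle$estimation_split)
  eval_data <- tss_subset(bundle$observed, bundle$evaluation_split)
  target <- compute_moments(est_data, include = moments)
  weights <- gmm_weights(target, mode = weights_mode)
  tt <- bundle$observed$timestamp
  nc <- length(candidates)

  ids <- vapply(candidates, function(m) m$id, integer(1))
  n_free <- vapply(candidates, function(m) m$n_free, integer(1))
  ace <- aicc <- objective <- rep(NA_real_, nc)
  converged <- failed <- rep(FALSE, nc)
  fits <- densities <- vector("list", nc)
  pointwise <- matrix(NA_real_, nrow(eval_data$abundances), nc,
                      dimnames = list(NULL, paste0("CM", ids)))
  pool_stats <- pool_evolved <- vector("list", nc)

  for (i in seq_len(nc)) {
    model <- candidates[[i]]
    res <- tryCatch({
      if (verbose) message("candidate ", model$id, ": GMM estimation")
      fit <- estimate_parameters(model, bundle$candidate_pool, target,
                                 weights = weights, n_starts = n_starts,
                                 seed = derive_seed(seed,
                                                    paste0("fit-", model$id)),
                                 lower = lower, upper = upper,
                                 search_size = search_size)
      evolved <- evolve_cells(model$network, fit$rates,
                              bundle$candidate_pool$abundances, tt)
      evolved_ds <- tss_dataset(evolved, tt, model$network$species,
                                bundle$candidate_pool$cell_ids)
      dens <- fit_joint_density(evolved_ds, cdf_clip = cdf_clip)
      pw <- -joint_log_density(dens, eval_data$abundances)
      list(fit = fit, dens = dens, pw = pw, evolved = evolved,
           aicc = tryCatch(approximate_aicc(eval_data, evolved_ds,
                                            k = model$n_free),
                           error = function(e) NA_real_),
           stats = list(means = colMeans(evolved), vars = apply(evolved, 2, var),
                        n = nrow(evolved)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("candidate ", model$id, " failed and is excluded: ",
              conditionMessage(res), call. = FALSE)
      failed[i] <- TRUE
      next
    }
    fits[[i]] <- res$fit
    if (keep_densities) densities[[i]] <- res$dens
    pointwise[, i] <- res$pw
    ace[i] <- mean(res$pw)
    aicc[i] <- res$aicc
    objective[i] <- res$fit$objective_value
    converged[i] <- res$fit$converged
    if (verbose) {
      message("candidate ", model$id, ": ACE = ", signif(ace[i], 6),
              ", AICc = ", signif(aicc[i], 6))
    }
    pool_stats[[i]] <- res$stats
    pool_evolved[[i]] <- res$evolved
  }

  ord <- order(ace)
  gap <- if (sum(is.finite(ace)) >= 2) {
    so <- sort(ace[is.finite(ace)])
    unname(abs(so[1] - so[2]))
  } else NA_real_

  structure(list(
    candidate_ids = ids, n_free = n_free,
    ace = stats::setNames(ace, paste0("CM", ids)),
    aicc = stats::setNames(aicc, paste0("CM", ids)),
    gmm_objective = objective, converged = converged, failed = failed,
    selected_by_ace = select_min(ace, n_free, ids),
    selected_by_aicc = select_min(aicc, n_free, ids),
    ace_gap = gap,
    n_eval = nrow(eval_data$abundances),
    n_estimation = nrow(est_data$abundances),
    pointwise_nll = pointwise,
    pool_stats = pool_stats,
    pool_evolved = pool_evolved,
    target = target, weights = weights, cdf_clip = cdf_clip,
    fits = fits,
    densities = if (keep_densities) densities else NULL,
    truth_id = bundle$truth_id,
    scenario = bundle$config$scenario,
    seed = seed),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Entropy-based model selection",
      if (!is.null(x$scenario)) paste0("(scenario ", x$scenario, ")"), "\n")
  df <- data.frame(candidate = paste0("CM", x$candidate_ids),
                   n_free = x$n_free,
                   ACE = signif(x$ace, 6), AICc = signif(x$aicc, 5),
                   converged = x$converged,
                   row.names = NULL, check.names = FALSE)
  print(df)
  cat("Selected by ACE: CM", x$selected_by_ace,
      "; by AICc: CM", x$selected_by_aicc, "\n", sep = "")
  cat("ACE gap (|best - runner-up|):", signif(x$ace_gap, 4), "nats;",
      x$n_eval, "evaluation cells\n")
  invisible(x)
}

#' @export
summary.selection_report <- function(object, ...) {
  out <- data.frame(candidate = paste0("CM", object$candidate_ids),
                    n_free = object$n_free,
                    theta_tilde = vapply(object$fits, function(f) {
                      if (is.null(f)) return(NA_character_)
                      paste(signif(f$theta_tilde, 5), collapse = ", ")
                    }, character(1)),
                    gmm_objective = object$gmm_objective,
                    ACE = object$ace, AICc = object$aicc,
                    selected_ace = object$candidate_ids ==
                      object$selected_by_ace,
                    selected_aicc = object$candidate_ids ==
                      object$selected_by_aicc %|NA|% -1L,
                    row.names = NULL)
  class(out) <- c("summary.selection_report", class(out))
  out
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

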