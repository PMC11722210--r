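# Multivariate predictive density via Sklar's theorem: each protein's
# marginal is a Gaussian-kernel KDE on the log scale (abundances are
# positive and lognormal-like, so log-domain kernels avoid boundary
# bias at zero), and dependence is carried by a Gaussian copula fitted
# on rank pseudo-observations. The joint log-density is the copula
# log-density at the smoothed marginal cdf values plus the sum of
# marginal log-densities.

#' Fit a log-scale kernel marginal to one protein
#'
#' @param column strictly positive abundance vector (N >= 2).
#' @param name protein label.
#' @param bandwidth optional log-scale bandwidth; defaults to
#'   Silverman's rule `0.9 * min(sd, IQR/1.34) * N^(-1/5)` on the log
#'   abundances (the classic normal-reference rule).
#' @return an object of class `kde_marginal`.
#' @export
fit_marginal <- function(column, name = "", bandwidth = NULL) {
  if (length(column) < 2) stop_data("need at least 2 points for a marginal")
  if (any(!is.finite(column)) || any(column <= 0)) {
    stop_data("abundances must be finite and strictly positive (", name, ")")
  }
  lp <- log(column)
  if (is.null(bandwidth)) {
    spread <- min(sd(lp), stats::IQR(lp) / 1.34)
    if (spread <= 0) {
      stop_data("column '", name, "' has zero spread on the log scale; ",
                "a kernel bandwidth cannot be derived - supply `bandwidth` ",
                "explicitly or drop the degenerate protein")
    }
    bandwidth <- 0.9 * spread * length(lp)^(-1 / 5)
  }
  if (bandwidth <= 0) stop_data("bandwidth must be > 0")
  structure(list(log_points = lp, bandwidth = bandwidth,
                 protein_name = name, n = length(lp)),
            class = "kde_marginal")
}

#' @export
print.kde_marginal <- function(x, ...) {
  cat("KDE marginal '", x$protein_name, "': ", x$n,
      " log-points, bandwidth ", signif(x$bandwidth, 4), "\n", sep = "")
  invisible(x)
}

# log pdf per abundance unit: log-scale KDE minus the Jacobian log(y).
marginal_log_pdf <- function(model, y) {
  if (any(y <= 0)) stop_data("marginal densities are defined for y > 0")
  ev <- kde_eval_cpp(model$log_points, model$bandwidth, log(y))
  ev$log_pdf - log(y)
}

#' Marginal kernel density
#'
#' Gaussian-kernel KDE of the log abundance with the change-of-variables
#' Jacobian: `(1/(N b y)) * sum_j phi((ln y - p_j)/b)`. Integrates to 1
#' over (0, Inf).
#'
#' @param model a [fit_marginal()] result.
#' @param y strictly positive abundance(s).
#' @return density value(s) >= 0, per abundance unit.
#' @export
marginal_pdf <- function(model, y) exp(marginal_log_pdf(model, y))

#' Marginal kernel distribution function
#'
#' The KDE-smoothed cdf `(1/N) * sum_j Phi((ln y - p_j)/b)`, using the
#' same bandwidth as the pdf so the pair is consistent in Sklar's
#' formula.
#'
#' @inheritParams marginal_pdf
#' @return probability value(s) in (0, 1), nondecreasing in `y`.
#' @export
marginal_cdf <- function(model, y) {
  if (any(y <= 0)) stop_data("marginal cdf is defined for y > 0")
  kde_eval_cpp(model$log_points, model$bandwidth, log(y))$cdf
}

#' Fit a Gaussian copula on rank pseudo-observations
#'
#' Pseudo-observations `u = rank/(N+1)` per column are mapped to normal
#' scores `z = qnorm(u)`; the copula correlation is their sample
#' correlation matrix. If the smallest eigenvalue is not safely
#' positive the matrix is shrunk toward the identity with the smallest
#' ridge on a fixed grid that restores positive definiteness.
#'
#' @param data a [tss_dataset()] or abundance matrix with N >= 10 rows.
#' @return an object of class `gaussian_copula` with the correlation
#'   matrix `correlation` and cached Cholesky/log-determinant.
#' @export
fit_copula <- function(data) {
  a <- if (inherits(data, "tss_dataset")) data$abundances else as.matrix(data)
  N <- nrow(a)
  if (N < 10) stop_data("need at least 10 cells to fit a copula")
  z <- apply(a, 2, function(x) {
    n_tied <- N - length(unique(x))
    if (n_tied > 0.5 * N) {
      stop_data("more than half of a column is tied; ranks are degenerate")
    }
    qnorm(rank(x, ties.method = "average") / (N + 1))
  })
  R <- cor(z)
  lambda_grid <- c(0, 10^seq(-8, -1), 0.2, 0.5)
  for (lam in lambda_grid) {
    Rs <- (1 - lam) * R + lam * diag(ncol(R))
    ev <- min(eigen(Rs, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-10) { R <- Rs; break }
  }
  new_gaussian_copula(R)
}

#' Construct a Gaussian copula from a correlation matrix
#'
#' @param R symmetric positive-definite correlation matrix.
#' @return a `gaussian_copula` with cached Cholesky factor and
#'   log-determinant.
#' @export
new_gaussian_copula <- function(R) {
  R <- (R + t(R)) / 2
  diag(R) <- 1
  U <- chol(R)
  structure(list(correlation = R, chol = U,
                 log_det = 2 * sum(log(diag(U)))),
            class = "gaussian_copula")
}

#' @export
print.gaussian_copula <- function(x, ...) {
  cat("Gaussian copula on", ncol(x$correlation), "variables;",
      "max |off-diagonal| =",
      signif(max(abs(x$correlation[upper.tri(x$correlation)])), 4), "\n")
  invisible(x)
}

# Log copula density for a matrix of u rows (each in (0,1)^n).
copula_log_density <- function(copula, u) {
  u <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  if (any(u <= 0) || any(u >= 1)) {
    stop_data("copula arguments must lie strictly inside (0, 1)")
  }
  z <- qnorm(u)
  w <- backsolve(copula$chol, t(z), transpose = TRUE)  # solves U' w = z'
  quad <- colSums(w^2)
  -0.5 * copula$log_det - 0.5 * (quad - rowSums(z^2))
}

#' Gaussian copula density
#'
#' `|R|^(-1/2) * exp(-z' (R^-1 - I) z / 2)` with `z = qnorm(u)`.
#'
#' @param copula a [fit_copula()] result (or [new_gaussian_copula()]).
#' @param u vector in `(0,1)^n`, or a matrix of such rows.
#' @return density value(s) >= 0.
#' @export
copula_density <- function(copula, u) exp(copula_log_density(copula, u))

#' Fit the joint predictive density of an evolved snapshot
#'
#' Fits one [fit_marginal()] per protein and a [fit_copula()] on the
#' same sample, composing them through Sklar's theorem. This is the
#' candidate's estimated predictive density at the snapshot time.
#'
#' @param evolved a [tss_dataset()] (typically the candidate pool
#'   propagated to time t under the candidate's estimated rates).
#' @param cdf_clip epsilon used to clip marginal cdf values into
#'   `[eps, 1 - eps]` before the copula, keeping the log-density finite
#'   for evaluation points far in the tails.
#' @param bandwidth optional fixed log-scale bandwidth for all
#'   marginals (default: per-protein Silverman rule).
#' @return an object of class `joint_density`.
#' @export
fit_joint_density <- function(evolved, cdf_clip = 1e-6, bandwidth = NULL) {
  a <- if (inherits(evolved, "tss_dataset")) evolved$abundances
       else as.matrix(evolved)
  if (!(cdf_clip > 0 && cdf_clip < 0.5)) {
    stop_config("cdf_clip must lie in (0, 0.5)")
  }
  nm <- colnames(a)
  if (is.null(nm)) nm <- paste0("P", seq_len(ncol(a)))
  marginals <- lapply(seq_len(ncol(a)), function(k) {
    fit_marginal(a[, k], nm[k], bandwidth = bandwidth)
  })
  names(marginals) <- nm
  structure(list(marginals = marginals, copula = fit_copula(a),
                 cdf_clip = cdf_clip, protein_names = nm,
                 timestamp = if (inherits(evolved, "tss_dataset"))
                   evolved$timestamp else NA_real_,
                 n_fit = nrow(a)),
            class = "joint_density")
}

#' @export
print.joint_density <- function(x, ...) {
  cat("Joint density (Sklar: ", length(x$marginals),
      " KDE marginals + Gaussian copula), fitted on ", x$n_fit,
      " cells at t = ", x$timestamp, " s\n", sep = "")
  invisible(x)
}

#' Write / read a fitted joint density
#'
#' Serializes a [fit_joint_density()] model to a single self-describing
#' text file (header with protein names, bandwidths and clipping, the
#' copula correlation matrix, then the training log-abundances) at full
#' double precision, so a density fitted in one session can be reused
#' in another. `read_joint_density()` reverses it exactly.
#'
#' @param model a [fit_joint_density()] result.
#' @param path file path.
#' @return `path` (write) / the restored `joint_density` (read).
#' @export
write_joint_density <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(model$marginals)
  writeLines(c(
    "# tssACE joint density (Sklar: KDE marginals + Gaussian copula)",
    paste0("timestamp: ", sprintf("%.17g", model$timestamp)),
    paste0("cdf_clip: ", sprintf("%.17g", model$cdf_clip)),
    paste0("proteins: ", paste(model$protein_names, collapse = ",")),
    paste0("bandwidths: ",
           paste(sprintf("%.17g", vapply(model$marginals,
                                         function(m) m$bandwidth,
                                         numeric(1))), collapse = ",")),
    "correlation:"), con)
  writeLines(apply(model$copula$correlation, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  }), con)
  writeLines("log_points:", con)
  pts <- vapply(model$marginals, function(m) m$log_points,
                numeric(model$marginals[[1]]$n))
  writeLines(apply(pts, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  }), con)
  invisible(path)
}

#' @rdname write_joint_density
#' @export
read_joint_density <- function(path) {
  if (!file.exists(path)) stop_data("density file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  field <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    if (is.na(ln)) stop_data("density file lacks '", key, "' field")
    trimws(sub(paste0("^", key, ":"), "", ln))
  }
  proteins <- strsplit(field("proteins"), ",")[[1]]
  bw <- as.numeric(strsplit(field("bandwidths"), ",")[[1]])
  n <- length(proteins)
  ri <- grep("^correlation:", lines)[1]
  pi_ <- grep("^log_points:", lines)[1]
  R <- do.call(rbind, lapply(lines[(ri + 1):(ri + n)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  pts <- do.call(rbind, lapply(lines[(pi_ + 1):length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (ncol(pts) != n || ncol(R) != n) stop_data("inconsistent density file")
  marginals <- lapply(seq_len(n), function(k) {
    structure(list(log_points = pts[, k], bandwidth = bw[k],
                   protein_name = proteins[k], n = nrow(pts)),
              class = "kde_marginal")
  })
  names(marginals) <- proteins
  dimnames(R) <- list(proteins, proteins)
  structure(list(marginals = marginals, copula = new_gaussian_copula(R),
                 cdf_clip = as.numeric(field("cdf_clip")),
                 protein_names = proteins,
                 timestamp = as.numeric(field("timestamp")),
                 n_fit = nrow(pts)),
            class = "joint_density")
}

#' Joint log-density of abundance vectors
#'
#' Sklar composition: the Gaussian-copula log-density evaluated at the
#' clipped smoothed marginal cdf values, plus the sum of marginal
#' log-densities. Always finite, even far outside the training range
#' (kernel sums use log-sum-exp and cdf values are clipped).
#'
#' @param model a [fit_joint_density()] result.
#' @param y strictly positive abundance vector of length n, or an
#'   N x n matrix of such rows.
#' @return log-density value(s) in nats.
#' @export
joint_log_density <- function(model, y) {
  ym <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  n <- length(model$marginals)
  if (ncol(ym) != n) {
    stop_data("y has ", ncol(ym), " columns but the model has ", n,
              " marginals")
  }
  if (any(ym <= 0)) stop_data("abundances must be strictly positive")
  lp <- matrix(0, nrow(ym), n)
  u <- matrix(0, nrow(ym), n)
  eps <- model$cdf_clip
  for (k in seq_len(n)) {
    mk <- model$marginals[[k]]
    ev <- kde_eval_cpp(mk$log_points, mk$bandwidth, log(ym[, k]))
    lp[, k] <- ev$log_pdf - log(ym[, k])
    u[, k] <- pmin(pmax(ev$cdf, eps), 1 - eps)
  }
  out <- copula_log_density(model$copula, u) + rowSums(lp)
  if (!is.matrix(y)) out <- out[[1]]
  out
}
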