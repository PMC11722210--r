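test_that("marginal bandwidth follows Silverman's rule on the log scale", {
  # two points exp(1), exp(3): hand evaluation of the rule on logs {1, 3}
  m <- fit_marginal(c(exp(1), exp(3)))
  expected <- 0.9 * min(sd(c(1, 3)), stats::IQR(c(1, 3)) / 1.34) * 2^(-0.2)
  expect_equal(m$bandwidth, expected)
  # ... which is exactly the classic normal-reference rule
  expect_equal(m$bandwidth, stats::bw.nrd0(c(1, 3)))

  set.seed(2)
  x <- rlnorm(500, 2, 0.5)
  expect_equal(fit_marginal(x)$bandwidth, stats::bw.nrd0(log(x)))

  expect_error(fit_marginal(rep(3, 10)), "zero spread")
  expect_error(fit_marginal(c(1, -2, 3)), "positive")
  expect_error(fit_marginal(2), "at least 2")
})

test_that("marginal pdf is a Jacobian-corrected log-scale KDE", {
  # all points equal: peak value 1/(b * sqrt(2*pi) * e^p)
  p <- 1.3; b <- 0.4
  m <- fit_marginal(rep(exp(p), 5), bandwidth = b)
  expect_equal(marginal_pdf(m, exp(p)), 1 / (b * sqrt(2 * pi) * exp(p)))
  expect_equal(marginal_cdf(m, exp(p)), 0.5)

  # matches a direct R-level kernel sum at random query points
  set.seed(4)
  x <- rlnorm(200, 1, 0.7)
  m <- fit_marginal(x)
  q <- rlnorm(100, 1, 1)
  brute <- vapply(q, function(y) {
    mean(dnorm((log(y) - m$log_points) / m$bandwidth)) / (m$bandwidth * y)
  }, numeric(1))
  expect_equal(marginal_pdf(m, q), brute, tolerance = 1e-12)
  brute_cdf <- vapply(q, function(y) {
    mean(pnorm((log(y) - m$log_points) / m$bandwidth))
  }, numeric(1))
  expect_equal(marginal_cdf(m, q), brute_cdf, tolerance = 1e-12)

  # normalization and cdf/pdf consistency by quadrature
  expect_equal(stats::integrate(function(y) marginal_pdf(m, y), 0, Inf,
                                rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  y0 <- 3.7
  expect_equal(stats::integrate(function(y) marginal_pdf(m, y), 0, y0,
                                rel.tol = 1e-9)$value,
               marginal_cdf(m, y0), tolerance = 1e-6)
  # monotone cdf
  qs <- sort(q)
  expect_true(all(diff(marginal_cdf(m, qs)) >= 0))
  expect_error(marginal_pdf(m, -1), "y > 0")
})

test_that("the fitted marginal approaches the true lognormal density", {
  set.seed(12)
  m <- fit_marginal(rlnorm(5000, 0, 1))
  grid <- seq(0.1, 10, length.out = 400)
  expect_lt(max(abs(marginal_pdf(m, grid) - dlnorm(grid, 0, 1))), 0.05)
})

test_that("the rank-based Gaussian copula recovers dependence structure", {
  set.seed(31)
  n <- 5000
  ind <- cbind(rlnorm(n), rexp(n) + 0.01, rlnorm(n, 2, 0.3))
  cop <- fit_copula(ind)
  off <- cop$correlation[upper.tri(cop$correlation)]
  expect_lt(max(abs(off)), 4 / sqrt(n))

  # a strictly increasing transform is rank-identical: correlation -> 1
  x <- rlnorm(n)
  com <- fit_copula(cbind(x, exp(x)))
  expect_gt(com$correlation[1, 2], 0.99)

  R <- cop$correlation
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_gt(min(eigen(R, symmetric = TRUE)$values), 1e-10)

  expect_error(fit_copula(matrix(1:6, 3, 2)), "at least 10")
  expect_error(fit_copula(cbind(rep(1, 20), rnorm(20))), "tied")
})

test_that("Gaussian copula density matches its closed form", {
  I2 <- new_gaussian_copula(diag(2))
  set.seed(6)
  u <- matrix(runif(20), 10, 2)
  expect_equal(copula_density(I2, u), rep(1, 10))

  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  cop <- new_gaussian_copula(R)
  expect_equal(copula_density(cop, c(0.5, 0.5)), det(R)^(-0.5))
  # direct matrix evaluation at u = (0.5, Phi(1)) i.e. z = (0, 1)
  z <- c(0, 1)
  expected <- det(R)^(-0.5) *
    exp(-0.5 * drop(t(z) %*% (solve(R) - diag(2)) %*% z))
  expect_equal(copula_density(cop, c(0.5, pnorm(1))), expected,
               tolerance = 1e-12)
  expect_error(copula_density(cop, c(0, 0.5)), "inside")
  expect_error(copula_density(cop, c(0.3, 1)), "inside")
})

test_that("Sklar composition reduces to independence under an identity copula", {
  set.seed(8)
  a <- cbind(A = rlnorm(400, 1, 0.4), B = rlnorm(400, 2, 0.6))
  jd <- fit_joint_density(tss_dataset(a, 0))
  jd_ind <- jd
  jd_ind$copula <- new_gaussian_copula(diag(2))
  q <- cbind(rlnorm(50, 1, 0.4), rlnorm(50, 2, 0.6))
  sum_marg <-
    log(marginal_pdf(jd$marginals[[1]], q[, 1])) +
    log(marginal_pdf(jd$marginals[[2]], q[, 2]))
  expect_equal(joint_log_density(jd_ind, q), sum_marg, tolerance = 1e-12)

  # and for truly independent columns the fitted copula is near-identity
  med_gap <- stats::median(abs(joint_log_density(jd, q) - sum_marg))
  expect_lt(med_gap, 0.02)
})

test_that("joint log-density equals its independent composition", {
  set.seed(9)
  z <- matrix(rnorm(1000), 500, 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
  a <- exp(sweep(z, 2, c(1, 2), "+"))
  colnames(a) <- c("A", "B")
  jd <- fit_joint_density(tss_dataset(a, 0), cdf_clip = 1e-6)
  q <- exp(matrix(rnorm(60, c(1, 2), 1), 30, 2, byrow = TRUE))
  u <- cbind(pmin(pmax(marginal_cdf(jd$marginals[[1]], q[, 1]), 1e-6), 1 - 1e-6),
             pmin(pmax(marginal_cdf(jd$marginals[[2]], q[, 2]), 1e-6), 1 - 1e-6))
  composed <- log(copula_density(jd$copula, u)) +
    log(marginal_pdf(jd$marginals[[1]], q[, 1])) +
    log(marginal_pdf(jd$marginals[[2]], q[, 2]))
  expect_equal(joint_log_density(jd, q), composed, tolerance = 1e-12)

  # finite even absurdly far outside the training range
  far <- joint_log_density(jd, matrix(c(1e-9, 1e9), 1, 2))
  expect_true(is.finite(far))

  # fitting is deterministic
  jd2 <- fit_joint_density(tss_dataset(a, 0), cdf_clip = 1e-6)
  expect_identical(joint_log_density(jd, q), joint_log_density(jd2, q))
})

test_that("fitted joint density approximates an analytic bivariate lognormal", {
  set.seed(14)
  rho <- 0.6
  n <- 5000
  S <- matrix(c(1, rho, rho, 1), 2)
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(S)
  a <- exp(z)
  colnames(a) <- c("A", "B")
  jd <- fit_joint_density(tss_dataset(a, 0))
  # mode of the bivariate lognormal with mu = 0
  dln2 <- function(y) {
    q <- drop(t(log(y)) %*% solve(S) %*% log(y))
    exp(-q / 2) / (2 * pi * sqrt(det(S)) * prod(y))
  }
  # evaluate at a high-density point near the mode
  y0 <- c(exp(-0.5), exp(-0.5))
  expect_equal(joint_log_density(jd, y0), log(dln2(y0)), tolerance = 0.1)

  # column permutation equivariance
  jd_perm <- fit_joint_density(tss_dataset(a[, c(2, 1)], 0))
  q <- exp(matrix(rnorm(40), 20, 2))
  expect_equal(joint_log_density(jd_perm, q[, c(2, 1)]),
               joint_log_density(jd, q), tolerance = 1e-12)
})

test_that("the 2-D joint density integrates to one", {
  set.seed(15)
  a <- cbind(A = rlnorm(800, 0.5, 0.4), B = rlnorm(800, 1, 0.5))
  jd <- fit_joint_density(tss_dataset(a, 0))
  f <- function(x, y) exp(joint_log_density(jd, cbind(x, y)))
  gx <- exp(seq(log(0.05), log(30), length.out = 120))
  gy <- exp(seq(log(0.05), log(60), length.out = 120))
  vals <- outer(gx, gy, function(x, y) f(x, y))
  wx <- diff(gx); wy <- diff(gy)
  mid <- (vals[-1, -1] + vals[-nrow(vals), -ncol(vals)]) / 2
  total <- sum(outer(wx, wy) * mid)
  expect_equal(total, 1, tolerance = 0.02)
})

test_that("joint densities serialize to text and back exactly", {
  set.seed(77)
  a <- cbind(A = rlnorm(120, 1, 0.4), B = rlnorm(120, 2, 0.5),
             C = rlnorm(120, 0.5, 0.3))
  jd <- fit_joint_density(tss_dataset(a, 1.5), cdf_clip = 1e-5)
  path <- tempfile(fileext = ".txt")
  write_joint_density(jd, path)
  jd2 <- read_joint_density(path)
  expect_identical(jd2$protein_names, jd$protein_names)
  expect_equal(jd2$copula$correlation, jd$copula$correlation,
               tolerance = 1e-15)
  expect_equal(jd2$timestamp, 1.5)
  q <- cbind(rlnorm(40, 1, 0.5), rlnorm(40, 2, 0.5), rlnorm(40, 0.5, 0.4))
  expect_equal(joint_log_density(jd2, q), joint_log_density(jd, q),
               tolerance = 1e-14)
  expect_error(read_joint_density("no/such/file"), "not found")
})

test_that("copula-KDE density recovers a correlated multivariate lognormal", {
  # Gaussian-like marginals + Gaussian copula fitted to a large sample
  # should reproduce the analytic log-density at held-out points
  set.seed(88)
  n <- 6; N <- 10000
  S <- outer(1:n, 1:n, function(i, j) 0.4^abs(i - j)) * 0.2
  mu <- c(5.25, 7.6, 5.25, 7.6, 5.25, 5.25)
  L <- chol(S)
  z <- matrix(rnorm(N * n), N, n) %*% L
  a <- exp(sweep(z, 2, mu, "+"))
  colnames(a) <- paste0("P", 1:n)
  jd <- fit_joint_density(tss_dataset(a, 0))
  zh <- matrix(rnorm(1000 * n), 1000, n) %*% L
  held <- exp(sweep(zh, 2, mu, "+"))
  Sinv <- solve(S)
  ldet <- as.numeric(determinant(S)$modulus)
  analytic <- vapply(seq_len(1000), function(j) {
    d <- log(held[j, ]) - mu
    -0.5 * (n * log(2 * pi) + ldet) -
      0.5 * drop(t(d) %*% Sinv %*% d) - sum(log(held[j, ]))
  }, numeric(1))
  err <- abs(joint_log_density(jd, held) - analytic)
  # Silverman smoothing alone sets a dimension-free bias floor: each
  # Gaussian-like marginal is oversmoothed to sd sqrt(sigma^2 + b^2)
  # with b/sigma ~= 0.9 N^(-1/5), costing ~ (b/sigma)^2 / 2 nats, so
  # six marginals at N = 10000 give ~ 6 * 0.0101 = 0.061 nats median
  # error before the copula contributes anything
  expect_lt(stats::median(err), 0.08)
})
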