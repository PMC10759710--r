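test_that("profiled site rate matches closed forms, limits, and a grid-scan oracle", {
  # closed form at x = 0, z = 1: argmax of -lam + log(1 - e^{-2 lam p})
  for (p in c(0.01, 0.3, 1)) {
    expect_equal(solve_site_rate(0, 1, p), log1p(2 * p) / (2 * p),
                 tolerance = 1e-10)
  }
  expect_identical(solve_site_rate(0, 0, 0.2), 0)
  # tiny p: parity factor inert, Poisson MLE x
  expect_equal(solve_site_rate(5, 0, 1e-8), 5, tolerance = 1e-4)

  # grid-scan oracle: argmax of the per-site log-likelihood over lambda
  lam_grid <- seq(1e-4, 50, by = 1e-4)
  for (case in list(c(3, 1, 0.1), c(2, 0, 0.4), c(7, 1, 0.05))) {
    x <- case[1]; z <- case[2]; p <- case[3]
    parity_term <- if (z == 1) log(1 - exp(-2 * lam_grid * p)) else
      log(1 + exp(-2 * lam_grid * p))
    ll <- -lam_grid + x * log(lam_grid) + parity_term
    expect_equal(solve_site_rate(x, z, p), lam_grid[which.max(ll)],
                 tolerance = 2e-4)
  }

  # the returned rate satisfies the stationarity equation
  withr::with_seed(2, {
    x <- rpois(200, 4)
    z <- rbinom(200, 1, 0.4)
    for (p in c(0.02, 0.2, 0.9)) {
      lam <- solve_site_rate(x, z, p)
      s <- ifelse(z == 1, -1, 1)
      resid <- lam + 2 * p * lam / (s * exp(2 * lam * p) + 1) - x
      expect_lt(max(abs(resid[x > 0])), 1e-9)
    }
  })
  expect_error(solve_site_rate(1, 0, 0), class = "pc_contract_error")
})

test_that("joint MLE matches 2-D brute force on a single site and flags boundaries", {
  # all even parities: likelihood increases as p -> 0
  pr <- parity_problem(c(3, 1, 2), c(0, 0, 0))
  est <- fit_mle(pr)
  expect_true(est$boundary_hit)
  expect_equal(est$p_hat, grid_spec()$p_min)

  expect_error(fit_mle(parity_problem(c(0, 0), c(0, 0))),
               class = "pc_estimation_error")

  # 2-D brute-force maximisation of the joint log-likelihood
  p_grid <- seq(1e-3, 1, by = 1e-3)
  l_grid <- seq(1e-3, 8, by = 1e-3)
  ll <- outer(l_grid, p_grid, function(l, p)
    -l + 4 * log(l) + log(1 - exp(-2 * l * p)))
  best <- arrayInd(which.max(ll), dim(ll))
  est1 <- fit_mle(parity_problem(4, 1), grid_spec(1e-3, 1, 200))
  expect_equal(est1$p_hat, p_grid[best[2]], tolerance = 2e-3)
  expect_equal(as.numeric(est1$lambda_hat), l_grid[best[1]],
               tolerance = 2e-3)
})

test_that("joint MLE satisfies its stationarity system at an interior optimum", {
  pr <- make_problem(4000, lam = 2, p = 0.08, seed = 31)
  est <- fit_mle(pr)
  expect_false(est$boundary_hit)
  expect_true(est$converged)
  # sum(lambda_hat) == sum(X)
  expect_lt(abs(sum(est$lambda_hat) - sum(pr$counts)) / sum(pr$counts), 1e-3)
  # profile stationarity in p
  s <- ifelse(pr$parity == 1, -1, 1)
  lam <- as.numeric(est$lambda_hat)
  stat <- sum(lam / (s * exp(2 * lam * est$p_hat) + 1))
  scale <- sum(lam / (exp(2 * lam * est$p_hat) + 1))
  expect_lt(abs(stat) / scale, 1e-4)
  # and the estimate is in the right neighbourhood
  expect_lt(abs(est$p_hat - 0.08), 0.03)
})

test_that("conditional estimator solves the aggregated parity equation exactly", {
  # all even parities
  est0 <- fit_conditional(make_problem(50, 2, 0, seed = 1))
  expect_identical(est0$p_hat, 0)

  # closed form with all X = 1: p = sum(Z)/n
  pr1 <- parity_problem(rep(1, 100), rep(c(1, 0), c(10, 90)))
  expect_equal(fit_conditional(pr1)$p_hat, 0.1, tolerance = 1e-9)
  # all X = 2: (1-2p)^2 = (n - 2 sum(Z))/n
  pr2 <- parity_problem(rep(2, 100), rep(c(1, 0), c(18, 82)))
  expect_equal(fit_conditional(pr2)$p_hat, (1 - sqrt(0.64)) / 2,
               tolerance = 1e-9)

  # the equation's left side is non-increasing in p
  withr::with_seed(8, {
    x <- rpois(300, 2)
    ps <- seq(0, 0.49, length.out = 100)
    lhs <- vapply(ps, function(p) sum((1 - 2 * p)^x), numeric(1))
    expect_true(all(diff(lhs) <= 1e-12))
  })

  # no root below 1/2: parity count exceeds what X = 0 sites allow
  pr_sat <- parity_problem(c(0, 0, 0, 1), c(1, 1, 1, 1))
  expect_warning(est_sat <- fit_conditional(pr_sat),
                 class = "pc_boundary_warning")
  expect_true(est_sat$boundary_hit)
  expect_equal(est_sat$p_hat, 0.5 - 1e-9)
})

test_that("negative-binomial prior fitting recovers generating hyperparameters", {
  withr::with_seed(12, {
    counts <- rnbinom(15629, size = 0.23, mu = 0.23 / 0.164)
    prior <- fit_nb_prior(counts)
    expect_equal(attr(prior, "fit_method"), "ml")
    expect_lt(abs(prior$alpha - 0.23) / 0.23, 0.15)
    expect_lt(abs(prior$beta - 0.164) / 0.164, 0.15)
  })

  # Poisson counts (alpha -> infinity limit): the mixture mean is identified
  withr::with_seed(13, {
    counts <- rpois(10000, 2)
    prior <- suppressWarnings(fit_nb_prior(counts))
    expect_lt(abs(prior$alpha / prior$beta - 2) / 2, 0.05)
  })

  # underdispersion triggers the near-degenerate fallback
  expect_warning(prior_u <- fit_nb_prior(rep(3L, 100)),
                 class = "pc_dispersion_warning")
  expect_equal(attr(prior_u, "fit_method"), "moments_underdispersed")
  expect_equal(prior_u$alpha / prior_u$beta, 3)
  expect_gte(prior_u$beta, 1e6)

  expect_error(fit_nb_prior(3), class = "pc_contract_error")
})

test_that("Gamma-prior MAP matches a fine grid search and its stationarity equation", {
  prior <- gamma_prior(0.23, 0.164)

  # all even parities: every term is maximised at p = 0
  est0 <- fit_gamma_map(make_problem(50, 2, 0, seed = 3), prior)
  expect_identical(est0$p_hat, 0)
  expect_true(est0$boundary_hit)

  # 1-D grid oracle on a tiny problem with an interior posterior mode
  x_tiny <- c(rep(3, 8), 2)
  z_tiny <- c(rep(0, 8), 1)
  pr <- parity_problem(x_tiny, z_tiny)
  pg <- seq(1e-6, 20, by = 1e-3)
  obj <- function(p) {
    t <- 1 + 2 * p / (prior$beta + 1)
    sum(log1p((-1)^z_tiny * t^(-(x_tiny + prior$alpha))))
  }
  vals <- vapply(pg, obj, numeric(1))
  est <- fit_gamma_map(pr, prior)
  expect_lt(abs(est$p_hat - pg[which.max(vals)]), 1.5e-3)  # one grid step
  expect_lt(abs(est$diagnostics$stationarity_residual), 1e-6)
  expect_true(est$converged)
  expect_false(est$boundary_hit)

  # when the data admit no interior mode, the boundary is flagged
  est_b <- fit_gamma_map(parity_problem(c(3, 0), c(0, 1)), prior)
  expect_true(est_b$boundary_hit)
  expect_equal(est_b$p_hat, 20, tolerance = 1e-4)

  # parameter-recovery sanity at phylotree scale
  rates <- sample_rates(rate_dist_gamma(), 15629, seed = 21)
  prm <- simulate_counts(rates, 0.1, seed = 22)
  estr <- fit_gamma_map(prm, fit_nb_prior(prm$counts))
  expect_lt(abs(estr$p_hat - 0.1), 0.03)
})

test_that("estimators concur on a large easy instance, up to the joint MLE's known bias", {
  # High equal rates, moderate p: the conditional and MAP estimators find
  # the same answer. The joint MLE profiles out one rate per site
  # (incidental parameters), which leaves it with a small upward bias
  # that does not vanish with n; it sits a few percent above the others,
  # consistent with its highest-squared-error ranking.
  rel_23 <- rep(NA_real_, 20)
  rel_1 <- rep(NA_real_, 20)
  withr::with_seed(77, {
    for (i in 1:20) {
      pr <- simulate_counts(site_rates(rep(2, 15629)), 0.05)
      p1 <- fit_mle(pr)$p_hat
      p2 <- fit_conditional(pr)$p_hat
      p3 <- fit_gamma_map(pr, suppressWarnings(fit_nb_prior(pr$counts)))$p_hat
      rel_23[i] <- abs(p2 - p3) / p2
      rel_1[i] <- (p1 - p2) / p2
    }
  })
  expect_lt(mean(rel_23), 0.02)
  expect_gt(mean(rel_1), 0)      # the MLE offset is upward...
  expect_lt(mean(rel_1), 0.10)   # ...and stays within a few percent
})
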