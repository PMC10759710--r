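test_that("parity probability matches its closed form and limits", {
  expect_identical(parity_prob(0), 0)          # a zero-rate site is always even
  expect_equal(parity_prob(log(2) / 2), 0.25)
  expect_equal(parity_prob(50), 0.5, tolerance = 1e-12)

  # strictly increasing and bounded above by 1/2 (within the range where
  # doubles can still resolve the gap to 1/2)
  grid <- seq(0, 10, length.out = 2000)
  pp <- parity_prob(grid)
  expect_true(all(diff(pp) > 0))
  expect_true(all(pp < 0.5))

  expect_error(parity_prob(-0.1), class = "pc_contract_error")
  expect_error(parity_prob(NaN), class = "pc_contract_error")
  expect_error(parity_prob(Inf), class = "pc_contract_error")
})

test_that("log-likelihood matches direct substitution and the product-form oracle", {
  pr0 <- parity_problem(0, 0)
  expect_equal(log_likelihood(pr0, model_params(0, 1)), -1 + log(2))
  # parity 1 is impossible at distance 0
  pr1 <- parity_problem(0, 1)
  expect_identical(log_likelihood(pr1, model_params(0, 1)), -Inf)
  # zero rate with a positive count has zero likelihood
  expect_identical(
    log_likelihood(parity_problem(2, 0), model_params(0.3, 0)), -Inf)

  # product-form oracle (explicit Poisson pmf x Bernoulli parity pmf),
  # compared after restoring the omitted constants
  x <- c(2, 1); z <- c(0, 1); lam <- c(2, 1); p <- 0.3
  ll <- log_likelihood(parity_problem(x, z), model_params(p, lam))
  ll_full <- ll - sum(lfactorial(x)) - length(x) * log(2)
  expect_equal(ll_full, log(oracle_likelihood(x, z, lam, p)),
               tolerance = 1e-12)

  expect_error(
    log_likelihood(parity_problem(c(1, 2), c(0, 0)), model_params(0.1, 1)),
    class = "pc_contract_error")
})

test_that("summing the parity factor over Z recovers the pure Poisson likelihood", {
  # conservation of probability over Z, site by site, random cases
  withr::with_seed(11, {
    for (rep in 1:20) {
      x <- rpois(1, 3)
      lam <- runif(1, 0.05, 5)
      p <- runif(1, 0.01, 2)
      pr <- parity_problem(x, 0)
      ll0 <- log_likelihood(pr, model_params(p, lam))
      ll1 <- log_likelihood(parity_problem(x, 1), model_params(p, lam))
      # site terms carry a spare factor 2 from the dropped 1/2 constant
      expect_equal(exp(ll0) + exp(ll1), 2 * dpois(x, lam) * exp(lfactorial(x)),
                   tolerance = 1e-10)
    }
  })
})

test_that("type constructors enforce their invariants", {
  expect_error(site_rates(numeric()), class = "pc_contract_error")
  expect_error(site_rates(c(1, -1)), class = "pc_contract_error")
  expect_error(site_rates(c(1, Inf)), class = "pc_contract_error")
  expect_error(parity_problem(c(1, 2), c(0, 2)), class = "pc_contract_error")
  expect_error(parity_problem(-1, 0), class = "pc_contract_error")
  expect_error(parity_problem(1.5, 0), class = "pc_contract_error")
  expect_error(model_params(-0.1, 1), class = "pc_contract_error")
  expect_error(gamma_prior(0, 1), class = "pc_contract_error")
  expect_error(grid_spec(p_min = 0.5, p_max = 0.1),
               class = "pc_contract_error")
  expect_silent(pr <- parity_problem(c(0, 3), c(0, 1), site_index = c(10, 20)))
  expect_identical(pr$site_index, c(10L, 20L))
})
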