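# Raw-scheme simulation: draw site rates from a Categorical or Gamma
# distribution mimicking mtDNA transition-rate heterogeneity, then draw
# (X, Z) directly from the Poisson-parity model. The sequence-level
# scheme (K2P/TN93) lives in seq_sim.R.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Site-rate distributions
#'
#' Two families mimic the substitution-rate heterogeneity seen in human
#' mtDNA: a two-point Categorical distribution (a low rate \eqn{\epsilon}
#' for cold sites with probability \eqn{\eta}, a high rate `a` otherwise)
#' and a Gamma distribution. The defaults are the mtDNA-calibrated values
#' \eqn{\epsilon = 0.1, \eta = 0.11, a = 11.87} and
#' \eqn{\Gamma(\alpha = 0.23, \beta = 0.164)} (rate convention, mean
#' \eqn{\alpha/\beta \approx 1.40}).
#'
#' @param epsilon,a the two categorical rate values (> 0).
#' @param eta probability of the `epsilon` value, in `[0, 1]`.
#' @return an object of class `rate_distribution`.
#' @examples
#' sample_rates(rate_dist_gamma(), n = 5, seed = 1)
#' @export
rate_dist_categorical <- function(epsilon = 0.1, a = 11.87, eta = 0.11) {
  if (!all(is.finite(c(epsilon, a, eta))) || epsilon <= 0 || a <= 0 ||
      eta < 0 || eta > 1) {
    pc_contract_error("invalid categorical rate distribution parameters")
  }
  structure(list(kind = "categorical", epsilon = epsilon, a = a, eta = eta),
            class = "rate_distribution")
}

#' @rdname rate_dist_categorical
#' @param shape,rate Gamma shape \eqn{\alpha} and rate \eqn{\beta} (> 0).
#' @export
rate_dist_gamma <- function(shape = 0.23, rate = 0.164) {
  if (!all(is.finite(c(shape, rate))) || shape <= 0 || rate <= 0) {
    pc_contract_error("invalid gamma rate distribution parameters")
  }
  structure(list(kind = "gamma", shape = shape, rate = rate),
            class = "rate_distribution")
}

#' @export
print.rate_distribution <- function(x, ...) {
  if (x$kind == "categorical") {
    cat(sprintf("<rate_distribution> categorical: %g w.p. %g, %g w.p. %g\n",
                x$epsilon, x$eta, x$a, 1 - x$eta))
  } else {
    cat(sprintf("<rate_distribution> gamma(shape %g, rate %g)\n",
                x$shape, x$rate))
  }
  invisible(x)
}

#' Draw i.i.d. site rates
#'
#' @param dist a [rate_dist_categorical()] or [rate_dist_gamma()].
#' @param n number of sites (>= 1).
#' @param seed optional integer seed; when given, the ambient RNG state is
#'   untouched and the draw is reproducible.
#' @return a [site_rates] vector of length `n`.
#' @export
sample_rates <- function(dist, n, seed = NULL) {
  if (!inherits(dist, "rate_distribution")) {
    pc_contract_error("dist must be a rate_distribution")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) pc_contract_error("n must be >= 1")
  r <- with_seed_if(seed, {
    if (dist$kind == "categorical") {
      sample(c(dist$epsilon, dist$a), n, replace = TRUE,
             prob = c(dist$eta, 1 - dist$eta))
    } else {
      stats::rgamma(n, shape = dist$shape, rate = dist$rate)
    }
  })
  site_rates(r)
}

#' Simulate (X, Z) from the Poisson-parity model
#'
#' \eqn{X_i \sim \mathrm{Pois}(\lambda_i)} (phylogeny-wide counts),
#' latent \eqn{Y_i \sim \mathrm{Pois}(\lambda_i p)} (pair counts), and
#' \eqn{Z_i = Y_i \bmod 2}. Only \eqn{(X, Z)} are returned; the latent
#' counts are discarded, as in the observation model.
#'
#' @param rates a [site_rates] vector.
#' @param p scaled distance (>= 0).
#' @param seed optional integer seed.
#' @return a [parity_problem].
#' @export
simulate_counts <- function(rates, p, seed = NULL) {
  rates <- as_rates(rates)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0) {
    pc_contract_error("p must be a single finite non-negative number")
  }
  n <- length(rates)
  with_seed_if(seed, {
    x <- stats::rpois(n, as.numeric(rates))
    y <- stats::rpois(n, as.numeric(rates) * p)
    parity_problem(x, y %% 2, site_index = seq_len(n))
  })
}

ks_statistic <- function(a, b) {
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Impute a rate for zero-count sites by Kolmogorov-Smirnov fitting
#'
#' Taking the observed phylogeny count as the rate estimate at each site
#' undercounts activity at sites that happen to show zero transitions
#' (roughly two thirds of human mtDNA sites). Those sites are assigned a
#' common small rate \eqn{\epsilon}, chosen so that counts simulated from
#' the resulting rate vector match the observed count distribution: for
#' each candidate \eqn{\epsilon} the rate vector (zero-count sites
#' \eqn{\leftarrow \epsilon}, others \eqn{\leftarrow} their observed
#' count) is used to simulate Poisson count vectors, and the candidate
#' minimising the two-sample Kolmogorov-Smirnov statistic against the
#' observed counts wins. Every candidate is evaluated under the same seed,
#' so the search is deterministic and exhaustive over the grid.
#'
#' @param observed_counts non-negative integer vector of per-site counts.
#' @param candidate_grid candidate \eqn{\epsilon} values; default 50
#'   log-spaced values on `[1e-3, 1]`.
#' @param seed integer seed shared across candidates.
#' @param n_sim simulated count vectors per candidate (concatenated before
#'   the KS comparison).
#' @return the winning \eqn{\epsilon}, with attributes `ks_table` (a
#'   data.frame of candidate/statistic) and `noop` (`TRUE` when the input
#'   had no zero-count sites, in which case the first candidate is
#'   returned untouched).
#' @export
fit_epsilon_ks <- function(observed_counts,
                           candidate_grid = exp(seq(log(1e-3), log(1),
                                                    length.out = 50)),
                           seed = 1L, n_sim = 3L) {
  observed_counts <- as.numeric(observed_counts)
  if (length(observed_counts) < 1L || any(observed_counts < 0) ||
      any(observed_counts != round(observed_counts))) {
    pc_contract_error("observed_counts must be non-negative integers")
  }
  if (length(candidate_grid) < 1L || any(!is.finite(candidate_grid)) ||
      any(candidate_grid <= 0)) {
    pc_contract_error("candidate_grid must be non-empty and positive")
  }
  zero <- observed_counts == 0
  if (!any(zero)) {
    out <- candidate_grid[1]
    attr(out, "noop") <- TRUE
    return(out)
  }
  stats_out <- vapply(candidate_grid, function(eps) {
    lam <- observed_counts
    lam[zero] <- eps
    sim <- with_seed_if(seed,
      stats::rpois(length(lam) * n_sim, rep(lam, n_sim)))
    ks_statistic(sim, observed_counts)
  }, numeric(1))
  best <- which.min(stats_out)
  out <- candidate_grid[best]
  attr(out, "ks_table") <- data.frame(epsilon = candidate_grid,
                                      ks = stats_out)
  attr(out, "noop") <- FALSE
  out
}
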