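#' Per-site Poisson transition rates
#'
#' A lightweight container for the vector of per-site transition rates
#' \eqn{\lambda_i}, in units of expected transitions per site per unit of
#' total phylogeny edge length (the tree's edges are normalised to sum to
#' one, so a rate of 1.4 means 1.4 expected transitions at that site over
#' the whole tree).
#'
#' Zero rates are permitted: they arise naturally from real count tables
#' where a site shows no transitions anywhere in the phylogeny.
#'
#' @param rates numeric vector, non-negative and finite, length >= 1.
#' @return an object of class `site_rates` (a classed numeric vector).
#' @examples
#' site_rates(c(0.1, 2, 0))
#' @export
site_rates <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) < 1L) {
    pc_contract_error("site_rates must have length >= 1")
  }
  if (anyNA(rates) || any(!is.finite(rates))) {
    pc_contract_error("site_rates must be finite and non-missing")
  }
  if (any(rates < 0)) {
    pc_contract_error("site_rates must be non-negative")
  }
  structure(rates, class = "site_rates")
}

as_rates <- function(rates) {
  if (inherits(rates, "site_rates")) return(rates)
  site_rates(rates)
}

#' @export
print.site_rates <- function(x, ...) {
  cat(sprintf("<site_rates> n = %d, mean = %.4g, range = [%.4g, %.4g]\n",
              length(x), mean(x), min(x), max(x)))
  invisible(x)
}

#' Paired parity observations
#'
#' The two observation vectors of the parity model: per-site transition
#' counts `counts` (\eqn{X_i}) extracted from the phylogeny, and the
#' per-site parity `parity` (\eqn{Z_i \in \{0,1\}}) of the latent number of
#' transitions between the two target sequences. The latent counts
#' themselves are never stored.
#'
#' @param counts non-negative integer vector.
#' @param parity vector of 0/1, same length as `counts`.
#' @param site_index optional 1-based original site coordinates (kept
#'   through transversion masking so estimates can be traced back to
#'   rCRS-style positions).
#' @return an object of class `parity_problem`.
#' @examples
#' parity_problem(counts = c(2, 0, 1), parity = c(0, 1, 0))
#' @export
parity_problem <- function(counts, parity, site_index = NULL) {
  counts <- as.numeric(counts)
  parity <- as.numeric(parity)
  if (length(counts) != length(parity)) {
    pc_contract_error(sprintf(
      "counts (%d) and parity (%d) must have equal length",
      length(counts), length(parity)))
  }
  if (length(counts) < 1L) {
    pc_contract_error("parity_problem must contain at least one site")
  }
  if (anyNA(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    pc_contract_error("counts must be non-negative integers")
  }
  if (anyNA(parity) || !all(parity %in% c(0, 1))) {
    pc_contract_error("parity entries must be 0 or 1")
  }
  if (!is.null(site_index)) {
    site_index <- as.integer(site_index)
    if (length(site_index) != length(counts) || anyNA(site_index) ||
        any(site_index < 1L)) {
      pc_contract_error("site_index must be 1-based and match counts length")
    }
  }
  structure(
    list(counts = as.integer(counts), parity = as.integer(parity),
         site_index = site_index),
    class = "parity_problem"
  )
}

#' @export
print.parity_problem <- function(x, ...) {
  cat(sprintf(
    "<parity_problem> n = %d sites, sum(X) = %d, sum(Z) = %d\n",
    length(x$counts), sum(x$counts), sum(x$parity)))
  invisible(x)
}

#' Model parameters (p, lambda)
#'
#' @param p non-negative scaled distance, a fraction of the total phylogeny
#'   edge length.
#' @param rates a [site_rates] vector (or plain numeric coerced to one).
#' @return an object of class `model_params`.
#' @export
model_params <- function(p, rates) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0) {
    pc_contract_error("p must be a single finite non-negative number")
  }
  structure(list(p = as.numeric(p), rates = as_rates(rates)),
            class = "model_params")
}

#' Gamma prior on site rates
#'
#' Shape/rate parameterisation: \eqn{\lambda_i \sim \Gamma(\alpha, \beta)}
#' with prior mean \eqn{\alpha/\beta}. Marginally the phylogeny counts are
#' then Negative-Binomial with size \eqn{\alpha} and success probability
#' \eqn{\beta/(\beta+1)}.
#'
#' @param alpha positive shape.
#' @param beta positive rate.
#' @return an object of class `gamma_prior`.
#' @examples
#' gamma_prior(0.23, 0.164)
#' @export
gamma_prior <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    pc_contract_error("alpha must be a single positive number")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    pc_contract_error("beta must be a single positive number")
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("<gamma_prior> alpha = %.4g, beta = %.4g (mean %.4g)\n",
              x$alpha, x$beta, x$alpha / x$beta))
  invisible(x)
}

#' Search grid for the profile-likelihood estimator
#'
#' Defaults follow the observed range of real scaled distances (roughly
#' 0.008 for human-Neanderthal up to ~0.12 for human-chimpanzee): 200
#' log-spaced points on \[1e-4, 1\], refined locally after the sweep.
#'
#' @param p_min,p_max positive grid limits, `p_min < p_max`.
#' @param n_points number of grid points (>= 2).
#' @param scale `"log"` or `"linear"` spacing.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(p_min = 1e-4, p_max = 1, n_points = 200L,
                      scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!is.numeric(p_min) || !is.numeric(p_max) || p_min <= 0 ||
      p_max <= p_min) {
    pc_contract_error("require 0 < p_min < p_max")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    pc_contract_error("n_points must be >= 2")
  }
  structure(list(p_min = p_min, p_max = p_max, n_points = n_points,
                 scale = scale),
            class = "grid_spec")
}

grid_points <- function(grid) {
  if (grid$scale == "log") {
    exp(seq(log(grid$p_min), log(grid$p_max), length.out = grid$n_points))
  } else {
    seq(grid$p_min, grid$p_max, length.out = grid$n_points)
  }
}

#' Calibration constants mapping scaled distance to years
#'
#' `p` is a fraction of the total phylogeny edge length; the edge length in
#' years is `mean_subs_per_site / mu`. Defaults are the coding-region
#' per-site per-year substitution rate 1.57e-8 and a phylogeny-wide mean of
#' 1.4 substitutions per site.
#'
#' @param mu per-site per-year substitution rate (> 0).
#' @param mean_subs_per_site mean substitutions per site over the whole
#'   phylogeny (> 0).
#' @param sample_age_1,sample_age_2 ages of the two samples in years before
#'   present (>= 0); 0 for modern sequences.
#' @return an object of class `calibration_config`.
#' @examples
#' calibration_config()  # defaults: 1.4 / 1.57e-8 years of total edge length
#' @export
calibration_config <- function(mu = 1.57e-8, mean_subs_per_site = 1.4,
                               sample_age_1 = 0, sample_age_2 = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    pc_contract_error("mu must be a single positive number")
  }
  if (!is.numeric(mean_subs_per_site) || length(mean_subs_per_site) != 1L ||
      !is.finite(mean_subs_per_site) || mean_subs_per_site <= 0) {
    pc_contract_error("mean_subs_per_site must be a single positive number")
  }
  if (any(c(sample_age_1, sample_age_2) < 0)) {
    pc_contract_error("sample ages must be >= 0 years before present")
  }
  structure(list(mu = mu, mean_subs_per_site = mean_subs_per_site,
                 sample_age_1 = sample_age_1, sample_age_2 = sample_age_2),
            class = "calibration_config")
}

new_distance_estimate <- function(p_hat, method, converged, objective,
                                  lambda_hat = NULL, boundary_hit = FALSE,
                                  diagnostics = list()) {
  structure(
    list(p_hat = p_hat, method = method, converged = converged,
         objective = objective, lambda_hat = lambda_hat,
         boundary_hit = boundary_hit, diagnostics = diagnostics),
    class = "distance_estimate"
  )
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf(
    "<distance_estimate> method = %s, p_hat = %.6g%s%s\n",
    x$method, x$p_hat,
    if (x$boundary_hit) " [boundary]" else "",
    if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
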