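# Core probabilistic model: distribution of the parity of a Poisson count
# and the joint (log-)likelihood of (p, lambda) given (X, Z).

# log(1 - exp(-t)) for t >= 0, switching forms at log(2) for accuracy.
# Exactly -Inf at t = 0; finite (~log t) for any representable t > 0, which
# keeps optimizers away from artificial plateaus near the Z = 1 singularity.
log1mexp <- function(t) {
  out <- numeric(length(t))
  small <- t <= log(2)
  out[small] <- log(-expm1(-t[small]))
  out[!small] <- log1p(-exp(-t[!small]))
  out
}

#' Probability that a Poisson count is odd
#'
#' If \eqn{Y \sim \mathrm{Pois}(\Lambda)} and \eqn{Z} is the parity of
#' \eqn{Y}, then \eqn{Z \sim \mathrm{Ber}\big(\tfrac12(1 - e^{-2\Lambda})\big)}.
#' This is the per-site observation model: between two sequences the
#' expected number of transitions at a site is \eqn{\Lambda = \lambda_i p},
#' and only the parity (agree/disagree) is observable.
#'
#' The function is strictly increasing in \eqn{\Lambda} and saturates at
#' 1/2: once many transitions are expected, the site carries no distance
#' signal.
#'
#' @param lam_times_p non-negative finite numeric vector \eqn{\Lambda}.
#' @return probabilities in `[0, 0.5)` (0.5 only in the limit).
#' @examples
#' parity_prob(0)            # 0: a zero-rate site is always even
#' parity_prob(log(2) / 2)   # 0.25
#' @export
parity_prob <- function(lam_times_p) {
  if (!is.numeric(lam_times_p) || length(lam_times_p) < 1L) {
    pc_contract_error("lam_times_p must be numeric")
  }
  if (anyNA(lam_times_p) || any(!is.finite(lam_times_p)) ||
      any(lam_times_p < 0)) {
    pc_contract_error("lam_times_p must be finite and non-negative")
  }
  0.5 * (-expm1(-2 * lam_times_p))
}

# Per-site log-likelihood terms: -lambda + x log(lambda) +
# log(1 + (-1)^z e^{-2 lambda p}), with 0*log(0) := 0. Vectorised over
# sites; scalar p.
site_loglik <- function(x, z, lam, p) {
  pois <- -lam
  pos <- x > 0
  pois[pos] <- pois[pos] + x[pos] * log(lam[pos])  # log(0) -> -Inf if lam=0
  t <- 2 * lam * p
  par <- numeric(length(x))
  odd <- z == 1
  par[odd] <- log1mexp(t[odd])
  par[!odd] <- log1p(exp(-t[!odd]))
  pois + par
}

#' Joint log-likelihood of (p, lambda) given (X, Z)
#'
#' Computes
#' \deqn{\ell(p, \lambda) = \sum_i \big[-\lambda_i + X_i \log \lambda_i +
#'   \log(1 + (-1)^{Z_i} e^{-2 \lambda_i p})\big],}
#' i.e. the joint log-likelihood of the per-site Poisson counts and parities
#' up to additive constants that do not involve \eqn{(p, \lambda)}: the
#' \eqn{-\sum_i \log X_i!} term and the \eqn{-n \log 2} from the parity
#' Bernoulli factor are both omitted. Rankings and maximisers over
#' \eqn{(p, \lambda)} at fixed data are unaffected.
#'
#' Returns `-Inf` for zero-likelihood configurations: any site with
#' \eqn{\lambda_i = 0} but \eqn{X_i > 0}, or \eqn{\lambda_i p = 0} with
#' \eqn{Z_i = 1} (parity 1 is impossible at distance 0). Sites with
#' \eqn{\lambda_i = 0, X_i = 0, Z_i = 0} are valid and contribute
#' \eqn{\log 2}.
#'
#' @param problem a [parity_problem].
#' @param params a [model_params].
#' @return scalar log-likelihood (possibly `-Inf`).
#' @examples
#' pr <- parity_problem(counts = c(2, 1), parity = c(0, 1))
#' log_likelihood(pr, model_params(0.3, c(2, 1)))
#' @export
log_likelihood <- function(problem, params) {
  if (!inherits(problem, "parity_problem")) {
    pc_contract_error("problem must be a parity_problem")
  }
  if (!inherits(params, "model_params")) {
    pc_contract_error("params must be a model_params")
  }
  lam <- as.numeric(params$rates)
  if (length(lam) != length(problem$counts)) {
    pc_contract_error(sprintf(
      "rates length (%d) must match number of sites (%d)",
      length(lam), length(problem$counts)))
  }
  sum(site_loglik(problem$counts, problem$parity, lam, params$p))
}
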