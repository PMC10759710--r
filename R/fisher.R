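# Fisher information and the Cramer-Rao lower bound for the scaled
# distance p in the Poisson-parity model.

#' Fisher information blocks for (lambda, p)
#'
#' The information matrix of the \eqn{(n+1)}-parameter problem is sparse:
#' the \eqn{\lambda}-block is diagonal,
#' \deqn{I_{i,i} = \frac{1}{\lambda_i} + \frac{4p^2}{e^{4\lambda_i p} - 1},
#'   \qquad I_{i,p} = \frac{4 p \lambda_i}{e^{4\lambda_i p} - 1}, \qquad
#'   I_{p,p} = 4 \sum_i \frac{\lambda_i^2}{e^{4\lambda_i p} - 1}.}
#' The exponential terms are evaluated with `expm1` so small
#' \eqn{\lambda_i p} does not lose precision.
#'
#' @param rates [site_rates] with strictly positive entries (a zero rate
#'   makes \eqn{1/\lambda_i} undefined).
#' @param p positive scaled distance.
#' @return an object of class `fisher_blocks`: list with `diag_lambda`,
#'   `cross`, `info_pp`, `n`. Use [as.matrix()] to assemble the dense
#'   \eqn{(n+1)\times(n+1)} matrix.
#' @seealso [crb_p()]
#' @export
fisher_information <- function(rates, p) {
  rates <- as_rates(rates)
  lam <- as.numeric(rates)
  if (any(lam == 0)) {
    pc_contract_error("fisher_information requires all rates > 0")
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0) {
    pc_contract_error("p must be a single positive number")
  }
  denom <- expm1(4 * lam * p)
  structure(
    list(diag_lambda = 1 / lam + 4 * p^2 / denom,
         cross = 4 * p * lam / denom,
         info_pp = 4 * sum(lam^2 / denom),
         n = length(lam)),
    class = "fisher_blocks"
  )
}

#' @method as.matrix fisher_blocks
#' @export
as.matrix.fisher_blocks <- function(x, ...) {
  n <- x$n
  m <- matrix(0, n + 1L, n + 1L)
  diag(m)[seq_len(n)] <- x$diag_lambda
  m[seq_len(n), n + 1L] <- x$cross
  m[n + 1L, seq_len(n)] <- x$cross
  m[n + 1L, n + 1L] <- x$info_pp
  m
}

#' @export
print.fisher_blocks <- function(x, ...) {
  cat(sprintf("<fisher_blocks> n = %d, I_pp = %.6g\n", x$n, x$info_pp))
  invisible(x)
}

#' Cramer-Rao lower bound on the variance of an unbiased estimator of p
#'
#' The Schur complement of the \eqn{\lambda}-block gives
#' \deqn{\mathrm{Var}(\hat p) \ge \Big[\,4 \sum_i
#'   \frac{\lambda_i^2}{e^{4\lambda_i p} - 1 + 4 p^2 \lambda_i}\Big]^{-1}.}
#' For equal rates \eqn{\lambda_i = \lambda} this reduces to
#' \eqn{(e^{4\lambda p} - 1 + 4 p^2 \lambda)/(4 n \lambda^2)}. The bound
#' grows with \eqn{p}: as parity saturates toward a fair coin, sites stop
#' carrying distance information.
#'
#' @inheritParams fisher_information
#' @return scalar lower bound on the variance of an unbiased \eqn{\hat p}.
#' @examples
#' crb_p(site_rates(rep(2, 1000)), p = 0.05)
#' @export
crb_p <- function(rates, p) {
  rates <- as_rates(rates)
  lam <- as.numeric(rates)
  if (any(lam == 0)) {
    pc_contract_error("crb_p requires all rates > 0")
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0) {
    pc_contract_error("p must be a single positive number")
  }
  1 / (4 * sum(lam^2 / (expm1(4 * lam * p) + 4 * p^2 * lam)))
}
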