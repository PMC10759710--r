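# The three estimators of the scaled distance p:
#   fit_mle         - joint profile MLE with a p-grid sweep (Method 1)
#   fit_conditional - rate-conditional aggregated-parity estimator (Method 2)
#   fit_gamma_map   - Gamma-prior marginal MAP (Method 3), with
#                     fit_nb_prior supplying (alpha, beta) from the counts.

# Vectorised bisection on per-element brackets [lo, hi] where g(lo) <= 0 <=
# g(hi). g must accept and return vectors.
vec_bisect <- function(g, lo, hi, iters = 55L) {
  glo <- g(lo)
  ghi <- g(hi)
  if (any(glo > 1e-9) || any(ghi < -1e-9)) {
    pc_convergence_error(sprintf(
      "root bracketing failed (max g(lo) = %.3g, min g(hi) = %.3g)",
      max(glo), min(ghi)))
  }
  for (k in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    gm <- g(mid)
    up <- gm > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  0.5 * (lo + hi)
}

#' Per-site rate solving the profile likelihood equation
#'
#' At fixed \eqn{p > 0}, the stationary point of the per-site log-likelihood
#' in \eqn{\lambda} solves
#' \deqn{x = \hat\lambda + \frac{2 p \hat\lambda}
#'   {(-1)^z e^{2\hat\lambda p} + 1}.}
#' Closed forms exist for \eqn{x = 0}: \eqn{\hat\lambda = 0} when
#' \eqn{z = 0} (boundary maximum) and
#' \eqn{\hat\lambda = \log(1 + 2p)/(2p)} when \eqn{z = 1}. For \eqn{x > 0}
#' the root is bracketed tightly — the parity correction term lies in
#' \eqn{(-1, 0)} for \eqn{z = 1} and \eqn{(0, 0.279)} for \eqn{z = 0}, so
#' \eqn{\hat\lambda \in (x, x+1)} resp. \eqn{(x - 0.3, x)} — and found by
#' bisection, vectorised over sites.
#'
#' @param x non-negative integer count(s).
#' @param z parity value(s) in \{0, 1\} (recycled against `x`).
#' @param p single positive distance.
#' @return \eqn{\hat\lambda \ge 0}, vectorised over `x`/`z`.
#' @examples
#' solve_site_rate(0, 1, 0.1)  # log(1.2) / 0.2
#' solve_site_rate(5, 0, 1e-8) # ~5: parity factor is inert at tiny p
#' @export
solve_site_rate <- function(x, z, p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0) {
    pc_contract_error("p must be a single positive number")
  }
  nn <- max(length(x), length(z))
  x <- rep_len(as.numeric(x), nn)
  z <- rep_len(as.numeric(z), nn)
  if (any(x < 0) || any(x != round(x)) || !all(z %in% c(0, 1))) {
    pc_contract_error("x must be non-negative integers and z in {0,1}")
  }
  out <- numeric(nn)
  zero_even <- x == 0 & z == 0
  zero_odd <- x == 0 & z == 1
  out[zero_odd] <- log1p(2 * p) / (2 * p)
  pos <- x > 0
  if (any(pos)) {
    xp <- x[pos]
    s <- ifelse(z[pos] == 1, -1, 1)
    g <- function(lam) lam + 2 * p * lam / (s * exp(2 * lam * p) + 1) - xp
    lo <- ifelse(s < 0, xp, xp - 0.3)
    hi <- ifelse(s < 0, xp + 1, xp)
    out[pos] <- vec_bisect(g, lo, hi)
  }
  out[zero_even] <- 0
  out
}

# Collapse a problem to unique (x, z) pairs with multiplicities; every
# per-site quantity in the estimators depends on the site only through
# (x, z), so all O(n) sums become O(#unique) sums.
unique_pairs <- function(problem) {
  key <- problem$counts * 2L + problem$parity
  tab <- table(key)
  ku <- as.integer(names(tab))
  list(x = ku %/% 2L, z = ku %% 2L, w = as.numeric(tab),
       key = key, ku = ku)
}

profile_loglik <- function(up, p) {
  lam <- solve_site_rate(up$x, up$z, p)
  list(ll = sum(up$w * site_loglik(up$x, up$z, lam, p)), lambda = lam)
}

#' Joint maximum-likelihood estimate of p (Method 1)
#'
#' Sweeps a grid of candidate distances; at each \eqn{p} every per-site
#' rate is profiled out via [solve_site_rate()] and the joint
#' log-likelihood evaluated; the best grid point is refined by a local
#' golden-section/parabolic pass ([stats::optimize()]) between its
#' neighbours. At an interior optimum the stationarity system holds:
#' \eqn{\sum_i \hat\lambda_i = \sum_i X_i} and
#' \eqn{\sum_i \hat\lambda_i / ((-1)^{Z_i} e^{2\hat\lambda_i \hat p} + 1) = 0};
#' both residuals are reported in `diagnostics`.
#'
#' When no site has odd parity the likelihood increases monotonically as
#' \eqn{p \to 0} and the estimate is clamped to the lower grid boundary
#' with `boundary_hit` set.
#'
#' @param problem a [parity_problem]; at least one count must be positive
#'   (all-zero counts leave the rates unidentifiable).
#' @param grid a [grid_spec].
#' @return a `distance_estimate` with `lambda_hat` (full-length profiled
#'   rates at \eqn{\hat p}).
#' @export
fit_mle <- function(problem, grid = grid_spec()) {
  if (!inherits(problem, "parity_problem")) {
    pc_contract_error("problem must be a parity_problem")
  }
  if (!inherits(grid, "grid_spec")) pc_contract_error("grid must be a grid_spec")
  if (all(problem$counts == 0)) {
    pc_estimation_error("all counts are zero: site rates are unidentifiable")
  }
  up <- unique_pairs(problem)
  sum_x <- sum(problem$counts)

  if (all(problem$parity == 0)) {
    p_hat <- grid$p_min
    pr <- profile_loglik(up, p_hat)
    lam_full <- pr$lambda[match(problem$counts * 2L + problem$parity, up$ku)]
    return(new_distance_estimate(
      p_hat = p_hat, method = "mle", converged = TRUE, objective = pr$ll,
      lambda_hat = site_rates(lam_full), boundary_hit = TRUE,
      diagnostics = list(reason = "no odd parities; likelihood maximal as p -> 0")))
  }

  pg <- grid_points(grid)
  lls <- vapply(pg, function(p) profile_loglik(up, p)$ll, numeric(1))
  k <- which.max(lls)
  lo <- pg[max(1L, k - 1L)]
  hi <- pg[min(length(pg), k + 1L)]
  opt <- stats::optimize(function(p) profile_loglik(up, p)$ll,
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  p_hat <- opt$maximum
  boundary <- (k == 1L && p_hat <= pg[1] * (1 + 1e-6)) ||
    (k == length(pg) && p_hat >= pg[length(pg)] * (1 - 1e-6))

  pr <- profile_loglik(up, p_hat)
  lam_u <- pr$lambda
  lam_full <- lam_u[match(problem$counts * 2L + problem$parity, up$ku)]
  s <- ifelse(up$z == 1, -1, 1)
  stat3 <- sum(up$w * lam_u / (s * exp(2 * lam_u * p_hat) + 1))
  stat3_scale <- sum(up$w * lam_u / (exp(2 * lam_u * p_hat) + 1))
  sum_lam_rel <- abs(sum(up$w * lam_u) - sum_x) / sum_x
  converged <- boundary || (sum_lam_rel < 1e-3 &&
                              abs(stat3) <= 1e-4 * max(stat3_scale, 1))
  new_distance_estimate(
    p_hat = p_hat, method = "mle", converged = converged, objective = pr$ll,
    lambda_hat = site_rates(lam_full), boundary_hit = boundary,
    diagnostics = list(sum_lambda_rel = sum_lam_rel,
                       stationarity_p = stat3,
                       stationarity_scale = stat3_scale,
                       grid_index = k))
}

#' Rate-conditional estimate of p (Method 2)
#'
#' Treats the latent transition count between the pair as a binomial
#' thinning of the phylogeny count, \eqn{Y_i | X_i \sim Bin(X_i, p)}, so
#' that \eqn{Z_i | X_i \sim Ber(\tfrac12(1 - (1-2p)^{X_i}))} and the MLE of
#' \eqn{p} given the aggregated parity count solves
#' \deqn{\sum_i (1 - 2\hat p)^{X_i} = n - 2 \sum_i Z_i.}
#' The aggregated (Poisson-approximation) form needs no special-casing of
#' \eqn{X_i = 0, Z_i = 1} sites. The left side is non-increasing in
#' \eqn{p} on \eqn{[0, 1/2)}, so the root is found by monotone bracketed
#' root finding ([stats::uniroot()], tolerance 1e-12).
#'
#' The estimator lives on \eqn{[0, 1/2)}: \eqn{(1-2p)^{X}} is a valid
#' parity-thinning probability only there. If the parity count is too
#' large for any root below 1/2 (`n - 2*sum(Z) < #\{X=0\}`), the estimate
#' is clamped just below 1/2 with `boundary_hit` set and a
#' `pc_boundary_warning` is signalled.
#'
#' @param problem a [parity_problem].
#' @return a `distance_estimate`; `objective` is the conditional parity
#'   log-likelihood at \eqn{\hat p}.
#' @export
fit_conditional <- function(problem) {
  if (!inherits(problem, "parity_problem")) {
    pc_contract_error("problem must be a parity_problem")
  }
  up <- unique_pairs(problem)
  xu <- up$x
  wu <- up$w
  n <- length(problem$counts)
  sz <- sum(problem$parity)
  target <- n - 2 * sz
  lhs <- function(p) sum(wu * (1 - 2 * p)^xu)

  cond_ll <- function(p) {
    pr1 <- 0.5 * (1 - (1 - 2 * p)^up$x)
    pr <- ifelse(up$z == 1, pr1, 1 - pr1)
    sum(up$w * log(pmax(pr, .Machine$double.xmin)))
  }

  if (sz == 0) {
    return(new_distance_estimate(
      p_hat = 0, method = "conditional", converged = TRUE,
      objective = cond_ll(0)))
  }

  p_cap <- 0.5 - 1e-9
  if (lhs(p_cap) - target > 0) {
    pc_warn(paste("parity count too large for a conditional estimate below",
                  "1/2; returning the boundary value"),
            "pc_boundary_warning")
    return(new_distance_estimate(
      p_hat = p_cap, method = "conditional", converged = FALSE,
      objective = cond_ll(p_cap), boundary_hit = TRUE))
  }
  root <- stats::uniroot(function(p) lhs(p) - target, c(0, p_cap),
                         tol = 1e-12)
  new_distance_estimate(
    p_hat = root$root, method = "conditional", converged = TRUE,
    objective = cond_ll(root$root),
    diagnostics = list(equation_residual = root$f.root))
}

#' Fit a Gamma rate prior by Negative-Binomial maximum likelihood
#'
#' Under \eqn{\lambda_i \sim \Gamma(\alpha, \beta)} the phylogeny counts
#' are marginally Negative-Binomial with size \eqn{\alpha} and success
#' probability \eqn{\beta/(\beta+1)} (mean \eqn{\alpha/\beta}, variance
#' \eqn{\alpha/\beta + \alpha/\beta^2}). Hyperparameters are estimated by
#' intercept-only NB-2 maximum likelihood via [MASS::glm.nb()]; the model
#' has no covariates, so the fit is aggregated over unique count values
#' with frequency weights, making it O(#unique values).
#'
#' Underdispersed counts (sample variance <= mean) admit no Gamma mixture;
#' the fit then falls back to method of moments with a large-\eqn{\beta}
#' clamp (\eqn{\beta = 10^6}, \eqn{\alpha = \bar x \beta}, i.e. an almost
#' degenerate prior at the sample mean) and signals a
#' `pc_dispersion_warning`. A failed ML fit falls back to plain method of
#' moments. The route taken is recorded in `attr(, "fit_method")`.
#'
#' @param counts non-negative integer vector (length >= 2).
#' @return a [gamma_prior] with attribute `fit_method` in
#'   `c("ml", "moments", "moments_underdispersed")`.
#' @export
fit_nb_prior <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L || anyNA(counts) || any(!is.finite(counts)) ||
      any(counts < 0)) {
    pc_contract_error("counts must be >= 2 finite non-negative values")
  }
  m <- mean(counts)
  v <- stats::var(counts)
  if (v <= m) {
    pc_warn(sprintf(
      "counts are underdispersed (var %.4g <= mean %.4g); using a near-degenerate prior at the mean",
      v, m), "pc_dispersion_warning")
    beta <- 1e6
    prior <- gamma_prior(m * beta, beta)
    attr(prior, "fit_method") <- "moments_underdispersed"
    return(prior)
  }
  fit <- tryCatch({
    tab <- table(round(counts))
    xs <- as.numeric(names(tab))
    w <- as.numeric(tab)
    nb <- suppressWarnings(MASS::glm.nb(xs ~ 1, weights = w))
    alpha <- nb$theta
    mu <- exp(unname(stats::coef(nb)[1]))
    gamma_prior(alpha, alpha / mu)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    alpha <- m^2 / (v - m)
    beta <- m / (v - m)
    prior <- gamma_prior(alpha, beta)
    attr(prior, "fit_method") <- "moments"
    return(prior)
  }
  attr(fit, "fit_method") <- "ml"
  fit
}

# Marginal log-posterior of p under the Gamma prior, aggregated over
# unique (x, z): sum_i log(1 + (-1)^{z_i} (1 + 2p/(beta+1))^{-(x_i+alpha)})
map_objective <- function(p, up, alpha, beta) {
  t <- 1 + 2 * p / (beta + 1)
  tc <- t^(-(up$x + alpha))
  terms <- ifelse(up$z == 1, log1p(-tc), log1p(tc))
  sum(up$w * terms)
}

# Stationarity residual of the marginal posterior:
# sum_i (x_i + alpha) / ((-1)^{z_i} (1 + 2p/(beta+1))^{x_i+alpha} + 1)
map_residual <- function(p, up, alpha, beta) {
  t <- 1 + 2 * p / (beta + 1)
  cc <- up$x + alpha
  s <- ifelse(up$z == 1, -1, 1)
  sum(up$w * cc / (s * t^cc + 1))
}

#' Gamma-prior maximum a posteriori estimate of p (Method 3)
#'
#' With \eqn{\lambda_i \sim \Gamma(\alpha, \beta)} integrated out and a
#' flat prior on \eqn{p}, the marginal log-posterior is
#' \deqn{\ell(p) = \sum_i \log\Big(1 + (-1)^{Z_i}
#'   \big(1 + \tfrac{2p}{\beta+1}\big)^{-(X_i+\alpha)}\Big)}
#' (up to constants). \eqn{\ell} is maximised directly — a coarse
#' log-spaced sweep followed by local refinement — rather than
#' root-solving its derivative, whose odd-parity terms are singular at
#' \eqn{p = 0}. Differentiating \eqn{\ell} shows interior stationary
#' points satisfy
#' \deqn{\sum_i \frac{X_i + \alpha}
#'   {(-1)^{Z_i}(1 + 2p/(\beta+1))^{X_i+\alpha} + 1} = 0,}
#' and the returned estimate is polished against (and checked to satisfy)
#' this condition; the residual is reported in `diagnostics`.
#'
#' @param problem a [parity_problem].
#' @param prior a [gamma_prior], typically from [fit_nb_prior()].
#' @param p_max upper search bound for \eqn{p} (default 20; uncalibrated
#'   distances beyond 20 total tree lengths are outside any use here).
#' @return a `distance_estimate`.
#' @export
fit_gamma_map <- function(problem, prior, p_max = 20) {
  if (!inherits(problem, "parity_problem")) {
    pc_contract_error("problem must be a parity_problem")
  }
  if (!inherits(prior, "gamma_prior")) {
    pc_contract_error("prior must be a gamma_prior")
  }
  if (!is.numeric(p_max) || length(p_max) != 1L || p_max <= 0) {
    pc_contract_error("p_max must be a single positive number")
  }
  up <- unique_pairs(problem)
  alpha <- prior$alpha
  beta <- prior$beta

  if (all(problem$parity == 0)) {
    # every term log(1 + t^{-c}) is maximal at p = 0
    return(new_distance_estimate(
      p_hat = 0, method = "gamma_map", converged = TRUE,
      objective = map_objective(0, up, alpha, beta), boundary_hit = TRUE))
  }

  pg <- exp(seq(log(1e-6), log(p_max), length.out = 300))
  vals <- vapply(pg, map_objective, numeric(1), up = up, alpha = alpha,
                 beta = beta)
  k <- which.max(vals)
  lo <- pg[max(1L, k - 1L)]
  hi <- pg[min(length(pg), k + 1L)]
  opt <- stats::optimize(map_objective, c(lo, hi), maximum = TRUE,
                         tol = 1e-11, up = up, alpha = alpha, beta = beta)
  p_hat <- opt$maximum
  objective <- opt$objective

  boundary <- (k == length(pg) && p_hat >= p_max * (1 - 1e-6))
  # polish interior optima on the stationarity equation when it brackets
  if (!boundary) {
    dlo <- max(p_hat * 0.99, 1e-12)
    dhi <- min(p_hat * 1.01, p_max)
    rlo <- map_residual(dlo, up, alpha, beta)
    rhi <- map_residual(dhi, up, alpha, beta)
    if (is.finite(rlo) && is.finite(rhi) && rlo * rhi < 0) {
      root <- stats::uniroot(map_residual, c(dlo, dhi), tol = 1e-14,
                             up = up, alpha = alpha, beta = beta)
      p_hat <- root$root
      objective <- map_objective(p_hat, up, alpha, beta)
    }
  }
  resid <- map_residual(p_hat, up, alpha, beta)
  resid_scale <- sum(up$w * (up$x + alpha) /
                       ((1 + 2 * p_hat / (beta + 1))^(up$x + alpha) + 1))
  new_distance_estimate(
    p_hat = p_hat, method = "gamma_map",
    converged = boundary || abs(resid) <= 1e-6 * max(1, resid_scale),
    objective = objective, boundary_hit = boundary,
    diagnostics = list(stationarity_residual = resid,
                       prior = prior))
}
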