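# Replicated estimator benchmark: draw rates, simulate (X, Z), run each
# estimator, collect squared errors, and compare methods pairwise with
# one-sided paired Wilcoxon signed-rank tests under Bonferroni correction.

estimate_one <- function(problem, method, grid, p_max) {
  switch(method,
    mle = fit_mle(problem, grid),
    conditional = fit_conditional(problem),
    gamma_map = fit_gamma_map(problem, fit_nb_prior(problem$counts),
                              p_max = p_max),
    pc_contract_error(sprintf("unknown method '%s'", method)))
}

#' Run a replicated estimator benchmark
#'
#' For every rate distribution and every true distance `p`, draws
#' `n_reps` independent data sets (rates, then counts/parities), runs each
#' estimator, and records squared errors. Methods are then compared on
#' each (distribution, p) cell with one-sided paired Wilcoxon signed-rank
#' tests ("method a has smaller squared error than method b") over all
#' ordered method pairs, Bonferroni-corrected over the number of tests in
#' the cell. Estimator failures on a replicate are recorded as `NA` with
#' a warning and excluded pairwise.
#'
#' Default replication here is desk scale; the reference study design for
#' this comparison uses 10,000 replicates per `p`, which this harness
#' reproduces by setting `n_reps = 10000`.
#'
#' @param dists named list of [rate_dist_gamma()] / [rate_dist_categorical()]
#'   objects (a bare `rate_distribution` is accepted and wrapped).
#' @param p_values true scaled distances to simulate.
#' @param n_sites sites per replicate.
#' @param n_reps replicates per (distribution, p) cell (>= 2).
#' @param methods subset of `c("mle", "conditional", "gamma_map")`;
#'   duplicate entries are allowed (labelled via [make.unique()]), which
#'   gives a null comparison of a method against itself.
#' @param seed integer seed for the whole run.
#' @param grid [grid_spec] used by the `mle` method.
#' @param p_max search cap for `gamma_map`.
#' @param alpha significance level for the Bonferroni-adjusted decisions.
#' @return an object of class `benchmark_result`: list with `results`
#'   (long data.frame: dist, p, replicate, method, p_hat, sq_error),
#'   `tests` (pairwise Wilcoxon table with raw and adjusted p-values and
#'   decisions), and `summary` (per-cell mean and log-mean squared error).
#' @export
run_benchmark <- function(dists, p_values, n_sites = 15629L, n_reps = 500L,
                          methods = c("mle", "conditional", "gamma_map"),
                          seed = 1L, grid = grid_spec(), p_max = 20,
                          alpha = 0.05) {
  if (inherits(dists, "rate_distribution")) dists <- list(dists)
  if (is.null(names(dists)) || any(names(dists) == "")) {
    names(dists) <- vapply(dists, function(d) d$kind, character(1))
    names(dists) <- make.unique(names(dists))
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 2L) pc_contract_error("n_reps must be >= 2")
  labels <- make.unique(methods)

  rows <- vector("list", length(dists) * length(p_values) * n_reps)
  ri <- 0L
  withr::with_seed(seed, {
    for (dn in names(dists)) {
      for (p in p_values) {
        for (rep_i in seq_len(n_reps)) {
          rates <- sample_rates(dists[[dn]], n_sites)
          problem <- simulate_counts(rates, p)
          p_hats <- vapply(seq_along(methods), function(mi) {
            tryCatch(
              estimate_one(problem, methods[mi], grid, p_max)$p_hat,
              error = function(e) {
                warning(sprintf(
                  "estimator %s failed on dist=%s p=%g replicate %d: %s",
                  labels[mi], dn, p, rep_i, conditionMessage(e)))
                NA_real_
              })
          }, numeric(1))
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            dist = dn, p = p, replicate = rep_i, method = labels,
            p_hat = p_hats, sq_error = (p_hats - p)^2,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  results <- do.call(rbind, rows[seq_len(ri)])

  tests <- benchmark_wilcoxon(results, alpha)
  agg <- stats::aggregate(sq_error ~ dist + p + method, data = results,
                          FUN = function(e) mean(e, na.rm = TRUE))
  names(agg)[names(agg) == "sq_error"] <- "mean_sq_error"
  agg$log_mean_sq_error <- log(agg$mean_sq_error)
  structure(list(results = results, tests = tests, summary = agg,
                 seed = seed),
            class = "benchmark_result")
}

benchmark_wilcoxon <- function(results, alpha = 0.05) {
  labels <- unique(results$method)
  cells <- unique(results[c("dist", "p")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sub <- results[results$dist == cells$dist[ci] & results$p == cells$p[ci], ]
    wide <- stats::reshape(sub[c("replicate", "method", "sq_error")],
                           idvar = "replicate", timevar = "method",
                           direction = "wide")
    pairs <- expand.grid(method_a = labels, method_b = labels,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$method_a != pairs$method_b, ]
    n_tests <- nrow(pairs)
    for (pi in seq_len(nrow(pairs))) {
      ea <- wide[[paste0("sq_error.", pairs$method_a[pi])]]
      eb <- wide[[paste0("sq_error.", pairs$method_b[pi])]]
      ok <- is.finite(ea) & is.finite(eb)
      pval <- if (sum(ok) < 2L || all(ea[ok] == eb[ok])) {
        1  # identical (or near-empty) paired samples: cannot reject
      } else {
        stats::wilcox.test(ea[ok], eb[ok], paired = TRUE,
                           alternative = "less", exact = FALSE)$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        dist = cells$dist[ci], p = cells$p[ci],
        method_a = pairs$method_a[pi], method_b = pairs$method_b[pi],
        n_pairs = sum(ok), p_value = pval,
        p_adjusted = min(1, pval * n_tests),
        significant = min(1, pval * n_tests) < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary)
  invisible(x)
}

#' Write a benchmark result to disk
#'
#' Writes the long replicate table as TSV (columns p, replicate, method,
#' p_hat, sq_error plus dist) and a JSON summary (per-cell mean squared
#' errors and the Wilcoxon table).
#'
#' @param result a `benchmark_result`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_benchmark <- function(result, dir) {
  if (!inherits(result, "benchmark_result")) {
    pc_contract_error("result must be a benchmark_result")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "benchmark_results.tsv")
  jsn <- file.path(dir, "benchmark_summary.json")
  utils::write.table(result$results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(summary = result$summary, wilcoxon = result$tests,
         seed = result$seed),
    jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results = tsv, summary = jsn))
}
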