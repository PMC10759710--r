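# Applied workflow: phylogeny counts + aligned sequence pair ->
# transversion masking -> (X, Z) -> distance estimate -> bootstrap SD ->
# calibration to years -> TMRCA, with uniform aggregation over many
# modern sequences.

#' Classify per-site differences between two aligned sequences
#'
#' Site-by-site comparison in a shared (rCRS-style) coordinate system;
#' alignment itself is out of scope — the sequences must already have
#' equal length. Classification: equal valid bases -> `same`; A<->G or
#' C<->T -> `transition`; purine<->pyrimidine change -> `transversion`;
#' any N, gap, or other ambiguity code (conservatively treated as N) ->
#' `unusable`. The parity value \eqn{Z_i} (0 = same, 1 = transition) is
#' defined only on `same`/`transition` sites and `NA` elsewhere.
#'
#' @param seq_a,seq_b aligned sequences: single character strings (or
#'   objects coercible via `as.character`), case-insensitive, alphabet
#'   `A C G T N -`.
#' @return an object of class `pair_diff`: list with `classification`
#'   (character vector) and `z` (0/1/NA per site).
#' @examples
#' diff_pair("ACGT", "ACGT")$z  # 0 0 0 0
#' diff_pair("AG", "GA")$z      # 1 1
#' @export
diff_pair <- function(seq_a, seq_b) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (length(a) != 1L || length(b) != 1L) {
    pc_contract_error("seq_a and seq_b must each be a single sequence")
  }
  if (nchar(a) != nchar(b)) {
    pc_contract_error(sprintf(
      "sequences must be aligned to equal length (%d vs %d)",
      nchar(a), nchar(b)))
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  valid <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  ok <- ca %in% valid & cb %in% valid
  cls <- rep("unusable", length(ca))
  same <- ok & ca == cb
  cls[same] <- "same"
  diffok <- ok & ca != cb
  ti <- diffok & ((ca %in% purine) == (cb %in% purine))
  cls[ti] <- "transition"
  cls[diffok & !ti] <- "transversion"
  z <- rep(NA_integer_, length(ca))
  z[cls == "same"] <- 0L
  z[cls == "transition"] <- 1L
  structure(list(classification = cls, z = z), class = "pair_diff")
}

#' @export
print.pair_diff <- function(x, ...) {
  tb <- table(factor(x$classification,
                     levels = c("same", "transition", "transversion",
                                "unusable")))
  cat(sprintf(
    "<pair_diff> %d sites: %d same, %d transition, %d transversion, %d unusable\n",
    length(x$classification), tb[["same"]], tb[["transition"]],
    tb[["transversion"]], tb[["unusable"]]))
  invisible(x)
}

#' Mask transversion sites and assemble the parity problem
#'
#' Drops every site that is (a) a phylogeny transversion site, (b)
#' classified `transversion` in the pair, or (c) `unusable`, and returns
#' the aligned (X, Z) vectors over the surviving sites, with original
#' 1-based site indices retained.
#'
#' @param summary a [phylogeny_summary].
#' @param diff a [pair_diff] of the same length.
#' @return a [parity_problem].
#' @export
mask_and_assemble <- function(summary, diff) {
  if (!inherits(summary, "phylogeny_summary")) {
    pc_contract_error("summary must be a phylogeny_summary")
  }
  if (!inherits(diff, "pair_diff")) {
    pc_contract_error("diff must be a pair_diff")
  }
  if (length(diff$classification) != summary$n_sites) {
    pc_contract_error(sprintf(
      "pair length (%d) must equal phylogeny n_sites (%d)",
      length(diff$classification), summary$n_sites))
  }
  keep <- diff$classification %in% c("same", "transition")
  keep[summary$transversion_sites] <- FALSE
  if (!any(keep)) {
    pc_estimation_error("no sites survive transversion masking")
  }
  parity_problem(summary$transition_counts[keep], diff$z[keep],
                 site_index = which(keep))
}

#' Estimate the scaled distance p
#'
#' Dispatches to the chosen estimator. `options` may carry `grid` (a
#' [grid_spec], `mle` only), `prior` (a [gamma_prior], `gamma_map` only;
#' fitted from the problem's counts via [fit_nb_prior()] when absent) and
#' `p_max` (`gamma_map` only).
#'
#' @param problem a [parity_problem].
#' @param method one of `"conditional"` (default), `"mle"`, `"gamma_map"`.
#' @param options named list of method options.
#' @return a `distance_estimate` (method and options recorded in
#'   `diagnostics$dispatch`).
#' @export
estimate_distance <- function(problem,
                              method = c("conditional", "mle", "gamma_map"),
                              options = list()) {
  method <- match.arg(method)
  est <- switch(method,
    conditional = fit_conditional(problem),
    mle = fit_mle(problem, grid = options$grid %||% grid_spec()),
    gamma_map = fit_gamma_map(
      problem,
      prior = options$prior %||% fit_nb_prior(problem$counts),
      p_max = options$p_max %||% 20))
  est$diagnostics$dispatch <- list(method = method, options = options)
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap standard deviation of the distance estimate
#'
#' Resamples site indices with replacement — jointly over X and Z, so the
#' pairing is preserved — re-estimates p on each resample, and returns
#' the standard deviation of the `B` estimates. More than 20% failed
#' resamples is an error.
#'
#' @param problem a [parity_problem].
#' @param method,options as in [estimate_distance()].
#' @param B number of site resamples (default 100).
#' @param seed optional integer seed.
#' @return non-negative bootstrap standard deviation.
#' @export
bootstrap_sd <- function(problem, method = "conditional", B = 100L,
                         seed = NULL, options = list()) {
  B <- as.integer(B)
  if (is.na(B) || B < 2L) pc_contract_error("B must be >= 2")
  n <- length(problem$counts)
  p_hats <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        suppressWarnings(estimate_distance(
          parity_problem(problem$counts[idx], problem$parity[idx]),
          method, options))$p_hat,
        error = function(e) NA_real_)
      res
    }, numeric(1))
  })
  fails <- sum(is.na(p_hats))
  if (fails > 0.2 * B) {
    pc_estimation_error(sprintf(
      "%d of %d bootstrap resamples failed", fails, B))
  }
  stats::sd(p_hats[!is.na(p_hats)])
}

#' Calibrate a scaled distance to years
#'
#' The total phylogeny edge length in years is
#' `mean_subs_per_site / mu`; a scaled distance `p` (fraction of total
#' edge length) therefore corresponds to `p * mean_subs_per_site / mu`
#' years of separation along the path between the two sequences.
#'
#' @param p_hat scaled distance (>= 0), possibly a vector.
#' @param cfg a [calibration_config].
#' @return years of path length.
#' @examples
#' calibrate(0.008, calibration_config())  # ~713,000 years
#' @export
calibrate <- function(p_hat, cfg = calibration_config()) {
  if (!inherits(cfg, "calibration_config")) {
    pc_contract_error("cfg must be a calibration_config")
  }
  if (any(p_hat < 0)) pc_contract_error("p_hat must be >= 0")
  p_hat * cfg$mean_subs_per_site / cfg$mu
}

#' TMRCA from a calibrated path length and the sample ages
#'
#' The path length in years between two samples of ages \eqn{T_1, T_2}
#' (years before present) implies
#' \eqn{\mathrm{TMRCA} = \tfrac12 (T_1 + T_2 + p_\mathrm{years})}.
#'
#' @param p_years calibrated path length in years (>= 0).
#' @param cfg a [calibration_config] carrying the sample ages.
#' @return TMRCA in years before present.
#' @examples
#' tmrca(800000, calibration_config())  # 400,000 for two modern samples
#' @export
tmrca <- function(p_years, cfg = calibration_config()) {
  if (!inherits(cfg, "calibration_config")) {
    pc_contract_error("cfg must be a calibration_config")
  }
  if (any(p_years < 0)) pc_contract_error("p_years must be >= 0")
  0.5 * (cfg$sample_age_1 + cfg$sample_age_2 + p_years)
}

#' Aggregate per-pair TMRCAs over many modern sequences
#'
#' Unweighted arithmetic mean; a uniform average over modern sequences of
#' diverse origins. (Weighted schemes for clustered panels are out of
#' scope.)
#'
#' @param estimates non-empty numeric vector of TMRCAs in years.
#' @return the mean TMRCA.
#' @export
aggregate_tmrca <- function(estimates) {
  if (length(estimates) < 1L || !is.numeric(estimates)) {
    pc_contract_error("estimates must be a non-empty numeric vector")
  }
  mean(estimates)
}

#' Run the full file-based estimation pipeline for one sequence pair
#'
#' Convenience wrapper: load the phylogeny summary, read the two FASTA
#' sequences, classify differences, mask transversions, estimate p,
#' bootstrap its SD, calibrate to years, and compute the TMRCA.
#'
#' @param counts_file,transversions_file phylogeny summary files (see
#'   [load_phylogeny_summary()]).
#' @param fasta_a,fasta_b FASTA files; the first record of each is used.
#' @param method,options estimator dispatch (see [estimate_distance()]).
#' @param cfg a [calibration_config].
#' @param B bootstrap resamples (0 disables the bootstrap).
#' @param seed optional integer seed (bootstrap only).
#' @param pair_id label for the output row.
#' @return a one-row data.frame with columns `pair_id, method, p_hat,
#'   p_hat_pct, sd_boot, p_years, tmrca_years`, with the
#'   `distance_estimate` attached as attribute `estimate`.
#' @export
run_pair_pipeline <- function(counts_file, transversions_file, fasta_a,
                              fasta_b, method = "conditional",
                              options = list(), cfg = calibration_config(),
                              B = 100L, seed = NULL, pair_id = "pair1") {
  summary <- load_phylogeny_summary(counts_file, transversions_file)
  diff <- diff_pair(read_fasta_first(fasta_a), read_fasta_first(fasta_b))
  problem <- mask_and_assemble(summary, diff)
  est <- estimate_distance(problem, method, options)
  sd_boot <- if (B >= 2L) {
    bootstrap_sd(problem, method, B = B, seed = seed, options = options)
  } else {
    NA_real_
  }
  p_years <- calibrate(est$p_hat, cfg)
  out <- data.frame(
    pair_id = pair_id, method = method, p_hat = est$p_hat,
    p_hat_pct = 100 * est$p_hat, sd_boot = sd_boot, p_years = p_years,
    tmrca_years = tmrca(p_years, cfg), stringsAsFactors = FALSE)
  attr(out, "estimate") <- est
  out
}
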