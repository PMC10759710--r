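# Sequence-level simulation under site-scaled K2P / TN93 substitution
# models. Used for robustness studies: unlike the raw Poisson-parity
# scheme, these generate actual nucleotide pairs including sparse
# transversions, which the pipeline then masks.

PC_BASES <- c("A", "C", "G", "T")
# transition partner of A,C,G,T (indices into PC_BASES)
PC_TI_PARTNER <- c(3L, 4L, 1L, 2L)
# transversion targets (two per state)
PC_TV_TARGETS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

#' Site-scaled substitution model specification
#'
#' K2P: one transition rate and one rate per transversion target, shared
#' by all states. TN93: separate purine (A<->G) and pyrimidine (C<->T)
#' transition rates. All rates are per unit of total phylogeny edge
#' length at unit site scale; site `i` multiplies the whole rate matrix
#' by `site_scale[i]`, so with `ti_rate = 1` the per-site transition rate
#' equals the site scale. Default rate-matrix parameters ship in
#' `inst/extdata/substitution_defaults.json` (transition/transversion
#' target ratio 40, i.e. a ti/tv event ratio of 20).
#'
#' @param kind `"K2P"` or `"TN93"`.
#' @param site_scale positive per-site rate multipliers, one per site.
#' @param ti_rate K2P transition rate (ignored for TN93).
#' @param ag_rate,ct_rate TN93 purine/pyrimidine transition rates
#'   (ignored for K2P).
#' @param tv_rate rate to *each* of the two transversion targets.
#' @param base_freqs ancestral base frequencies for A, C, G, T.
#' @return an object of class `substitution_model_spec`.
#' @export
substitution_model_spec <- function(kind = c("K2P", "TN93"), site_scale,
                                    ti_rate = NULL, ag_rate = NULL,
                                    ct_rate = NULL, tv_rate = NULL,
                                    base_freqs = rep(0.25, 4)) {
  kind <- match.arg(kind)
  defaults <- substitution_defaults()[[kind]]
  site_scale <- as.numeric(site_scale)
  if (length(site_scale) < 1L || any(!is.finite(site_scale)) ||
      any(site_scale <= 0)) {
    pc_contract_error("site_scale must be positive and finite")
  }
  if (is.null(tv_rate)) tv_rate <- defaults$tv_rate
  if (kind == "K2P") {
    if (is.null(ti_rate)) ti_rate <- defaults$ti_rate
    ag_rate <- ct_rate <- ti_rate
  } else {
    if (is.null(ag_rate)) ag_rate <- defaults$ag_rate
    if (is.null(ct_rate)) ct_rate <- defaults$ct_rate
    ti_rate <- NULL
  }
  if (any(c(ag_rate, ct_rate) <= 0) || tv_rate < 0) {
    pc_contract_error("transition rates must be > 0 and tv_rate >= 0")
  }
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    pc_contract_error("base_freqs must be 4 non-negative values summing to 1")
  }
  structure(list(kind = kind, site_scale = site_scale, ag_rate = ag_rate,
                 ct_rate = ct_rate, tv_rate = tv_rate,
                 base_freqs = base_freqs),
            class = "substitution_model_spec")
}

#' Default substitution-model rate parameters
#'
#' Reads the packaged defaults (`inst/extdata/substitution_defaults.json`).
#' @return named list with `K2P` and `TN93` entries.
#' @export
substitution_defaults <- function() {
  path <- system.file("extdata", "substitution_defaults.json",
                      package = "parityclock", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Evolve a sequence pair under a site-scaled substitution model
#'
#' Each site runs an independent continuous-time Markov chain on
#' \{A, C, G, T\} with the site-scaled rate matrix for total time `p` (in
#' tree-length units): one endpoint is the ancestral sequence, the other
#' the evolved one, so `p` is the full path length between the returned
#' pair. Simulation uses uniformisation (a dominating Poisson clock with
#' thinning), and the latent numbers of real transition and transversion
#' events per site are recorded — these let robustness studies check what
#' masking of transversion sites does downstream.
#'
#' @param spec a [substitution_model_spec].
#' @param p total path length between the two sequences (>= 0).
#' @param seed optional integer seed.
#' @return an object of class `sequence_sim`: list with `seq_a`, `seq_b`
#'   (single-character strings), `transitions`, `transversions` (per-site
#'   latent event counts), and `p`.
#' @export
simulate_sequences <- function(spec, p, seed = NULL) {
  if (!inherits(spec, "substitution_model_spec")) {
    pc_contract_error("spec must be a substitution_model_spec")
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0) {
    pc_contract_error("p must be a single finite non-negative number")
  }
  n <- length(spec$site_scale)
  ti_by_state <- c(spec$ag_rate, spec$ct_rate, spec$ag_rate, spec$ct_rate)
  m_unit <- max(ti_by_state) + 2 * spec$tv_rate  # dominating rate, unit scale
  with_seed_if(seed, {
    anc <- sample.int(4L, n, replace = TRUE, prob = spec$base_freqs)
    n_ev <- stats::rpois(n, spec$site_scale * m_unit * p)
    der <- anc
    ti_count <- integer(n)
    tv_count <- integer(n)
    active <- which(n_ev > 0L)
    if (length(active)) {
      us <- stats::runif(sum(n_ev[active]))
      tvs <- stats::runif(sum(n_ev[active]))  # which tv target, if any
      ptr <- 0L
      for (i in active) {
        st <- anc[i]
        for (k in seq_len(n_ev[i])) {
          ptr <- ptr + 1L
          p_ti <- ti_by_state[st] / m_unit
          p_tv <- spec$tv_rate / m_unit
          u <- us[ptr]
          if (u < p_ti) {
            st <- PC_TI_PARTNER[st]
            ti_count[i] <- ti_count[i] + 1L
          } else if (u < p_ti + 2 * p_tv) {
            st <- PC_TV_TARGETS[[st]][1L + (tvs[ptr] > 0.5)]
            tv_count[i] <- tv_count[i] + 1L
          } # else: virtual jump of the dominating clock
        }
        der[i] <- st
      }
    }
    structure(
      list(seq_a = paste(PC_BASES[anc], collapse = ""),
           seq_b = paste(PC_BASES[der], collapse = ""),
           transitions = ti_count, transversions = tv_count, p = p,
           kind = spec$kind),
      class = "sequence_sim")
  })
}

#' @export
print.sequence_sim <- function(x, ...) {
  cat(sprintf(
    "<sequence_sim> %s, %d sites, p = %g, %d transition / %d transversion events\n",
    x$kind, nchar(x$seq_a), x$p, sum(x$transitions), sum(x$transversions)))
  invisible(x)
}
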