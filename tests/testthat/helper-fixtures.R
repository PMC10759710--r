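# Shared test helpers: small simulated problems and an independent
# per-site likelihood used as an oracle against the packaged one.

make_problem <- function(n, lam, p, seed) {
  simulate_counts(site_rates(rep_len(lam, n)), p, seed = seed)
}

# Independent evaluation of the full joint likelihood (product form,
# including the X! and 1/2 constants): Poisson pmf times the parity
# Bernoulli pmf. Used as the oracle for log_likelihood.
oracle_likelihood <- function(x, z, lam, p) {
  prod(stats::dpois(x, lam) *
         ifelse(z == 1, parity_prob(lam * p), 1 - parity_prob(lam * p)))
}

# Directed one-sided paired Wilcoxon p-value (a < b), for readable
# acceptance assertions.
wilcox_less <- function(a, b) {
  stats::wilcox.test(a, b, paired = TRUE, alternative = "less",
                     exact = FALSE)$p.value
}

write_pair_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(fx$summary$transition_counts,
                    file.path(dir, "counts.tsv"))
  write_transversion_sites(fx$summary$transversion_sites,
                           file.path(dir, "tv.txt"))
  write_fasta(c(a = fx$sim$seq_a), file.path(dir, "a.fasta"))
  write_fasta(c(b = fx$sim$seq_b), file.path(dir, "b.fasta"))
  list(counts = file.path(dir, "counts.tsv"),
       tv = file.path(dir, "tv.txt"),
       a = file.path(dir, "a.fasta"),
       b = file.path(dir, "b.fasta"))
}
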