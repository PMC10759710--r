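# parityclock

Dating the most recent common ancestor (TMRCA) of two aligned sequences
from the **parity of per-site transition counts**, with per-site Poisson
transition rates borrowed from a large detailed phylogeny such as the
human mtDNA Phylotree.

## The idea

Who is this for: anyone with (a) a per-site transition-count table
extracted from a dense single-species phylogeny and (b) a pair of
aligned sequences — one of which may be far outside that phylogeny
(a Neanderthal, a Denisovan, a chimpanzee) — who wants a fast,
single-parameter TMRCA estimate instead of a full Bayesian tree
reconstruction.

Normalise the phylogeny's edges to total length 1. At site *i*,

* X<sub>i</sub> ~ Pois(λ<sub>i</sub>) — transitions at site *i* over the
  whole phylogeny,
* Y<sub>i</sub> ~ Pois(λ<sub>i</sub>·p) — latent transitions along the
  path of scaled length *p* between the two target sequences,
* Z<sub>i</sub> = Y<sub>i</sub> mod 2 — the only thing observable from
  the pair: do they agree at site *i*?

If Y ~ Pois(Λ), its parity is Ber(½(1 − e<sup>−2Λ</sup>)). The package
estimates *p* from (X, Z) after masking every site touched by a
transversion, using three estimators:

1. **`fit_mle`** — joint maximum likelihood: grid sweep over *p*,
   profiling out each λ<sub>i</sub> via its per-site stationarity
   equation (carries a known upward incidental-parameter bias at
   larger *p*);
2. **`fit_conditional`** — treats Y as a binomial thinning of X and
   solves the aggregated parity equation
   Σ(1 − 2p̂)<sup>X<sub>i</sub></sup> = n − 2ΣZ<sub>i</sub> (the
   recommended default);
3. **`fit_gamma_map`** — maximum a posteriori under
   λ<sub>i</sub> ~ Γ(α, β), with (α, β) fitted to the counts by
   intercept-only Negative-Binomial maximum likelihood
   (`fit_nb_prior`).

`fisher_information()` / `crb_p()` give the Cramer-Rao lower bound for
benchmarking; `calibrate()` and `tmrca()` map *p* to years
(defaults: substitution rate μ = 1.57e-8 per site per year, phylogeny
mean 1.4 substitutions per site, so one tree length ≈ 89 Myr of path);
the simulate module generates realistic synthetic data (Gamma or
Categorical mtDNA-like site rates, site-scaled K2P/TN93 sequence pairs
with sparse transversions, KS-based rate imputation for zero-count
sites) and `run_benchmark()` compares the estimators with paired
Wilcoxon tests.

## Worked example

Simulate a Neanderthal-like problem — 16,569 sites, true scaled
distance p = 0.00915 (≈ 408 kya for two modern samples) — write it to
files, and run the full pipeline:

```r
library(parityclock)

fx <- simulate_phylogeny_fixture(n_sites = 16569, p = 0.00915, seed = 42)
dir <- tempfile(); dir.create(dir)
write_count_table(fx$summary$transition_counts, file.path(dir, "counts.tsv"))
write_transversion_sites(fx$summary$transversion_sites, file.path(dir, "tv.txt"))
write_fasta(c(modern = fx$sim$seq_a),  file.path(dir, "modern.fasta"))
write_fasta(c(ancient = fx$sim$seq_b), file.path(dir, "ancient.fasta"))

run_pair_pipeline(file.path(dir, "counts.tsv"), file.path(dir, "tv.txt"),
                  file.path(dir, "modern.fasta"), file.path(dir, "ancient.fasta"),
                  method = "conditional", B = 100, seed = 1)
#>   pair_id      method    p_hat p_hat_pct   sd_boot p_years tmrca_years
#> 1   pair1 conditional 0.008018    0.8018 0.0006735  715017      357509
```

Reading the row: the pair differs (by a transition) at 172 of the
15,620 sites that survive transversion masking; the conditional
estimator turns that into p̂ = 0.80% of the total phylogeny edge length
(true value 0.915%, bootstrap SD 0.067% — the estimate is within 2 SD,
and the SD matches the Cramer-Rao bound of 0.067% for this rate
profile). Calibration makes that 715,017 years of path; splitting it
between two modern lineages dates their common ancestor to ~358 kya.

The same steps decompose into `load_phylogeny_summary()` →
`diff_pair()` → `mask_and_assemble()` → `estimate_distance()` →
`bootstrap_sd()` → `calibrate()` → `tmrca()`, and a thin command-line
launcher wraps them:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","parityclock",package="parityclock"))')" \
  estimate --counts counts.tsv --transversions tv.txt \
  --fasta-a modern.fasta --fasta-b ancient.fasta --method conditional \
  --out neander
```

with subcommands `estimate`, `simulate`, `benchmark`, `crb`; every run
writes a JSON manifest of its inputs, seed, and defaults.

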