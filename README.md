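# ldnescan

Effective population size (Ne) quantifies genetic drift, and genomic
data offer several routes to it: nucleotide diversity (`pi / 4mu`),
the variance of family sizes, and linkage disequilibrium (LD) between
SNP pairs.  Selection on linked sites — background selection against
recurrent deleterious mutations, hitch-hiking during selective sweeps —
erodes diversity, most strongly where recombination is low, so
diversity-based Ne estimates mix demography with selection.  LD-based
estimates, which read drift from the squared allelic correlation r²
between pairs of SNPs at recombination fraction c, are expected to be
far more robust: LD at distance c mainly reflects the ancestral Ne about
1/(2c) generations ago, and most SNP pairs sit far from any selected
locus.

`ldnescan` is an R package for population geneticists who want to study
this contrast quantitatively at desk scale.  It provides:

* a forward-time diploid Wright–Fisher simulator (Rcpp core) with
  multiplicative fecundity selection (genotype fitnesses `1`, `1+sh`,
  `1+s`), four mutation models (neutral; background selection: 5%
  deleterious, gamma DFE with shape 0.2 and mean |s| = 0.02; selective
  sweeps: 0.1% beneficial, same gamma; overdominance: s = 0.02,
  h = 1.5), Poisson crossovers on an arbitrary recombination map,
  partial self-fertilisation and arbitrary census trajectories;
* the three Ne estimator families:
  `estimate_ne_ld()` / `historical_trajectory()` (binned pairwise r²,
  Sved-type inversion `Ne = (1/r2_adj − α)/(4c)`, Haldane map function,
  horizons `t = 1/(2c)`), `ne_from_pi()` (`pi/(4mu)`), and
  `ne_vk_analytic()` / `ne_vk_from_pedigree()`
  (`N/(1+α)`, `α = β/(2−β)` for selfing fraction β; `(4N−2)/(Vk+2)`);
* a windowed genome scan (`scan_genome()`): 2 cM windows on the genetic
  map, per-window diversity statistics and a regional constant-size Ne
  from pooled pairs at `c ∈ [1/100, 1/50]`, the standard exclusion rules
  (> 250,000 pairs; 0 < Ne ≤ 100,000), and Spearman correlations against
  recombination rate and annotation tracks;
* generators for synthetic human-like inputs (heterogeneous log-normal
  recombination maps, copula-coupled annotation tracks, and
  background-selection genotype data) so the full scan runs without any
  real cohort;
* minimal VCF / genetic-map / BED-like IO and a thin CLI
  (`inst/exec/ldnescan`) over the same functions.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a neutral constant-size population of N = 1000 diploids at
mutation–drift equilibrium (2 Mb, mu = 1e-8, 2.5 cM/Mb, 700
generations), sample 100 individuals, and estimate Ne three ways:

```r
library(ldnescan)

cfg <- study_config("neutral_recovery")
cfg$seed <- 101L
sim <- run_simulation(cfg)
sim
#> <wf_sim> neutral model, 700 generations, sampled 100 diploids, 506 sites, pi = 4.1e-05
glance(sim)
#> # A tibble: 1 × 6
#>   n_sites        pi final_census n_fixed mean_vk ne_pi
#>     <int>     <dbl>        <dbl>   <dbl>   <dbl> <dbl>
#> 1     506 0.0000410         1000      13    1.99 1026.

estimate_ne_ld(sim$sample)
#> # A tibble: 1 × 3
#>   ne_ld n_bins n_pairs
#>   <dbl>  <int>   <int>
#> 1  977.     12   23856

ne_vk_from_pedigree(sim$family_sizes)
#> [1] 1015.252
ne_vk_analytic(1000, 0.5)
#> [1] 750
```

All three estimators agree with the census: the sample's diversity gives
`ne_pi ≈ 1026` (`pi/(4mu)` with `pi = 4.1e-5`), the mean of the twelve
LD bins with `c ∈ [0.0025, 0.025]` gives `ne_ld ≈ 977`, and the realised
family-size variance (`mean_vk ≈ 2`, the multinomial value) gives
`≈ 1015`.  The last line is the analytic value under 50% selfing, where
drift runs faster and `Ne = 3N/4 = 750`.

The historical trajectory behind the LD estimate, and its plot:

```r
traj <- attr(estimate_ne_ld(sim$sample), "trajectory")
head(tidy(traj), 4)
#> # A tibble: 4 × 6
#>       t ne_hat valid mean_c mean_r2 n_pairs
#>   <dbl>  <dbl> <lgl>  <dbl>   <dbl>   <int>
#> 1  11.5   674. TRUE  0.0436  0.0134     783
#> 2  13.3   824. TRUE  0.0375  0.0130    2809
#> 3  16.4   705. TRUE  0.0305  0.0165    3220
#> 4  20.2   701. TRUE  0.0248  0.0192    3558
autoplot(traj)
```

Swapping `study_config("bs_rr1")` (background selection at 1 cM/Mb) into
the same pipeline leaves `ne_ld` essentially unchanged while tight
linkage (`study_config("bs_tight")`) collapses `ne_pi` — the package's
central contrast.  For the genome-scan stage on synthetic human-like
windows:

```r
hw <- simulate_humanlike_windows(n_windows = 30, base_seed = 1)
correlate_windows(hw, list(c("pi", "rr_mean"), c("ne_ld", "rr_mean")))
```

which shows the positive diversity–recombination coupling induced by
background selection alongside a near-zero coupling for the LD-based
regional Ne.

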