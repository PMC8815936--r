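---
title: "LD-based effective population size under selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based effective population size under selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ldnescan)
```

## The question

The effective population size $N_e$ measures the rate of genetic drift.
Three families of estimators see it through different lenses:

* **Pedigree / analytic** ($N_{eVk}$): from the variance of family sizes
  $V_k$, $N_{eVk} = (4N-2)/(V_k+2)$ for constant census $N$; under
  partial self-fertilisation with selfed fraction $\beta$,
  $N_{eVk} = N/(1+\alpha)$ with $\alpha = \beta/(2-\beta)$.  This is the
  "demographic truth" that drift at neutral loci should reflect.
* **Diversity-based** ($N_{e\pi}$): at mutation-drift equilibrium the
  per-site nucleotide diversity is $\pi = 4 N_e \mu$, so
  $N_{e\pi} = \pi/(4\mu)$.
* **LD-based** ($N_{eLD}$): drift generates squared allelic correlation
  $r^2$ between linked SNPs; at recombination fraction $c$ the expected
  level is approximately $1/(\alpha + 4 N_e c)$ plus a sampling term, and
  it mainly reflects the ancestral $N_e$ about $1/(2c)$ generations ago.

Directional selection on linked sites (background selection from
recurrent deleterious mutations, hitch-hiking during selective sweeps)
removes neutral diversity, and does so most strongly where recombination
is low.  $N_{e\pi}$ therefore conflates demography with selection.  The
package exists to demonstrate, by forward simulation and by a windowed
genome-scan analysis of human-like data, that $N_{eLD}$ is by contrast
almost insensitive to selection and tracks the pedigree $N_{eVk}$.

## The forward simulator

`run_simulation()` iterates a discrete-generation diploid Wright-Fisher
model:

* **Reproduction and selection.** Each offspring is produced by selfing
  with probability $\beta$ (one parent, both gametes) or outcrossing (two
  parents drawn independently, with replacement).  Parents are drawn with
  probability proportional to fitness - fecundity selection, the standard
  Wright-Fisher realisation.  Fitness is multiplicative over loci with
  genotype values $1$, $1+sh$, $1+s$, floored at zero.
* **Mutation models.** `neutral`; `bs` (5% of new mutations deleterious,
  $|s| \sim$ Gamma(shape 0.2, mean 0.02), $h = 0.5$); `ss` (0.1%
  advantageous, same gamma, $h = 0.5$); `od` (0.01% overdominant,
  $s = 0.02$, $h = 1.5$).  Gamma draws that would give $s \le -1$ are
  re-drawn.  Mutations arise at Poisson($\mu L$) per gamete at uniform
  bp positions under infinite sites (collisions re-drawn), so every site
  stays biallelic.
* **Recombination.** Each gamete receives Poisson(map length in Morgans)
  crossovers placed uniformly on the *map* scale - no interference -
  which makes Haldane's function $c = \tfrac12(1-e^{-2d})$ the exact
  map-distance-to-recombination-fraction conversion.
* **Bookkeeping.** Gamete counts per parent (the $V_k$ pedigree record)
  and fixed-mutation counts are kept; fixed and lost mutations are pruned
  from haplotypes every generation, and the mutation registry is
  compacted (renumbered in position order) so runs stay cache-friendly
  and memory-bounded.  All randomness flows from R's RNG: a seeded run is
  bit-reproducible.

### Initialisation instead of long burn-in

Rather than burning in for thousands of generations, the population can
start at the *neutral* mutation-drift equilibrium
(`burn_in = "equilibrium_init"`): the number of sites with derived count
$i$ out of $2N$ is Poisson with mean $\theta L / i$
($\theta = 4N\mu$ per site), carriers are assigned independently across
sites (linkage equilibrium).  Pairwise LD then needs only
$\approx 3/(2c_{\min})$ forward generations to reach its
drift-recombination equilibrium at the smallest analysed $c$ - about 600
generations for $c_{\min} = 0.0025$; the reference scenarios run 700.
This is what makes replicated recovery experiments possible at desk
scale.  The cost is that *selected* scenarios start from neutral standing
variation, so background-selection scenarios need the additional
generations for diversity to erode toward its selected equilibrium; the
tight-linkage scenario below is sized accordingly.

### Rescaling

`rescale_config(config, Q)` applies the standard population-genetic
rescaling $N/Q$, $t/Q$, $\mu Q$, map $\times Q$, $s Q$, preserving
$N\mu$, $N \times$ map length and $Ns$.  When a scenario is rescaled,
every *analysis* window defined in $c$ must scale with it ($c' = Qc$
keeps $\rho = 4Nc$ fixed) - the tight-linkage study below estimates in
$c \in [0.01, 0.1]$ precisely because it is a $Q = 4$ rescaling of a
scenario analysed in $c \in [0.0025, 0.025]$.

## The estimators

`pairwise_r2()` computes $r^2$ as the squared correlation of allele
states across haplotypes (phased) or of genotype dosages (unphased; under
Hardy-Weinberg this equals the Burrows composite measure normalised by
allele-frequency products).  Sites with minor allele frequency below 0.05
are excluded by default; pairs are restricted to
$c \in [0.001, 0.5]$ and capped (seeded uniform subsample) at $5\times10^6$.

`bin_pairs()` uses 30 logarithmic bins over that range with at least 100
pairs per bin.  `ne_from_bin()` inverts the Sved-family expectation: with
the sampling correction ($1/n_h$ phased, $1/n$ unphased) subtracted,
$\hat N_e = (1/\bar r^2_{adj} - \alpha)/(4\bar c)$, $\alpha = 1$ phased
and $2$ unphased.  Non-positive adjusted $r^2$ yields an *invalid* flag,
never a silent drop.  `historical_trajectory()` assigns each bin the
horizon $t = 1/(2\bar c)$; `estimate_ne_ld()` averages (unweighted) the
valid bins with $\bar c \in [0.0025, 0.025]$ - horizons of roughly
20-200 generations - into one headline value.

Two numerical properties of this inversion are worth knowing.  First, it
is exact against its own forward form (the round-trip is tested to
$10^{-9}$).  Second, the Sved form $1/(1+\rho)$ overstates the true
equilibrium $r^2$ when $\rho = 4N_e c \lesssim 10$, so single windows
analysed at small $\rho$ carry an upward bias of tens of percent, and
per-window estimates at small $N$ fluctuate enormously (the inversion is
convex, so means across windows inflate further).  The package therefore
validates the estimator by *parameter recovery at the study scale*
($\rho \in [10, 100]$, where the residual bias is under ~10%) rather
than by formula fidelity, and regional per-window values should be read
as order-of-magnitude local estimates - exactly how the genome-scan
stage treats them (their rank correlation with other variables, not
their absolute level, is the object of interest).

`regional_ne()` is the constant-size single-window variant: all pairs
with $c \in [1/100, 1/50]$ pooled into one bin, unphased correction by
default (mirroring genotype data of unknown phase), with a window flagged
when fewer than 250,000 pairs are available.

## The genome scan

`partition_windows()` cuts each chromosome into consecutive 2 cM spans
from its first mapped position, dropping the trailing (telomeric)
remainder.  `window_stats()` computes per window: $\pi$ (sum of unbiased
per-site heterozygosity over segregating sites, divided by the window's
bp length, so monomorphic sites count in the denominator - the
convention chosen here, since none is universal), the proportion
of polymorphic sites $P$, mean MAF over SNPs (mean, not median, where a
summary was needed), mean recombination rate (cM/Mb), the regional
LD-based $N_e$, and window means of any annotation tracks (features
spanning windows are assigned by midpoint).  `filter_windows()` applies
the exclusion rules - strictly more than 250,000 pairs, $0 < \hat N_e
\le 100{,}000$ - and reports per-rule tallies that always reconcile with
the total.  `correlate_windows()` computes Spearman rank correlations
(average ranks on ties) with two-sided p-values from the t-approximation
on $n-2$ degrees of freedom; a permutation option was considered and
rejected as the t-approximation is standard at hundreds of windows.

## Synthetic human-like data

No human genotypes ship with the package; `synthetic` generators stand in
for them and are first-class, tested code.

* `sample_heterogeneous_map()` draws per-region rates from a log-normal
  with mean 1 cM/Mb and coefficient of variation 1, truncated to
  [0.01, 5] cM/Mb, over 70 equal-length regions by default.  The
  log-normal is a parametric stand-in for the empirical distribution of
  human 2 cM window averages, which is known only graphically; its mean
  and range match the simulated-rate range.
* `generate_tracks()` builds annotation tracks (gene density, LoF and
  missense counts, a background-selection statistic $B \in (0.4, 1]$)
  through a Gaussian copula on window ranks, with default Spearman
  targets +0.6 (gene-LoF, gene-missense), -0.5 (B-gene) and +0.5 (B-RR);
  the implied latent matrix must be positive semi-definite.  The copula
  reproduces the *sign structure* of real annotation couplings without
  claiming their magnitudes.
* `simulate_humanlike_windows()` makes each window an independently
  simulated chromosome whose recombination rate is drawn from the
  heterogeneous distribution (truncated to [0.25, 5] cM/Mb so chromosome
  lengths stay bounded), evolved under background selection.  Because BS
  erodes diversity fastest where recombination is low, the windows carry
  the empirical positive coupling between RR and $\pi$, while regional
  $N_{eLD}$ tracks the (constant) demography.  Desk-scale defaults:
  N = 150, mu = 4e-7, 300 generations, 50 sampled diploids, 2 cM windows
  with a 0.2 cM margin.  What these windows do *not* emulate: hotspot
  fine structure, real gene maps, ascertainment, population structure or
  sequencing error - so passing the pattern tests shows the pipeline
  recovers the selection signature under its own model assumptions, not
  that it would do so on any real cohort.

## Reference study scenarios

`study_config()` freezes the package's reference conditions (all with
100 sampled diploids, equilibrium initialisation):

| scenario | census | sequence | RR (cM/Mb) | mu | generations |
|---|---|---|---|---|---|
| neutral_recovery | 1000 | 2 Mb | 2.5 | 1e-8 | 700 |
| bs_rr1 / neutral_rr1 / ss_rr1 | 1000 | 5.2 Mb | 1 | 1e-8 | 700 |
| bs_tight / neutral_tight | 250 (Q=4 rescale of 1000) | 100 Mb | 0.04 | 4e-8 | 625 |
| step_demography | 1000 -> 250 at t-30 | 2 Mb | 10 | 1e-8 | 700 |

Geometry choices: `neutral_recovery` uses 2.5 cM/Mb so a 2 Mb sequence
spans 5 cM and SNP pairs cover the whole estimation window
$c \in [0.0025, 0.025]$; the 1 cM/Mb scenarios keep the same 5.2 cM map
extent (hence 5.2 Mb) so the estimation protocol is identical across
recombination rates.  The tight-linkage pair is the full-scale extreme
scenario (a 1 cM genome of 100 Mb) rescaled by $Q = 4$;
`step_demography` uses a 20 cM map so the trajectory resolves horizons
from a few to ~200 generations on both sides of the census drop.
Replicate counts (20 for recovery studies, 8 per arm for the rescaled
tight-linkage contrast, 210 human-like windows) are the package's
desk-scale choices; standard errors of the replicate means are
reported by `replicate_ne_study()` consumers.

## Known limitations

* The LD inversion is the classical Sved-family point estimator, not a
  full likelihood or regression fit; its small-$\rho$ bias is documented
  above and bounded by the recovery tests at the study scale.
* Single populations only: no migration, structure, overlapping
  generations or non-Wright-Fisher reproduction.
* The unphased correction ($\alpha = 2$, $1/n$) is calibration-validated
  against simulated genotype data, not derived; phase-known data should
  use the phased mode.
* Equilibrium initialisation is neutral; selected scenarios inherit a
  transient until linked selection reshapes variation, which the scenario
  run lengths absorb but very short custom runs may not.
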