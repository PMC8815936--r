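#' Canonical desk-scale study scenarios
#'
#' The package's reference simulation conditions for studying how
#' selection affects each Ne estimator.  All use a census of breeding
#' diploids, mutation rate 1e-8 (unless noted), equilibrium
#' initialisation, 100 sampled diploids, and enough forward generations
#' (>= 3 relaxation times at the smallest analysed c, i.e. >= 600) for
#' pairwise LD to reach drift-recombination equilibrium:
#'
#' * `"neutral_recovery"` - neutral, N = 1000, 2 Mb at 2.5 cM/Mb (5 cM
#'   map, so SNP pairs cover the whole c-window 0.0025-0.025).
#' * `"bs_rr1"` / `"neutral_rr1"` - background selection (and its neutral
#'   control) at the human-typical 1 cM/Mb; 5.2 Mb keeps the same 5.2 cM
#'   map extent so the estimation protocol matches `neutral_recovery`.
#' * `"ss_rr1"` - selective sweeps at 1 cM/Mb, same geometry.
#' * `"bs_tight"` / `"neutral_tight"` - the tight-linkage contrast: the
#'   full-scale extreme scenario (N = 1000, 100 Mb at uniform 0.01
#'   cM/Mb, i.e. a 1 cM genome, mutation rate 1e-8) rescaled by Q = 4
#'   via [rescale_config()], preserving N*mu, N*s and N*(map length):
#'   N = 250, mutation rate 4e-8, 0.04 cM/Mb, gamma-mean |s| = 0.08,
#'   625 generations.
#' * `"step_demography"` - neutral census drop 1000 -> 250 thirty
#'   generations before sampling, on a 20 cM map (10 cM/Mb over 2 Mb) so
#'   the LD trajectory resolves horizons from a few to ~200 generations.
#'
#' @param name Scenario name.
#' @return A [sim_config()] (seedless; set `$seed` or use
#'   [replicate_ne_study()]).
#' @export
study_config <- function(name = c("neutral_recovery", "bs_rr1",
                                  "neutral_rr1", "ss_rr1", "bs_tight",
                                  "neutral_tight", "step_demography")) {
  name <- match.arg(name)
  switch(name,
    neutral_recovery = sim_config(
      n = 1000, sequence_length_bp = 2e6, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 2.5, model = "neutral",
      n_generations = 700, sample_size = 100),
    bs_rr1 = sim_config(
      n = 1000, sequence_length_bp = 5.2e6, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 1, model = "bs",
      n_generations = 700, sample_size = 100),
    neutral_rr1 = sim_config(
      n = 1000, sequence_length_bp = 5.2e6, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 1, model = "neutral",
      n_generations = 700, sample_size = 100),
    ss_rr1 = sim_config(
      n = 1000, sequence_length_bp = 5.2e6, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 1, model = "ss",
      n_generations = 700, sample_size = 100),
    bs_tight = rescale_config(sim_config(
      n = 1000, sequence_length_bp = 1e8, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 0.01, model = "bs",
      n_generations = 2500, sample_size = 100), 4),
    neutral_tight = rescale_config(sim_config(
      n = 1000, sequence_length_bp = 1e8, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 0.01, model = "neutral",
      n_generations = 2500, sample_size = 100), 4),
    step_demography = sim_config(
      census_trajectory = tibble::tibble(generation = c(0L, 670L),
                                         n = c(1000L, 250L)),
      sequence_length_bp = 2e6, mutation_rate = 1e-8,
      recomb_rate_cM_Mb = 10, model = "neutral",
      n_generations = 700, sample_size = 100))
}
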