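#' Configure one forward Wright-Fisher scenario
#'
#' Collects everything one simulation run needs: the census trajectory,
#' sequence length, mutation rate, recombination map, mutation/selection
#' model, selfing fraction, run length, initialisation mode, sample size
#' and seed.
#'
#' The census trajectory is a set of `(generation, n)` change points:
#' the census holds each value from its generation index until the next
#' change point.  Indices must be strictly increasing and start at 0
#' (generation 0 is the initial population).
#'
#' Initialisation (`burn_in`):
#' * `"equilibrium_init"` - segregating sites are seeded from the neutral
#'   mutation-drift equilibrium: the expected number of sites at derived
#'   count `i` out of `2N` is `theta L / i` (`theta = 4 N mu` per site),
#'   counts are Poisson, and carriers are assigned independently across
#'   sites (linkage equilibrium).  Forward generations then let LD
#'   equilibrate; LD at recombination distance `c` does so on the
#'   `1/(2c)`-generation timescale, so `n_generations >= 3/(2 c_min)` for
#'   the smallest `c` to be analysed.
#' * `"full"` - the population starts mutation-free.
#'
#' @param n Constant census size (diploids).  Alternatively supply
#'   `census_trajectory`.
#' @param census_trajectory Data frame or tibble with columns `generation`
#'   and `n`.
#' @param sequence_length_bp Sequence length `L` in bp.
#' @param mutation_rate Per-bp per-generation mutation probability `mu`.
#' @param recomb_rate_cM_Mb Uniform recombination rate; alternatively
#'   supply `map`.
#' @param map A [recomb_map()] (overrides `recomb_rate_cM_Mb`).
#' @param model Mutation model: `"neutral"`, `"bs"`, `"ss"` or `"od"`.
#' @param dfe Optional [dfe_config()] overriding the model defaults.
#' @param selfing Probability `beta` that an offspring is produced by
#'   self-fertilisation.
#' @param n_generations Number of forward generations to run.
#' @param burn_in `"equilibrium_init"` or `"full"`.
#' @param sample_size Number of diploids sampled at the final generation.
#' @param seed Optional integer seed; all randomness in the run flows from
#'   it.
#' @param max_sites Refuse configurations whose expected segregating-site
#'   count exceeds this cap.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n = 200, sequence_length_bp = 5e5, mutation_rate = 1e-7,
#'                   recomb_rate_cM_Mb = 2, model = "neutral",
#'                   n_generations = 50, sample_size = 20, seed = 1)
#' @export
sim_config <- function(n = NULL, census_trajectory = NULL,
                       sequence_length_bp, mutation_rate,
                       recomb_rate_cM_Mb = NULL, map = NULL,
                       model = c("neutral", "bs", "ss", "od"), dfe = NULL,
                       selfing = 0, n_generations,
                       burn_in = c("equilibrium_init", "full"),
                       sample_size, seed = NULL, max_sites = 2e6) {
  model <- match.arg(model)
  burn_in <- match.arg(burn_in)
  if (is.null(census_trajectory)) {
    stopifnot(!is.null(n))
    census_trajectory <- tibble::tibble(generation = 0L, n = as.integer(n))
  }
  census_trajectory <- tibble::as_tibble(census_trajectory)
  stopifnot(all(c("generation", "n") %in% names(census_trajectory)))
  ct <- dplyr::arrange(census_trajectory, .data$generation)
  if (ct$generation[1] != 0)
    stop("census_trajectory must start at generation 0", call. = FALSE)
  if (is.unsorted(ct$generation, strictly = TRUE))
    stop("census_trajectory generation indices must be strictly increasing",
         call. = FALSE)
  if (any(ct$n < 2))
    stop("census sizes must be >= 2", call. = FALSE)
  if (any(ct$generation > n_generations))
    stop("census_trajectory references generation ", max(ct$generation),
         " beyond n_generations = ", n_generations, call. = FALSE)
  stopifnot(sequence_length_bp >= 1, mutation_rate >= 0,
            is.finite(mutation_rate * sequence_length_bp),
            selfing >= 0, selfing <= 1, n_generations >= 0,
            sample_size >= 1)
  if (is.null(map)) {
    stopifnot(!is.null(recomb_rate_cM_Mb))
    map <- recomb_map(recomb_rate_cM_Mb, sequence_length_bp)
  }
  stopifnot(inherits(map, "recomb_map"), map$L == sequence_length_bp)
  if (is.null(dfe)) dfe <- dfe_config(model)
  stopifnot(inherits(dfe, "dfe_config"), dfe$model == model)
  structure(
    list(census_trajectory = ct,
         sequence_length_bp = as.double(sequence_length_bp),
         mutation_rate = mutation_rate, map = map,
         model = model, dfe = dfe, selfing = selfing,
         n_generations = as.integer(n_generations), burn_in = burn_in,
         sample_size = as.integer(sample_size),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         rescale_factor = 1,
         max_sites = as.integer(max_sites)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  ns <- x$census_trajectory$n
  cat(sprintf(paste0("<sim_config> model=%s N=%s L=%s bp mu=%.3g map=%.4g cM ",
                     "beta=%g gens=%d sample=%d init=%s\n"),
              x$model, paste(ns, collapse = ">"),
              format(x$sequence_length_bp, big.mark = ","), x$mutation_rate,
              100 * map_length(x$map), x$selfing, x$n_generations,
              x$sample_size, x$burn_in))
  invisible(x)
}

# census size at each generation 0..n_generations
expand_census <- function(config) {
  ct <- config$census_trajectory
  idx <- findInterval(0:config$n_generations, ct$generation)
  as.integer(ct$n[idx])
}

#' Rescale a scenario by a factor Q
#'
#' Standard population-genetic rescaling so that large scenarios run at
#' desk scale: `N' = N/Q`, generations are divided by `Q`, and `mu`,
#' recombination rates and selection coefficients are multiplied by `Q`.
#' The compound parameters `N mu`, `N x (map length)` and `N s` - which
#' control diversity, LD decay and the strength of selection - are
#' preserved.
#'
#' @param config A [sim_config()].
#' @param Q Rescaling factor, `>= 1`; `N/Q` must stay `>= 20`.
#' @return A rescaled `sim_config` with `rescale_factor = Q` recorded.
#' @examples
#' cfg <- sim_config(n = 10000, sequence_length_bp = 1e6,
#'                   mutation_rate = 1e-9, recomb_rate_cM_Mb = 1,
#'                   model = "neutral", n_generations = 1000,
#'                   sample_size = 50)
#' rescale_config(cfg, 10)$census_trajectory$n  # 1000
#' @export
rescale_config <- function(config, Q) {
  stopifnot(inherits(config, "sim_config"), is.numeric(Q), Q >= 1)
  if (Q == 1) return(config)
  ct <- config$census_trajectory
  if (any(ct$n / Q < 20))
    stop("rescaled census N/Q = ", min(ct$n) / Q,
         " is below 20; choose a smaller Q", call. = FALSE)
  mu2 <- config$mutation_rate * Q
  if (mu2 > 1)
    stop("rescaled mutation rate exceeds 1; Q too large", call. = FALSE)
  map <- config$map
  map2 <- recomb_map(map$rates_cM_Mb * Q, map$L,
                     starts_bp = map$bp[-length(map$bp)])
  ct2 <- tibble::tibble(generation = as.integer(round(ct$generation / Q)),
                        n = as.integer(round(ct$n / Q)))
  if (is.unsorted(ct2$generation, strictly = TRUE) && nrow(ct2) > 1)
    stop("rescaled census trajectory collapses change points; Q too large",
         call. = FALSE)
  dfe2 <- config$dfe
  dfe2$gamma_mean_abs_s <- dfe2$gamma_mean_abs_s * Q
  dfe2$fixed_s <- dfe2$fixed_s * Q
  if (dfe2$fixed_s * max(1, dfe2$fixed_h) >= 1 && config$model == "od")
    stop("rescaled overdominant effect gives fitness >= 2 per locus; Q too large",
         call. = FALSE)
  out <- config
  out$census_trajectory <- ct2
  out$mutation_rate <- mu2
  out$map <- map2
  out$dfe <- dfe2
  out$n_generations <- as.integer(round(config$n_generations / Q))
  out$sample_size <- min(config$sample_size, min(ct2$n))
  out$rescale_factor <- config$rescale_factor * Q
  out
}
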