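#' Haplotype sample container
#'
#' A sample of `n_h` haplotypes at `S` segregating sites: a 0/1 matrix
#' (rows = haplotypes, columns = sites sorted by position), physical
#' positions (0-based bp), cumulative map positions (Morgans) and the
#' chromosome of each site.  Columns fixed or lost within the sample are
#' not allowed; drop them with `drop_monomorphic = TRUE`.
#'
#' @param matrix Integer/numeric matrix of 0/1 allele states.
#' @param positions_bp Per-site physical positions (sorted within
#'   chromosome).
#' @param map_morgans Per-site cumulative map positions.
#' @param chrom Chromosome id per site (scalar recycled).
#' @param phased Logical: rows are true haplotypes (`TRUE`) or the matrix
#'   holds per-individual genotype dosages 0/1/2 (`FALSE`).
#' @param drop_monomorphic Drop columns with no variation instead of
#'   erroring.
#' @return An object of class `hap_sample`.
#' @export
hap_sample <- function(matrix, positions_bp, map_morgans,
                       chrom = "1", phased = TRUE,
                       drop_monomorphic = FALSE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  S <- ncol(matrix)
  stopifnot(length(positions_bp) == S, length(map_morgans) == S)
  chrom <- rep_len(as.character(chrom), S)
  for (ch in unique(chrom)) {
    j <- chrom == ch
    if (is.unsorted(positions_bp[j]))
      stop("positions_bp must be sorted within chromosome", call. = FALSE)
    if (is.unsorted(map_morgans[j]))
      stop("map_morgans must be non-decreasing with positions_bp",
           call. = FALSE)
  }
  top <- if (phased) 1L else 2L
  cs <- colSums(matrix)
  mono <- cs == 0L | cs == nrow(matrix) * top
  if (any(mono)) {
    if (!drop_monomorphic)
      stop(sum(mono), " monomorphic column(s) in hap_sample; ",
           "use drop_monomorphic = TRUE", call. = FALSE)
    matrix <- matrix[, !mono, drop = FALSE]
    positions_bp <- positions_bp[!mono]
    map_morgans <- map_morgans[!mono]
    chrom <- chrom[!mono]
  }
  structure(
    list(matrix = matrix, positions_bp = positions_bp,
         map_morgans = map_morgans, chrom = chrom, phased = phased,
         n_ind = if (phased) nrow(matrix) / 2 else nrow(matrix)),
    class = "hap_sample")
}

#' @export
print.hap_sample <- function(x, ...) {
  cat(sprintf("<hap_sample> %d %s x %d sites, %d chromosome(s)\n",
              nrow(x$matrix), if (x$phased) "haplotypes" else "genotypes",
              ncol(x$matrix), length(unique(x$chrom))))
  invisible(x)
}

#' Allele frequencies of a haplotype sample
#' @param sample A [hap_sample()].
#' @return Derived-allele frequency per site.
#' @export
allele_freq <- function(sample) {
  stopifnot(inherits(sample, "hap_sample"))
  colMeans(sample$matrix) / (if (sample$phased) 1 else 2)
}

#' Collapse a phased sample to genotype dosages
#'
#' Pairs consecutive haplotype rows (2i-1, 2i) into one individual and
#' sums them, giving 0/1/2 dosages, as when phase is unknown.
#' @param sample A phased [hap_sample()].
#' @export
as_unphased <- function(sample) {
  stopifnot(inherits(sample, "hap_sample"))
  if (!sample$phased) return(sample)
  m <- sample$matrix
  g <- m[seq(1, nrow(m), 2), , drop = FALSE] +
       m[seq(2, nrow(m), 2), , drop = FALSE]
  hap_sample(g, sample$positions_bp, sample$map_morgans, sample$chrom,
             phased = FALSE, drop_monomorphic = TRUE)
}

new_population <- function(generation, haplotypes, registry,
                           family_sizes = NULL) {
  structure(
    list(generation = as.integer(generation), haplotypes = haplotypes,
         registry = registry, family_sizes = family_sizes,
         n = length(haplotypes) / 2),
    class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("<wf_population> generation %d, N = %d, %d segregating site(s)\n",
              x$generation, x$n, sum(x$registry$active)))
  invisible(x)
}

#' Initialise a population
#'
#' Under `burn_in = "equilibrium_init"` the population is seeded at the
#' neutral mutation-drift equilibrium: the number of segregating sites
#' with derived count `i` (of `2N`) is Poisson with mean `theta L / i`
#' where `theta = 4 N mu` per site, positions are uniform (infinite
#' sites), and the `i` carrier haplotypes of each site are drawn
#' independently across sites, i.e. at linkage equilibrium.  Under
#' `burn_in = "full"` the population starts mutation-free.
#'
#' @param config A [sim_config()].  If `config$seed` is set, the RNG is
#'   seeded before drawing.
#' @return A `wf_population` at generation 0.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$census_trajectory$n[1]
  twoN <- 2L * N
  L <- config$sequence_length_bp
  reg <- tibble::tibble(position_bp = numeric(0), map_morgans = numeric(0),
                        s = numeric(0), h = numeric(0),
                        origin = integer(0), active = logical(0))
  haps <- rep(list(integer(0)), twoN)
  if (config$burn_in == "equilibrium_init" && config$mutation_rate > 0) {
    thetaL <- 4 * N * config$mutation_rate * L
    i <- seq_len(twoN - 1)
    expected_S <- thetaL * sum(1 / i)
    if (expected_S > config$max_sites)
      stop("expected segregating-site count ", round(expected_S),
           " exceeds max_sites = ", config$max_sites,
           "; lower N*mu*L or raise max_sites", call. = FALSE)
    counts <- rpois(twoN - 1, thetaL / i)
    S <- sum(counts)
    if (S > 0) {
      freqs <- rep.int(i, counts)
      pos <- sort(sample.int(L, S)) - 1   # unique 0-based positions
      freqs <- sample(freqs)              # decouple frequency from position
      carriers <- lapply(freqs, function(k) sample.int(twoN, k))
      hap_of <- unlist(carriers, use.names = FALSE)
      site_of <- rep.int(seq_len(S), freqs)
      haps <- unname(split(site_of, factor(hap_of, levels = seq_len(twoN))))
      reg <- tibble::tibble(
        position_bp = as.double(pos),
        map_morgans = map_position(config$map, pos),
        s = 0, h = 0.5, origin = 0L, active = TRUE)
    }
  }
  new_population(0L, haps, reg)
}

evolve_population <- function(pop, config, census) {
  res <- cpp_evolve(
    pop$haplotypes,
    pop$registry$position_bp, pop$registry$map_morgans,
    pop$registry$s, pop$registry$h, pop$registry$origin,
    pop$registry$active,
    as.integer(census), config$mutation_rate, config$sequence_length_bp,
    config$map$bp, config$map$morgans,
    config$selfing, dfe_kind_code(config$dfe), config$dfe$p_selected,
    config$dfe$gamma_shape,
    config$dfe$gamma_mean_abs_s / config$dfe$gamma_shape,
    config$dfe$fixed_s, config$dfe$fixed_h,
    pop$generation, config$max_sites)
  reg <- tibble::tibble(position_bp = res$pos, map_morgans = res$mpos,
                        s = res$s, h = res$h, origin = res$origin,
                        active = res$active)
  out <- new_population(pop$generation + length(census), res$haplotypes,
                        reg, family_sizes = res$family_sizes)
  attr(out, "vk") <- res$vk
  attr(out, "kbar") <- res$kbar
  attr(out, "fixed") <- res$fixed_total
  out
}

#' Advance a population by one generation
#'
#' One round of Wright-Fisher reproduction: each of the `n_next` offspring
#' is selfed with probability `beta` (one parent drawn with probability
#' proportional to fitness, both gametes from it) or outcrossed (two
#' fitness-weighted parents drawn independently, with replacement).  Each
#' gamete receives Poisson(map length) crossovers at map-uniform positions
#' and Poisson(`mu L`) new mutations at uniform bp positions (re-drawn on
#' collision).  Fixed and lost mutations are pruned; gamete counts per
#' parent are recorded in `family_sizes`.
#'
#' @param pop A `wf_population`.
#' @param config A [sim_config()].
#' @param n_next Census size of the offspring generation; defaults to the
#'   config trajectory value at `pop$generation + 1`.
#' @return The offspring `wf_population`.
#' @export
step_generation <- function(pop, config, n_next = NULL) {
  stopifnot(inherits(pop, "wf_population"), inherits(config, "sim_config"))
  if (is.null(n_next)) {
    cens <- expand_census(config)
    g <- min(pop$generation + 1L, length(cens) - 1L) + 1L
    n_next <- cens[g]
  }
  evolve_population(pop, config, n_next)
}

sample_haplotypes <- function(pop, n_ind) {
  if (n_ind > pop$n)
    stop("sample_size ", n_ind, " exceeds final census ", pop$n,
         call. = FALSE)
  ids <- sort(sample.int(pop$n, n_ind))
  rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  active <- which(pop$registry$active)
  col_of <- integer(nrow(pop$registry))
  ord <- active[order(pop$registry$position_bp[active])]
  col_of[ord] <- seq_along(ord)
  m <- matrix(0L, nrow = length(rows), ncol = length(ord))
  for (k in seq_along(rows)) {
    h <- pop$haplotypes[[rows[k]]]
    if (length(h)) m[k, col_of[h]] <- 1L
  }
  hap_sample(m, pop$registry$position_bp[ord],
             pop$registry$map_morgans[ord],
             chrom = "1", phased = TRUE, drop_monomorphic = TRUE)
}

#' Run a full forward simulation
#'
#' Initialises the population (see [initialize_population()]), iterates
#' [step_generation()] for `n_generations` honouring the census
#' trajectory, then samples `sample_size` diploids without replacement at
#' the final generation.
#'
#' @param config A [sim_config()].
#' @return An object of class `wf_sim`: a list with
#'   * `sample` - the final [hap_sample()];
#'   * `pedigree` - tibble of per-generation census, mean gamete count and
#'     variance of family sizes `Vk`;
#'   * `family_sizes` - final-generation gamete counts per parent;
#'   * `diversity` - one-row tibble with the sample's segregating sites
#'     `S`, per-site nucleotide diversity `pi` and the realised census;
#'   * `population` - the final `wf_population`;
#'   * `n_fixed`, `config`.
#' @examples
#' cfg <- sim_config(n = 100, sequence_length_bp = 2e5, mutation_rate = 1e-7,
#'                   recomb_rate_cM_Mb = 2, model = "neutral",
#'                   n_generations = 20, sample_size = 30, seed = 42)
#' sim <- run_simulation(cfg)
#' glance(sim)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cens <- expand_census(config)
  pop0 <- initialize_population(config)
  if (config$n_generations > 0) {
    pop <- evolve_population(pop0, config, cens[-1])
    vk <- attr(pop, "vk"); kbar <- attr(pop, "kbar")
    n_fixed <- attr(pop, "fixed")
  } else {
    pop <- pop0
    vk <- numeric(0); kbar <- numeric(0); n_fixed <- 0
  }
  samp <- sample_haplotypes(pop, config$sample_size)
  pedigree <- tibble::tibble(
    generation = seq_len(config$n_generations),
    census = cens[-1], mean_k = kbar, vk = vk)
  pi_site <- sample_pi(samp, config$sequence_length_bp)
  diversity <- tibble::tibble(
    n_sites = ncol(samp$matrix), pi = pi_site,
    final_census = pop$n, n_fixed = n_fixed)
  structure(
    list(sample = samp, pedigree = pedigree,
         family_sizes = pop$family_sizes, diversity = diversity,
         population = pop, n_fixed = n_fixed, config = config),
    class = "wf_sim")
}

# unbiased per-site nucleotide diversity of a phased sample, averaged over
# a sequence of denom_bp sites (monomorphic sites contribute zero)
sample_pi <- function(sample, denom_bp) {
  p <- allele_freq(sample)
  nh <- nrow(sample$matrix)
  sum(2 * p * (1 - p)) * nh / (nh - 1) / denom_bp
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf("<wf_sim> %s model, %d generations, sampled %d diploids, %d sites, pi = %.3g\n",
              x$config$model, x$config$n_generations, x$config$sample_size,
              x$diversity$n_sites, x$diversity$pi))
  invisible(x)
}

#' @rdname run_simulation
#' @param x A `wf_sim` object.
#' @param ... Unused.
#' @export
tidy.wf_sim <- function(x, ...) x$pedigree

#' @rdname run_simulation
#' @export
glance.wf_sim <- function(x, ...) {
  dplyr::mutate(x$diversity,
                mean_vk = mean(x$pedigree$vk),
                ne_pi = ne_from_pi(.data$pi, x$config$mutation_rate))
}
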