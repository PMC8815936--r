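#' Distribution of fitness effects (DFE) configuration
#'
#' Parameterises how selection coefficients are assigned to new mutations
#' under the four mutation models:
#'
#' * `neutral` - every mutation has `s = 0`.
#' * `bs` (background selection) - a fraction `p_selected` (default 5%) of
#'   new mutations is deleterious, with `|s|` drawn from a gamma
#'   distribution (shape 0.2, mean 0.02) and `h = 0.5` (additive).
#' * `ss` (selective sweeps) - a fraction (default 0.1%) is advantageous,
#'   gamma-distributed with the same shape and mean, `h = 0.5`.
#' * `od` (overdominance) - a fraction (default 0.01%) has fixed
#'   `s = 0.02` and dominance `h = 1.5` (heterozygote advantage).
#'
#' Gamma draws for deleterious effects that would give `s <= -1` are
#' re-drawn: with shape 0.2 the tail is long and a fitness below zero for a
#' single homozygote is meaningless.
#'
#' @param model One of `"neutral"`, `"bs"`, `"ss"`, `"od"`.
#' @param p_selected Fraction of new mutations that are non-neutral.
#'   Defaults to the per-model values above.
#' @param gamma_shape,gamma_mean_abs_s Gamma shape and mean of `|s|` for
#'   the `bs` and `ss` models.
#' @param fixed_s,fixed_h Effect and dominance for the `od` model.
#' @return A list of class `dfe_config`.
#' @examples
#' dfe_config("bs")
#' draw_fitness_effects(5, dfe_config("ss"))
#' @export
dfe_config <- function(model = c("neutral", "bs", "ss", "od"),
                       p_selected = NULL,
                       gamma_shape = 0.2, gamma_mean_abs_s = 0.02,
                       fixed_s = 0.02, fixed_h = 1.5) {
  model <- match.arg(model)
  if (is.null(p_selected))
    p_selected <- switch(model, neutral = 0, bs = 0.05, ss = 0.001, od = 1e-4)
  stopifnot(p_selected >= 0, p_selected <= 1,
            gamma_shape > 0, gamma_mean_abs_s > 0)
  structure(
    list(model = model, p_selected = p_selected,
         gamma_shape = gamma_shape, gamma_mean_abs_s = gamma_mean_abs_s,
         fixed_s = fixed_s, fixed_h = fixed_h),
    class = "dfe_config")
}

dfe_kind_code <- function(dfe) {
  match(dfe$model, c("neutral", "bs", "ss", "od")) - 1L
}

#' Draw fitness effects for new mutations
#'
#' Classifies `n` new mutations under a DFE: each is neutral
#' (`s = 0, h = 0.5`) with probability `1 - p_selected`, otherwise receives
#' a model-specific selection coefficient (see [dfe_config()]).
#'
#' @param n Number of mutations to classify.
#' @param dfe A [dfe_config()].
#' @return A tibble with columns `s`, `h` and logical `selected`.
#' @export
draw_fitness_effects <- function(n, dfe) {
  stopifnot(inherits(dfe, "dfe_config"), n >= 0)
  s <- numeric(n)
  h <- rep(0.5, n)
  sel <- runif(n) < dfe$p_selected
  k <- sum(sel)
  if (k > 0) {
    if (dfe$model == "bs") {
      scale <- dfe$gamma_mean_abs_s / dfe$gamma_shape
      g <- stats::rgamma(k, shape = dfe$gamma_shape, scale = scale)
      while (any(bad <- g >= 1))
        g[bad] <- stats::rgamma(sum(bad), shape = dfe$gamma_shape, scale = scale)
      s[sel] <- -g
    } else if (dfe$model == "ss") {
      s[sel] <- stats::rgamma(k, shape = dfe$gamma_shape,
                              scale = dfe$gamma_mean_abs_s / dfe$gamma_shape)
    } else if (dfe$model == "od") {
      s[sel] <- dfe$fixed_s
      h[sel] <- dfe$fixed_h
    } else {
      sel[] <- FALSE
    }
  }
  tibble::tibble(s = s, h = h, selected = sel)
}

#' Multiplicative fitness of one diploid individual
#'
#' Fitness is the product over loci of 1 (wild-type homozygote),
#' `1 + s h` (heterozygote) and `1 + s` (mutant homozygote), floored at
#' zero.  The two haplotypes are given as vectors of mutation ids (rows of
#' `registry`).
#'
#' @param hap1,hap2 Integer vectors of mutation ids carried by each
#'   haplotype.
#' @param registry A data frame with per-mutation columns `s` and `h`,
#'   indexed by id.
#' @return A single fitness value `>= 0`.
#' @examples
#' reg <- tibble::tibble(s = c(-0.02, -0.02), h = c(0.5, 0.5))
#' individual_fitness(1L, integer(0), reg)   # one het: 0.99
#' individual_fitness(1:2, integer(0), reg)  # two hets: 0.9801
#' @export
individual_fitness <- function(hap1, hap2, registry) {
  stopifnot(all(hap1 >= 1), all(hap2 >= 1),
            all(hap1 <= nrow(registry)), all(hap2 <= nrow(registry)))
  hom <- intersect(hap1, hap2)
  het <- setdiff(union(hap1, hap2), hom)
  w <- 1
  if (length(hom))
    w <- w * prod(1 + registry$s[hom])
  if (length(het))
    w <- w * prod(1 + registry$s[het] * registry$h[het])
  max(w, 0)
}

#' Critical recombination distance for sweep-generated LD
#'
#' A sweeping beneficial allele with homozygous advantage `s` measurably
#' builds up linkage disequilibrium between flanking neutral loci only when
#' their recombination distance to the selected site is below about
#' `0.1 * s` (Stephan-type hitch-hiking result).
#'
#' @param s Homozygous selection coefficient of the sweeping allele.
#' @return Critical recombination fraction `0.1 * s`.
#' @examples
#' sweep_critical_c(0.02)  # 0.002
#' @export
sweep_critical_c <- function(s) {
  stopifnot(is.numeric(s), all(s >= 0))
  0.1 * s
}
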