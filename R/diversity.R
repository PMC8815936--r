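#' Diversity-based effective size: pi / (4 mu)
#'
#' At mutation-drift equilibrium the expected per-site nucleotide
#' diversity of a neutral population is `4 Ne mu`, so `Ne = pi / (4 mu)`.
#' Under linked selection pi - and therefore this estimate - is reduced,
#' most strongly where recombination is low.
#'
#' @param pi Per-site nucleotide diversity (`>= 0`).
#' @param mu Per-bp per-generation mutation rate (`> 0`).
#' @examples
#' ne_from_pi(4e-5, 1e-8)  # 1000
#' @export
ne_from_pi <- function(pi, mu) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  stopifnot(all(pi >= 0))
  pi / (4 * mu)
}

#' Analytic effective size under partial self-fertilisation
#'
#' With a proportion `beta` of selfed offspring,
#' `Ne = N / (1 + alpha)` where `alpha = beta / (2 - beta)`; random mating
#' (`beta = 0`) gives `Ne = N` and complete selfing gives `N/2`.
#'
#' @param N Census size (diploids).
#' @param beta Selfed-offspring proportion in `[0, 1]`.
#' @examples
#' ne_vk_analytic(1000, 0.5)  # 750
#' @export
ne_vk_analytic <- function(N, beta) {
  stopifnot(all(N >= 1), all(beta >= 0), all(beta <= 1))
  alpha <- beta / (2 - beta)
  N / (1 + alpha)
}

#' Effective size from realised variance of family sizes
#'
#' For a constant-size diploid population, the pedigree (variance of
#' progeny numbers) effective size is `Ne = (4N - 2) / (Vk + 2)` where
#' `Vk` is the variance of per-parent gamete counts.  Under neutral
#' random mating gamete counts are multinomial, `Vk` is close to 2 and
#' `Ne` is close to `N`.
#'
#' @param family_gamete_counts Integer vector of gamete counts per parent
#'   (length `N`); must sum to `2N`.
#' @param N Number of parents; defaults to
#'   `length(family_gamete_counts)`.
#' @examples
#' ne_vk_from_pedigree(rep(2, 100))  # (4*100 - 2) / (0 + 2) = 199
#' @export
ne_vk_from_pedigree <- function(family_gamete_counts, N = NULL) {
  if (is.null(N)) N <- length(family_gamete_counts)
  stopifnot(length(family_gamete_counts) == N, N >= 1)
  if (sum(family_gamete_counts) != 2 * N)
    stop("family gamete counts must sum to 2N (gamete conservation)",
         call. = FALSE)
  vk <- if (N > 1) var(family_gamete_counts) else 0
  (4 * N - 2) / (vk + 2)
}
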