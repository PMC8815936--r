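#' Pairwise linkage disequilibrium (r2) at binned recombination distances
#'
#' Computes squared allelic correlation for pairs of segregating sites.
#' For phased samples r2 is the squared correlation of haplotype allele
#' states, identical to `D^2 / (p_A p_a p_B p_b)`; for unphased samples it
#' is the squared correlation of genotype dosages (the Burrows composite
#' measure normalised under Hardy-Weinberg).  The recombination fraction
#' `c` per pair comes from the map distance via Haldane's function.
#'
#' Sites with minor allele frequency below `maf_min` are excluded first;
#' if more than `max_pairs` pairs survive the `c` filter, a uniform random
#' subsample of `max_pairs` is taken (seeded by the caller's RNG state).
#' Only within-chromosome pairs are formed.
#'
#' @param sample A [hap_sample()].
#' @param c_min,c_max Recombination-fraction limits for retained pairs.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param max_pairs Cap on the number of pairs (default 5e6).
#' @param max_snps If the post-filter site count exceeds this, sites are
#'   thinned deterministically (evenly spaced) before pairing.
#' @return A tibble with columns `site_i`, `site_j`, `dist_m` (Morgans),
#'   `c` and `r2`.
#' @examples
#' m <- rbind(c(1,1),c(1,1),c(1,1),c(1,1),c(1,0),
#'            c(0,1),c(0,0),c(0,0),c(0,0),c(0,0))
#' s <- hap_sample(m, c(100, 200), c(0.001, 0.002))
#' pairwise_r2(s, maf_min = 0)$r2   # 0.36
#' @export
pairwise_r2 <- function(sample, c_min = 0.001, c_max = 0.5,
                        maf_min = 0.05, max_pairs = 5e6,
                        max_snps = Inf) {
  stopifnot(inherits(sample, "hap_sample"), c_min > 0, c_max <= 0.5,
            c_min < c_max)
  p <- allele_freq(sample)
  if (any(p == 0 | p == 1))
    stop("monomorphic site encountered in pairwise_r2", call. = FALSE)
  keep <- pmin(p, 1 - p) >= maf_min
  if (sum(keep) < 2)
    stop("fewer than 2 sites pass the MAF filter", call. = FALSE)
  idx <- which(keep)
  if (length(idx) > max_snps)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_snps)))]
  X <- sample$matrix[, idx, drop = FALSE]
  mp <- sample$map_morgans[idx]
  ch <- sample$chrom[idx]
  r2 <- suppressWarnings(cor(X))^2
  S <- length(idx)
  ii <- rep(seq_len(S), times = S)
  jj <- rep(seq_len(S), each = S)
  ut <- ii < jj & ch[ii] == ch[jj]
  ii <- ii[ut]; jj <- jj[ut]
  d <- abs(mp[jj] - mp[ii])
  cc <- haldane_c(d)
  sel <- cc >= c_min & cc <= c_max
  ii <- ii[sel]; jj <- jj[sel]; d <- d[sel]; cc <- cc[sel]
  if (length(ii) > max_pairs) {
    take <- sample.int(length(ii), max_pairs)
    ii <- ii[take]; jj <- jj[take]; d <- d[take]; cc <- cc[take]
  }
  tibble::tibble(site_i = idx[ii], site_j = idx[jj],
                 dist_m = d, c = cc,
                 r2 = r2[cbind(ii, jj)])
}

#' Bin SNP pairs by recombination fraction
#'
#' Logarithmic bins over `[c_min, c_max]` (30 by default); bins holding
#' fewer than `min_pairs` pairs are dropped.
#'
#' @param pairs Output of [pairwise_r2()].
#' @param n_bins Number of logarithmic bins.
#' @param c_min,c_max Binning range.
#' @param min_pairs Minimum pairs per retained bin (default 100).
#' @return A tibble with `c_low`, `c_high`, `n_pairs`, `mean_c`,
#'   `mean_r2`.
#' @export
bin_pairs <- function(pairs, n_bins = 30, c_min = 0.001, c_max = 0.5,
                      min_pairs = 100) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  edges <- exp(seq(log(c_min), log(c_max), length.out = n_bins + 1))
  b <- cut(pairs$c, edges, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(b)
  out <- tibble::tibble(bin = b[ok], c = pairs$c[ok], r2 = pairs$r2[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_c = mean(.data$c),
                     mean_r2 = mean(.data$r2), .groups = "drop") |>
    dplyr::mutate(c_low = edges[.data$bin], c_high = edges[.data$bin + 1]) |>
    dplyr::filter(.data$n_pairs >= min_pairs) |>
    dplyr::select("c_low", "c_high", "n_pairs", "mean_c", "mean_r2")
  out
}

#' Effective size from one recombination-distance bin
#'
#' Inverts the drift-recombination expectation of r2 (Sved-type): with the
#' sampling correction subtracted, `ne = (1 / r2_adj - alpha) / (4 c)`.
#' For phased data the correction is `1/n_haplotypes` and `alpha = 1`; for
#' unphased (composite) data it is `1/n_individuals` and `alpha = 2`.
#' Estimates with non-positive adjusted r2 (or non-finite values) are
#' flagged invalid rather than dropped.
#'
#' @param mean_r2,mean_c Bin summaries (vectors allowed).
#' @param n Number of haplotypes (phased) or individuals (unphased).
#' @param phased Logical.
#' @return A tibble with `r2_adj`, `ne_hat` and logical `valid`.
#' @examples
#' ne_from_bin(1 / 11 + 1 / 200, 0.0025, n = 200)$ne_hat  # 1000
#' @export
ne_from_bin <- function(mean_r2, mean_c, n, phased = TRUE) {
  stopifnot(n >= 4, all(mean_c > 0))
  alpha <- if (phased) 1 else 2
  r2_adj <- mean_r2 - 1 / n
  ne <- (1 / r2_adj - alpha) / (4 * mean_c)
  valid <- is.finite(ne) & r2_adj > 0 & ne >= 0
  ne[!valid & !(is.finite(ne) & ne == 0)] <- NA_real_
  tibble::tibble(r2_adj = r2_adj, ne_hat = ne, valid = valid)
}

#' Historical Ne trajectory from binned LD
#'
#' Maps each recombination-distance bin to a time point `t = 1/(2 mean_c)`
#' generations in the past (LD at distance `c` mainly reflects drift
#' around that horizon) and attaches the bin's Ne estimate.
#'
#' @param bins Output of [bin_pairs()].
#' @param n Number of haplotypes (phased) or individuals (unphased).
#' @param phased Logical.
#' @return A tibble of class `ne_trajectory`, sorted by `t` ascending,
#'   with columns `t`, `ne_hat`, `valid`, `mean_c`, `mean_r2`, `n_pairs`.
#' @export
historical_trajectory <- function(bins, n, phased = TRUE) {
  stopifnot(is.data.frame(bins))
  if (nrow(bins) == 0) stop("empty bin list", call. = FALSE)
  est <- ne_from_bin(bins$mean_r2, bins$mean_c, n, phased)
  out <- tibble::tibble(
    t = 1 / (2 * bins$mean_c), ne_hat = est$ne_hat, valid = est$valid,
    mean_c = bins$mean_c, mean_r2 = bins$mean_r2, n_pairs = bins$n_pairs) |>
    dplyr::arrange(.data$t)
  class(out) <- c("ne_trajectory", class(out))
  out
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("<ne_trajectory> %d bins, t in [%.3g, %.3g] generations\n",
              nrow(x), min(x$t), max(x$t)))
  NextMethod()
}

#' @rdname historical_trajectory
#' @param x An `ne_trajectory`.
#' @param ... Unused.
#' @export
tidy.ne_trajectory <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname historical_trajectory
#' @param c_window Range of `mean_c` averaged by `glance` (the window the
#'   headline Ne summary uses).
#' @export
glance.ne_trajectory <- function(x, c_window = c(0.0025, 0.025), ...) {
  sel <- x$valid & x$mean_c >= c_window[1] & x$mean_c <= c_window[2]
  tibble::tibble(n_bins = nrow(x), n_valid = sum(x$valid),
                 n_in_window = sum(sel),
                 ne_ld = mean(x$ne_hat[sel]))
}

#' @rdname historical_trajectory
#' @param object An `ne_trajectory`.
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(x = .data$t, y = .data$ne_hat)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "generations in the past (1 / 2c)",
                  y = expression(hat(N)[e])) +
    ggplot2::theme_minimal()
}

#' LD-based Ne of a sample
#'
#' The full pipeline: pairwise r2, logarithmic c-bins, Sved inversion,
#' then the unweighted mean of valid bin estimates whose mean c lies in
#' `c_window` (default `[0.0025, 0.025]`, i.e. horizons of roughly 20-200
#' generations).
#'
#' @inheritParams pairwise_r2
#' @inheritParams bin_pairs
#' @param c_window Range of bin `mean_c` averaged into the summary value.
#' @param phased Force the phased or composite correction; defaults to
#'   the sample's phasing.  Requesting the phased estimator on unphased
#'   data is an error.
#' @return One-row tibble with `ne_ld`, `n_bins`, `n_pairs`, and the
#'   trajectory as an attribute `"trajectory"`.
#' @export
estimate_ne_ld <- function(sample, c_window = c(0.0025, 0.025),
                           c_min = 0.001, c_max = 0.5, maf_min = 0.05,
                           n_bins = 30, min_pairs = 100, max_pairs = 5e6,
                           max_snps = Inf, phased = NULL) {
  if (is.null(phased)) phased <- sample$phased
  if (phased && !sample$phased)
    stop("sample is unphased; use the composite mode (phased = FALSE)",
         call. = FALSE)
  if (!phased && sample$phased) sample <- as_unphased(sample)
  n <- nrow(sample$matrix)
  pairs <- pairwise_r2(sample, c_min, c_max, maf_min, max_pairs, max_snps)
  bins <- bin_pairs(pairs, n_bins, c_min, c_max, min_pairs)
  traj <- historical_trajectory(bins, n, phased)
  sel <- traj$valid & traj$mean_c >= c_window[1] & traj$mean_c <= c_window[2]
  out <- tibble::tibble(ne_ld = mean(traj$ne_hat[sel]),
                        n_bins = sum(sel),
                        n_pairs = sum(traj$n_pairs[sel]))
  attr(out, "trajectory") <- traj
  out
}

#' Constant-size regional Ne from pooled short-range LD
#'
#' For one genomic window, pools all SNP pairs with recombination fraction
#' in `c_range` (default `[1/100, 1/50]` Morgans) into a single bin and
#' inverts it, using the unphased (composite) correction by default as
#' when genotype phase is unknown.  Windows providing fewer than
#' `min_pairs` pairs (default 250,000) are flagged as having insufficient
#' pairs; the estimate is still returned but `enough_pairs` is `FALSE`.
#'
#' @param sample A [hap_sample()] restricted to the window.
#' @param c_range Pooled recombination-fraction range.
#' @param min_pairs Minimum number of available pairs in `c_range`.
#' @param phased Use the phased correction instead of the composite one.
#' @param maf_min MAF filter.
#' @param max_snps Deterministic thinning cap before pair formation (the
#'   pair count for the `min_pairs` rule is computed before thinning).
#' @return One-row tibble: `ne_hat`, `n_pairs`, `mean_c`, `mean_r2`,
#'   `enough_pairs`, `valid`.
#' @export
regional_ne <- function(sample, c_range = c(0.01, 0.02),
                        min_pairs = 250000, phased = FALSE,
                        maf_min = 0.05, max_snps = 1500) {
  stopifnot(inherits(sample, "hap_sample"))
  if (phased && !sample$phased)
    stop("sample is unphased; use the composite mode (phased = FALSE)",
         call. = FALSE)
  if (!phased && sample$phased) sample <- as_unphased(sample)
  n <- nrow(sample$matrix)
  p <- allele_freq(sample)
  keep <- which(pmin(p, 1 - p) >= maf_min)
  empty <- tibble::tibble(ne_hat = NA_real_, n_pairs = 0L,
                          mean_c = NA_real_, mean_r2 = NA_real_,
                          enough_pairs = FALSE, valid = FALSE)
  if (length(keep) < 2) return(empty)
  # available pairs in range, before any thinning
  mp <- sample$map_morgans[keep]
  ch <- sample$chrom[keep]
  n_avail <- 0L
  for (cc in unique(ch)) {
    m <- sort(mp[ch == cc])
    d_lo <- -log(1 - 2 * c_range[1]) / 2   # invert Haldane
    d_hi <- -log(1 - 2 * c_range[2]) / 2
    lo <- findInterval(m + d_lo, m, left.open = TRUE)
    hi <- findInterval(m + d_hi, m)
    n_avail <- n_avail + sum(pmax(hi - lo, 0))
  }
  if (n_avail == 0) return(empty)
  pr <- pairwise_r2(sample, c_min = c_range[1], c_max = c_range[2],
                    maf_min = maf_min, max_snps = max_snps)
  if (nrow(pr) == 0) return(empty)
  est <- ne_from_bin(mean(pr$r2), mean(pr$c), n, phased = phased)
  tibble::tibble(ne_hat = (1 / (mean(pr$r2) - 1 / n) -
                             (if (phased) 1 else 2)) / (4 * mean(pr$c)),
                 n_pairs = as.integer(n_avail),
                 mean_c = mean(pr$c), mean_r2 = mean(pr$r2),
                 enough_pairs = n_avail >= min_pairs,
                 valid = est$valid)
}

#' Replicate simulation study of Ne estimators
#'
#' Runs `n_reps` independent simulations of one scenario and returns, per
#' replicate, the LD-based Ne (mean of c-window bins), the sample
#' diversity and the diversity-based Ne `pi/(4 mu)`.
#'
#' @param config A [sim_config()]; its `seed` field is ignored in favour
#'   of `base_seed + replicate`.
#' @param n_reps Number of replicates.
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`.
#' @param c_window Bin window averaged into `ne_ld`.
#' @param ... Passed to [estimate_ne_ld()].
#' @return A tibble with one row per replicate: `rep`, `ne_ld`, `pi`,
#'   `ne_pi`, `n_sites`, `mean_vk`.
#' @export
replicate_ne_study <- function(config, n_reps = 20, base_seed = 1,
                               c_window = c(0.0025, 0.025), ...) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    sim <- run_simulation(cfg)
    est <- estimate_ne_ld(sim$sample, c_window = c_window, ...)
    tibble::tibble(
      rep = r, ne_ld = est$ne_ld, pi = sim$diversity$pi,
      ne_pi = ne_from_pi(sim$diversity$pi, cfg$mutation_rate),
      n_sites = sim$diversity$n_sites,
      mean_vk = mean(sim$pedigree$vk))
  })
}
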