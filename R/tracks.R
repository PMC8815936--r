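#' Draw a heterogeneous recombination map
#'
#' Splits a chromosome of length `L` into `n_regions` equal-length
#' segments (70 by default, mirroring how simulated genomes are usually
#' regionalised when emulating human recombination heterogeneity) and
#' draws each segment's rate independently from a log-normal distribution
#' truncated to `rr_range`.  The default log-normal has mean 1 cM/Mb and
#' coefficient of variation 1, a reasonable stand-in for the empirical
#' distribution of human 2 cM window averages.
#'
#' @param L Chromosome length in bp.
#' @param n_regions Number of equal-length segments.
#' @param rr_meanlog,rr_sdlog Log-normal parameters of the segment rates
#'   (cM/Mb).  Defaults give mean 1, CV 1.
#' @param rr_range Truncation range (draws outside are re-drawn).
#' @return A [recomb_map()].
#' @export
sample_heterogeneous_map <- function(L, n_regions = 70,
                                     rr_meanlog = -log(2) / 2,
                                     rr_sdlog = sqrt(log(2)),
                                     rr_range = c(0.01, 5)) {
  stopifnot(n_regions >= 1, L >= n_regions)
  r <- rlnorm(n_regions, rr_meanlog, rr_sdlog)
  while (any(bad <- r < rr_range[1] | r > rr_range[2]))
    r[bad] <- rlnorm(sum(bad), rr_meanlog, rr_sdlog)
  recomb_map(r, L)
}

#' Synthetic annotation tracks for genomic windows
#'
#' Generates human-like per-window annotation values through a Gaussian
#' copula on window ranks:
#' * `gene_density` - Poisson(`gene_mean`) counts;
#' * `lof_count`, `missense_count` - Poisson counts positively coupled to
#'   gene density (targets `rho_lof_gene`, `rho_mis_gene`);
#' * `b_mean` - a background-selection statistic in (0, 1], decreasing in
#'   gene density (`rho_b_gene` < 0) and increasing in recombination rate
#'   (`rho_b_rr` > 0), mapped into `b_range`.
#'
#' Latent correlations are chosen so the realised Spearman couplings land
#' near the targets; the implied latent correlation matrix must be
#' positive semi-definite or an error is raised.
#'
#' @param windows A window tibble with an `rr_mean` column (e.g. from
#'   [partition_windows()]).
#' @param gene_mean Mean genes per window.
#' @param lof_per_gene,mis_per_gene Mean deleterious variants per gene.
#' @param rho_lof_gene,rho_mis_gene,rho_b_gene,rho_b_rr Spearman coupling
#'   targets (|rho| <= 1).
#' @param b_range Range of the B statistic.
#' @return `windows` with `gene_density`, `lof_count`, `missense_count`
#'   and `b_mean` columns appended.
#' @export
generate_tracks <- function(windows, gene_mean = 15,
                            lof_per_gene = 2, mis_per_gene = 10,
                            rho_lof_gene = 0.6, rho_mis_gene = 0.6,
                            rho_b_gene = -0.5, rho_b_rr = 0.5,
                            b_range = c(0.4, 1)) {
  stopifnot(is.data.frame(windows), "rr_mean" %in% names(windows),
            gene_mean > 0,
            all(abs(c(rho_lof_gene, rho_mis_gene, rho_b_gene,
                      rho_b_rr)) <= 1))
  n <- nrow(windows)
  # latent order: gene, lof, mis, b (rr enters via its rank transform)
  r_lg <- 2 * sin(pi * rho_lof_gene / 6)  # invert the Spearman-Gauss map
  r_mg <- 2 * sin(pi * rho_mis_gene / 6)
  r_bg <- 2 * sin(pi * rho_b_gene / 6)
  r_br <- 2 * sin(pi * rho_b_rr / 6)
  R <- diag(5)
  dimnames(R) <- rep(list(c("gene", "lof", "mis", "b", "rr")), 2)
  R["gene", "lof"] <- R["lof", "gene"] <- r_lg
  R["gene", "mis"] <- R["mis", "gene"] <- r_mg
  R["gene", "b"] <- R["b", "gene"] <- r_bg
  R["b", "rr"] <- R["rr", "b"] <- r_br
  R["lof", "mis"] <- R["mis", "lof"] <- r_lg * r_mg  # via shared gene load
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("coupling targets imply a non-positive-semi-definite latent ",
         "correlation matrix", call. = FALSE)
  # condition the latent field on the observed rr ranks
  z_rr <- stats::qnorm((rank(windows$rr_mean, ties.method = "average") - 0.5) / n)
  z <- matrix(rnorm(4 * n), n, 4)
  Rc <- R[1:4, 1:4] - tcrossprod(R[1:4, "rr"])   # conditional covariance
  mu_c <- outer(z_rr, R[1:4, "rr"])
  ch <- chol(Rc + diag(1e-10, 4))
  lat <- mu_c + z %*% ch
  u <- pnorm(lat)
  gene <- qpois(u[, 1], gene_mean)
  lof <- qpois(u[, 2], lof_per_gene * gene_mean)
  mis <- qpois(u[, 3], mis_per_gene * gene_mean)
  b <- b_range[1] + (b_range[2] - b_range[1]) * u[, 4]
  dplyr::mutate(windows, gene_density = gene, lof_count = lof,
                missense_count = mis, b_mean = b)
}

#' Simulate human-like windows end to end
#'
#' The work-horse behind the synthetic human-data stand-in: each window
#' is one independently simulated chromosome whose recombination rate is
#' drawn from the heterogeneous-map distribution, evolved under the
#' requested mutation model (background selection by default), sampled,
#' and summarised with [window_stats()].  Because background selection
#' erodes diversity fastest where recombination is low, the resulting
#' windows carry the empirical positive coupling between recombination
#' rate and nucleotide diversity, while regional LD-based Ne tracks the
#' (constant) demography.
#'
#' @param n_windows Number of windows (= chromosomes) to simulate.
#' @param N Census size per chromosome.
#' @param mu Mutation rate per bp per generation.
#' @param model Mutation model (default `"bs"`).
#' @param n_generations Forward generations after equilibrium
#'   initialisation.
#' @param sample_size Diploids sampled per chromosome.
#' @param window_cm Window genetic length (cM); each chromosome's
#'   physical length is chosen as `(window_cm + margin_cm) / RR`.
#' @param margin_cm Extra map length beyond the window.
#' @param rr_range Truncation range of the per-chromosome rate draw
#'   (cM/Mb); the desk-scale default keeps chromosome bp lengths bounded.
#' @param rr_meanlog,rr_sdlog Log-normal parameters of the rate draw.
#' @param base_seed Chromosome `k` is simulated with seed
#'   `base_seed + k`.
#' @param tracks Also attach copula-generated annotation tracks.
#' @param ... Passed to [window_stats()] (thence [regional_ne()]).
#' @return A window-statistics tibble (one row per window).
#' @export
simulate_humanlike_windows <- function(n_windows = 30, N = 150, mu = 4e-7,
                                       model = "bs", n_generations = 300,
                                       sample_size = 50, window_cm = 2,
                                       margin_cm = 0.2,
                                       rr_range = c(0.25, 5),
                                       rr_meanlog = -log(2) / 2,
                                       rr_sdlog = sqrt(log(2)),
                                       base_seed = 1, tracks = TRUE, ...) {
  stopifnot(n_windows >= 1)
  rows <- purrr::map_dfr(seq_len(n_windows), function(k) {
    set.seed(base_seed + k)
    rr <- rlnorm(1, rr_meanlog, rr_sdlog)
    while (rr < rr_range[1] || rr > rr_range[2])
      rr <- rlnorm(1, rr_meanlog, rr_sdlog)
    L <- ceiling((window_cm + margin_cm) / rr * 1e6)
    cfg <- sim_config(n = N, sequence_length_bp = L, mutation_rate = mu,
                      recomb_rate_cM_Mb = rr, model = model,
                      n_generations = n_generations,
                      sample_size = sample_size,
                      seed = base_seed + k)
    sim <- run_simulation(cfg)
    samp <- sim$sample
    samp$chrom <- rep(paste0("chr", k), length(samp$chrom))
    map_tab <- tibble::tibble(chrom = paste0("chr", k),
                              bp = cfg$map$bp, cm = 100 * cfg$map$morgans)
    win <- partition_windows(map_tab, window_cm)[1, , drop = FALSE]
    window_stats(samp, win, ...)
  })
  if (tracks) rows <- generate_tracks(rows)
  rows
}

#' Write a complete synthetic human-like dataset to disk
#'
#' Simulates `n_windows` chromosomes (see
#' [simulate_humanlike_windows()]), writes the pooled genotypes as a
#' minimal VCF, the genetic map as a three-column sidecar and the
#' annotation tracks as a BED-like TSV, so the genome-scan stage can be
#' exercised from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param n_windows,N,mu,model,n_generations,sample_size,window_cm,margin_cm
#'   See [simulate_humanlike_windows()].
#' @param rr_range,rr_meanlog,rr_sdlog Rate-draw parameters.
#' @param base_seed Seed; byte-identical outputs for equal seeds.
#' @return Invisibly, a list with the file paths (`vcf`, `map`, `tracks`)
#'   and the window tibble.
#' @export
generate_humanlike_dataset <- function(dir, n_windows = 5, N = 150,
                                       mu = 4e-7, model = "bs",
                                       n_generations = 300,
                                       sample_size = 50, window_cm = 2,
                                       margin_cm = 0.2,
                                       rr_range = c(0.25, 5),
                                       rr_meanlog = -log(2) / 2,
                                       rr_sdlog = sqrt(log(2)),
                                       base_seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- list(); poss <- list(); maps <- list(); chroms <- list()
  map_tabs <- list(); wins <- list()
  for (k in seq_len(n_windows)) {
    set.seed(base_seed + k)
    rr <- rlnorm(1, rr_meanlog, rr_sdlog)
    while (rr < rr_range[1] || rr > rr_range[2])
      rr <- rlnorm(1, rr_meanlog, rr_sdlog)
    L <- ceiling((window_cm + margin_cm) / rr * 1e6)
    cfg <- sim_config(n = N, sequence_length_bp = L, mutation_rate = mu,
                      recomb_rate_cM_Mb = rr, model = model,
                      n_generations = n_generations,
                      sample_size = sample_size, seed = base_seed + k)
    sim <- run_simulation(cfg)
    mats[[k]] <- sim$sample$matrix
    poss[[k]] <- sim$sample$positions_bp
    maps[[k]] <- sim$sample$map_morgans
    chroms[[k]] <- rep(paste0("chr", k), length(sim$sample$positions_bp))
    map_tabs[[k]] <- tibble::tibble(chrom = paste0("chr", k),
                                    bp = cfg$map$bp,
                                    cm = 100 * cfg$map$morgans)
    wins[[k]] <- partition_windows(map_tabs[[k]], window_cm)[1, , drop = FALSE]
  }
  samp <- hap_sample(do.call(cbind, mats), unlist(poss), unlist(maps),
                     unlist(chroms), phased = TRUE)
  map_tab <- dplyr::bind_rows(map_tabs)
  win <- generate_tracks(dplyr::bind_rows(wins))
  paths <- list(vcf = file.path(dir, "synthetic.vcf"),
                map = file.path(dir, "synthetic.map"),
                tracks = file.path(dir, "synthetic_tracks.tsv"))
  write_vcf(samp, paths$vcf)
  write_genetic_map(map_tab, paths$map)
  tr <- tidyr::pivot_longer(
    dplyr::transmute(win, chrom = .data$chrom,
                     start = .data$start_bp, end = .data$end_bp,
                     b_mean = .data$b_mean, lof_count = .data$lof_count,
                     missense_count = .data$missense_count,
                     gene_density = .data$gene_density),
    cols = c("b_mean", "lof_count", "missense_count", "gene_density"),
    names_to = "name", values_to = "value")
  readr::write_tsv(tr, paths$tracks)
  invisible(c(paths, list(windows = win, sample = samp, map = map_tab)))
}
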