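test_that("heterogeneous maps tile the sequence with independent rates", {
  set.seed(4)
  m1 <- sample_heterogeneous_map(1e6, n_regions = 1)
  expect_equal(length(m1$rates_cM_Mb), 1)          # uniform map
  m70 <- sample_heterogeneous_map(7e6, n_regions = 70)
  expect_equal(length(m70$rates_cM_Mb), 70)
  expect_equal(unique(diff(m70$bp)), 1e5)          # equal-length regions
  expect_true(all(m70$rates_cM_Mb >= 0.01 & m70$rates_cM_Mb <= 5))
  # empirical mean of draws matches a Monte-Carlo of the same truncated
  # log-normal
  big <- sample_heterogeneous_map(1e7, n_regions = 10000)
  oracle <- rlnorm(2e5, -log(2) / 2, sqrt(log(2)))
  oracle <- oracle[oracle >= 0.01 & oracle <= 5]
  expect_equal(mean(big$rates_cM_Mb), mean(oracle), tolerance = 0.05)
})

test_that("copula tracks land on their coupling targets", {
  set.seed(9)
  win <- tibble::tibble(chrom = paste0("c", 1:400),
                        start_bp = 0, end_bp = 2e6,
                        rr_mean = rlnorm(400, -log(2) / 2, sqrt(log(2))))
  tr <- generate_tracks(win)
  expect_true(all(tr$b_mean > 0 & tr$b_mean <= 1))
  expect_true(all(tr$gene_density >= 0))
  sp <- function(a, b) cor(a, b, method = "spearman")
  expect_equal(sp(tr$gene_density, tr$lof_count), 0.6, tolerance = 0.25)
  expect_equal(sp(tr$gene_density, tr$missense_count), 0.6, tolerance = 0.25)
  expect_lt(sp(tr$b_mean, tr$gene_density), -0.35)
  expect_gt(sp(tr$b_mean, tr$rr_mean), 0.35)
  # zero targets give near-independence
  tr0 <- generate_tracks(win, rho_lof_gene = 0, rho_mis_gene = 0,
                         rho_b_gene = 0, rho_b_rr = 0)
  expect_lt(abs(sp(tr0$gene_density, tr0$lof_count)), 0.15)
  expect_lt(abs(sp(tr0$b_mean, tr0$rr_mean)), 0.15)
  # infeasible coupling matrices are refused
  expect_error(generate_tracks(win, rho_lof_gene = 0.99,
                               rho_mis_gene = -0.99, rho_b_gene = 0.99,
                               rho_b_rr = 0.99),
               "positive-semi-definite")
})

test_that("human-like window simulation is seeded and well-formed", {
  w <- simulate_humanlike_windows(n_windows = 2, N = 60, mu = 3e-7,
                                  n_generations = 40, sample_size = 20,
                                  base_seed = 77, min_pairs = 1000)
  expect_equal(nrow(w), 2)
  expect_true(all(c("pi", "P", "maf_mean", "rr_mean", "ne_ld", "n_pairs",
                    "gene_density", "b_mean") %in% names(w)))
  expect_true(all(abs(100 * (w$map_end - w$map_start) - 2) < 1e-6))
  w2 <- simulate_humanlike_windows(n_windows = 2, N = 60, mu = 3e-7,
                                   n_generations = 40, sample_size = 20,
                                   base_seed = 77, min_pairs = 1000)
  expect_identical(w$pi, w2$pi)
  expect_identical(w$ne_ld, w2$ne_ld)
})

test_that("the written human-like dataset round-trips losslessly", {
  dir <- withr::local_tempdir()
  out <- generate_humanlike_dataset(dir, n_windows = 2, N = 50, mu = 3e-7,
                                    n_generations = 30, sample_size = 15,
                                    base_seed = 5)
  expect_true(all(file.exists(out$vcf, out$map, out$tracks)))
  # byte-identical under the same seed
  dir2 <- withr::local_tempdir()
  out2 <- generate_humanlike_dataset(dir2, n_windows = 2, N = 50, mu = 3e-7,
                                     n_generations = 30, sample_size = 15,
                                     base_seed = 5)
  expect_identical(readLines(out$vcf), readLines(out2$vcf))
  # readers reproduce the in-memory objects
  map <- read_genetic_map(out$map)
  samp <- read_vcf(out$vcf, map = map)
  expect_identical(samp$matrix, out$sample$matrix)
  expect_equal(samp$positions_bp, out$sample$positions_bp)
  expect_equal(samp$map_morgans, out$sample$map_morgans, tolerance = 1e-9)
  tr <- read_tracks(out$tracks)
  expect_setequal(unique(tr$name),
                  c("b_mean", "lof_count", "missense_count", "gene_density"))
  # and the scan stage consumes the files without error
  sc <- scan_genome(samp, map, tracks = tr, min_pairs = 10)
  expect_equal(nrow(sc$windows), 2)
})
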