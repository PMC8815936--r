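test_that("pairwise r2 reproduces hand-computed haplotype tables", {
  expect_equal(sample_from_counts(5, 0, 0, 5) |>
                 pairwise_r2(maf_min = 0) |> _$r2, 1)
  expect_equal(sample_from_counts(25, 25, 25, 25) |>
                 pairwise_r2(maf_min = 0) |> _$r2, 0)
  # (4,1,1,4): D = 0.4 - 0.25 = 0.15, r2 = 0.0225 / 0.0625 = 0.36
  expect_equal(sample_from_counts(4, 1, 1, 4) |>
                 pairwise_r2(maf_min = 0) |> _$r2, 0.36)
})

test_that("r2 equals the brute-force 2x2 oracle on random small tables", {
  set.seed(8)
  for (i in 1:40) {
    repeat {   # need both sites polymorphic
      n <- sample(4:20, 1)
      cts <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
      pA <- (cts[1] + cts[2]) / n; pB <- (cts[1] + cts[3]) / n
      if (pA > 0 && pA < 1 && pB > 0 && pB < 1) break
    }
    s <- sample_from_counts(cts[1], cts[2], cts[3], cts[4])
    expect_equal(pairwise_r2(s, maf_min = 0)$r2,
                 r2_from_counts(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-12)
  }
})

test_that("pairwise r2 respects MAF, c-range and pair-cap contracts", {
  set.seed(12)
  m <- matrix(rbinom(20 * 6, 1, 0.5), nrow = 20)
  m[, 6] <- c(1L, rep(0L, 19))                    # MAF = 0.05 boundary
  s <- hap_sample(m, 1:6 * 100, 1:6 * 0.002, drop_monomorphic = TRUE)
  pr <- pairwise_r2(s, maf_min = 0.06)
  expect_false(any(pr$site_i == 6 | pr$site_j == 6))
  pr_all <- pairwise_r2(s, maf_min = 0)
  expect_true(all(pr_all$c >= 0.001 & pr_all$c <= 0.5))
  set.seed(1)
  pr_cap <- pairwise_r2(s, maf_min = 0, max_pairs = 3)
  expect_equal(nrow(pr_cap), 3)
  # monomorphic columns are an upstream invariant violation
  s_bad <- s; s_bad$matrix[, 2] <- 1L
  expect_error(pairwise_r2(s_bad), "monomorphic")
})

test_that("the Sved inversion is the exact inverse of the forward form", {
  # worked example: mean_r2 = 1/11 + 1/200 at c = 0.0025 inverts to 1000
  est <- ne_from_bin(1 / 11 + 1 / 200, 0.0025, n = 200)
  expect_equal(est$ne_hat, 1000)
  expect_true(est$valid)
  # round-trip across a grid: r2 = 1/(alpha + 4 Ne c) + 1/n inverts
  for (ne in c(50, 500, 5000)) for (cc in c(0.001, 0.01, 0.2)) {
    r2p <- 1 / (1 + 4 * ne * cc) + 1 / 100
    expect_equal(ne_from_bin(r2p, cc, 100, phased = TRUE)$ne_hat, ne,
                 tolerance = 1e-9)
    r2u <- 1 / (2 + 4 * ne * cc) + 1 / 50
    expect_equal(ne_from_bin(r2u, cc, 50, phased = FALSE)$ne_hat, ne,
                 tolerance = 1e-9)
  }
  # boundary and invalid flags
  expect_equal(ne_from_bin(1 + 1 / 200, 0.01, 200)$ne_hat, 0)
  low <- ne_from_bin(1 / 300, 0.01, n = 200)      # below sampling floor
  expect_false(low$valid)
  expect_true(is.na(low$ne_hat))
  # monotone: larger c at fixed r2 means smaller ne
  nes <- ne_from_bin(0.05, c(0.001, 0.01, 0.1), 200)$ne_hat
  expect_true(all(diff(nes) < 0))
})

test_that("trajectory maps bins to t = 1/(2c) and keeps order", {
  bins <- tibble::tibble(c_low = c(0.4, 0.002), c_high = c(0.5, 0.003),
                         n_pairs = c(500L, 500L), mean_c = c(0.5, 0.0025),
                         mean_r2 = c(0.01, 0.1))
  tr <- historical_trajectory(bins, n = 200)
  expect_equal(tr$t, c(1, 200))
  expect_true(!is.unsorted(tr$t))
  expect_error(historical_trajectory(bins[0, ], 200), "empty")
})

test_that("diversity- and pedigree-based Ne follow their closed forms", {
  expect_equal(ne_from_pi(4e-5, 1e-8), 1000)
  expect_equal(ne_from_pi(0, 1e-8), 0)
  expect_equal(ne_from_pi(3e-5, 1e-8), 750)
  expect_error(ne_from_pi(1e-5, 0), "mu")

  expect_equal(ne_vk_analytic(1000, 0.5), 750)
  expect_equal(ne_vk_analytic(1000, 0), 1000)
  expect_equal(ne_vk_analytic(1000, 1), 500)

  expect_equal(ne_vk_from_pedigree(rep(2L, 100)), 199)
  expect_equal(ne_vk_from_pedigree(2L, N = 1), 1)
  expect_error(ne_vk_from_pedigree(rep(1L, 100)), "sum to 2N")
  # multinomial oracle: Vk ~ 2 so ne ~ N
  set.seed(21)
  nes <- replicate(300, {
    k <- tabulate(sample.int(100, 200, replace = TRUE), nbins = 100)
    ne_vk_from_pedigree(k)
  })
  expect_equal(mean(nes), 100, tolerance = 0.05)
})

test_that("binning drops sparse bins and respects edges", {
  set.seed(5)
  pairs <- tibble::tibble(c = exp(runif(5000, log(0.001), log(0.5))),
                          r2 = runif(5000))
  b <- bin_pairs(pairs, n_bins = 10, min_pairs = 200)
  expect_true(all(b$n_pairs >= 200))
  expect_true(all(b$mean_c >= b$c_low & b$mean_c <= b$c_high))
  expect_equal(sum(bin_pairs(pairs, n_bins = 10, min_pairs = 1)$n_pairs),
               5000)
})

test_that("trajectory objects expose tidy, glance and autoplot methods", {
  bins <- tibble::tibble(c_low = 0.002, c_high = 0.003, n_pairs = 500L,
                         mean_c = c(0.0025, 0.01, 0.02),
                         mean_r2 = c(0.1, 0.04, 0.025))
  tr <- historical_trajectory(bins, n = 200)
  expect_s3_class(tidy(tr), "tbl_df")
  g <- glance(tr)
  expect_equal(g$n_bins, 3)
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("unphased data cannot be routed to the phased estimator", {
  set.seed(3)
  m <- matrix(rbinom(40 * 8, 1, 0.5), nrow = 40)
  s <- hap_sample(m, 1:8 * 50, 1:8 * 0.004, drop_monomorphic = TRUE)
  u <- as_unphased(s)
  expect_error(estimate_ne_ld(u, phased = TRUE), "composite")
  expect_error(regional_ne(u, phased = TRUE), "composite")
})
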