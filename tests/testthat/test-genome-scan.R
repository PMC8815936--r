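test_that("2 cM windows tile the map and drop telomeric remainders", {
  # uniform 1 cM/Mb, 10 Mb -> 5 windows of exactly 2 Mb
  m10 <- tibble::tibble(chrom = "1", bp = c(0, 1e7), cm = c(0, 10))
  w <- partition_windows(m10)
  expect_equal(nrow(w), 5)
  expect_equal(w$end_bp - w$start_bp, rep(2e6, 5))
  expect_equal(w$rr_mean, rep(1, 5))
  # 11 Mb -> still 5 windows; the 1 Mb telomeric remainder is dropped
  m11 <- tibble::tibble(chrom = "1", bp = c(0, 1.1e7), cm = c(0, 11))
  w11 <- partition_windows(m11)
  expect_equal(nrow(w11), 5)
  expect_equal(max(w11$end_bp), 1e7)
  # chromosome shorter than one window -> zero windows
  short <- tibble::tibble(chrom = "1", bp = c(0, 1e6), cm = c(0, 1))
  expect_equal(nrow(partition_windows(short)), 0)
  # non-uniform map: bp width varies inversely with local RR
  m2 <- tibble::tibble(chrom = "1", bp = c(0, 1e6, 5e6),
                       cm = c(0, 2, 4))     # 2 cM/Mb then 0.5 cM/Mb
  w2 <- partition_windows(m2)
  expect_equal(w2$end_bp - w2$start_bp, c(1e6, 4e6))
  expect_equal(w2$rr_mean, c(2, 0.5))
})

test_that("window statistics match hand computation on a toy sample", {
  # 4 haplotypes, one SNP at p = 0.5 in a 100 bp window:
  # pi = 2 * 0.25 * (4/3) / 100 = 1/150
  s <- hap_sample(matrix(c(1L, 1L, 0L, 0L), ncol = 1), 10, 0.0001)
  win <- tibble::tibble(chrom = "1", start_bp = 0, end_bp = 100,
                        map_start = 0, map_end = 0.02, rr_mean = 1)
  st <- window_stats(s, win)
  expect_equal(st$pi, 1 / 150)
  expect_equal(st$P, 1 / 100)
  expect_equal(st$maf_mean, 0.5)
  expect_true(is.na(st$ne_ld))           # a single SNP gives no pairs
  # a window holding no segregating site has pi = 0 and P = 0
  win2 <- tibble::tibble(chrom = "1", start_bp = 200, end_bp = 300,
                         map_start = 0, map_end = 0.02, rr_mean = 1)
  st2 <- window_stats(s, win2)
  expect_equal(st2$pi, 0)
  expect_equal(st2$P, 0)
  # 2 Mb window spanning 2 cM -> rr_mean = 1 cM/Mb (from the partition)
  m <- tibble::tibble(chrom = "1", bp = c(0, 2e6), cm = c(0, 2))
  expect_equal(partition_windows(m)$rr_mean, 1)
})

test_that("window filtering reproduces the exclusion rules exactly", {
  st <- tibble::tibble(
    chrom = "1", start_bp = 1:6, n_pairs = c(249999, 250000, 250001,
                                             300000, 300000, 300000),
    ne_ld = c(5000, 5000, 5000, -12, 100001, 99999))
  kept <- filter_windows(st)
  # strictly more than 250,000 pairs required
  expect_equal(kept$n_pairs[1], 250001)
  # negative excluded; > 100,000 excluded; 99,999 kept
  expect_setequal(kept$ne_ld, c(5000, 99999))
  ex <- attr(kept, "exclusions")
  expect_equal(sum(ex$n), nrow(st))              # filter conservation
  expect_equal(ex$n[ex$rule == "insufficient_pairs"], 2)
  expect_equal(ex$n[ex$rule == "nonpositive_ne"], 1)
  expect_equal(ex$n[ex$rule == "ne_above_max"], 1)
  # everything failing leaves an empty result and correlations refuse it
  none <- filter_windows(dplyr::mutate(st, n_pairs = 0))
  expect_equal(nrow(none), 0)
  cr <- correlate_windows(dplyr::mutate(none, pi = numeric(0),
                                        rr_mean = numeric(0)))
  expect_true(all(cr$reason == "too few windows"))
})

test_that("Spearman correlations match the rank formula and its invariances", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  st <- tibble::tibble(pi = x, rr_mean = 2 * x, ne_ld = -x)
  cr <- correlate_windows(st, list(c("pi", "rr_mean"), c("pi", "ne_ld")))
  expect_equal(cr$rho, c(1, -1))
  # ranks (1,2,3,4,5) vs (2,1,4,3,5): 1 - 6*4/120 = 0.8
  st2 <- tibble::tibble(pi = 1:5, rr_mean = c(2, 1, 4, 3, 5))
  expect_equal(correlate_windows(st2, list(c("pi", "rr_mean")))$rho, 0.8)
  # invariant under strictly monotone transforms of either variable
  st3 <- tibble::tibble(pi = exp(x), rr_mean = (2 * x)^3)
  expect_equal(correlate_windows(st3, list(c("pi", "rr_mean")))$rho, 1)
  # p-value is the t-approximation on n - 2 df
  r <- correlate_windows(st2, list(c("pi", "rr_mean")))
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(r$p_value, 2 * stats::pt(tstat, 3, lower.tail = FALSE),
               tolerance = 1e-9)
  # constant variable reported as absent with a reason
  st4 <- tibble::tibble(pi = rep(1, 8), rr_mean = 1:8)
  r4 <- correlate_windows(st4, list(c("pi", "rr_mean")))
  expect_true(is.na(r4$rho))
  expect_equal(r4$reason, "constant variable")
})

test_that("correlation results plot as an annotated bar chart", {
  st <- tibble::tibble(pi = runif(20), rr_mean = runif(20),
                       ne_ld = runif(20))
  cr <- correlate_windows(st)
  expect_s3_class(autoplot(cr), "ggplot")
})

test_that("features are assigned to windows by their midpoint", {
  win <- tibble::tibble(chrom = "1", start_bp = c(0, 1000),
                        end_bp = c(1000, 2000))
  # feature spans both windows but its midpoint (1100) is in window 2
  tr <- tibble::tibble(chrom = "1", start = 800, end = 1400,
                       name = "gene_density", value = 7)
  out <- ldnescan:::join_tracks(win, tr)
  expect_true(is.na(out$gene_density[1]))
  expect_equal(out$gene_density[2], 7)
})
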