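test_that("recombination maps convert between bp, Morgans and c", {
  m <- recomb_map(1, 1e6)
  expect_equal(map_length(m), 0.01)                # 1 cM/Mb over 1 Mb
  expect_equal(map_position(m, 5e5), 0.005)
  expect_equal(map_to_bp(m, 0.005), 5e5)
  # piecewise map: total length is sum of segment_len_Mb * RR / 100
  m2 <- recomb_map(c(5, 0.01), 2e6)
  expect_equal(map_length(m2), (1 * 5 + 1 * 0.01) / 100)
  expect_true(!is.unsorted(map_position(m2, seq(0, 2e6, length.out = 50))))
  # Haldane: small distances ~ d, saturates at 0.5
  expect_equal(haldane_c(0), 0)
  expect_equal(haldane_c(1e-4), 1e-4, tolerance = 1e-3)
  expect_lt(haldane_c(10), 0.5 + 1e-12)
  expect_error(recomb_map(-1, 1e6))
})

test_that("config validation enforces the documented invariants", {
  expect_error(tiny_config(selfing = 1.5))
  expect_error(tiny_config(census_trajectory =
    tibble::tibble(generation = c(0L, 50L), n = c(60L, 30L))),
    "beyond n_generations")
  expect_error(tiny_config(census_trajectory =
    tibble::tibble(generation = c(5L, 10L), n = c(60L, 30L))),
    "start at generation 0")
  expect_error(tiny_config(n = 1), "census sizes")
})

test_that("rescaling preserves N*mu, N*map-length and N*s", {
  cfg <- sim_config(n = 10000, sequence_length_bp = 1e6,
                    mutation_rate = 1e-9, recomb_rate_cM_Mb = 1,
                    model = "bs", n_generations = 1000, sample_size = 50)
  expect_identical(rescale_config(cfg, 1), cfg)
  r <- rescale_config(cfg, 10)
  expect_equal(r$census_trajectory$n, 1000L)
  expect_equal(r$mutation_rate, 1e-8)
  expect_equal(r$n_generations, 100L)
  # compound parameters preserved
  expect_equal(r$census_trajectory$n * r$mutation_rate,
               cfg$census_trajectory$n * cfg$mutation_rate)
  expect_equal(r$census_trajectory$n * map_length(r$map),
               cfg$census_trajectory$n * map_length(cfg$map))
  expect_equal(r$census_trajectory$n * r$dfe$gamma_mean_abs_s,
               cfg$census_trajectory$n * cfg$dfe$gamma_mean_abs_s)
  expect_error(rescale_config(cfg, 1000), "below 20")
})

test_that("equilibrium initialisation matches neutral theory", {
  # no mutation -> no segregating sites
  p0 <- initialize_population(tiny_config(mutation_rate = 0))
  expect_equal(sum(p0$registry$active), 0)
  # seeded runs are identical
  cfg <- tiny_config()
  a <- initialize_population(cfg)
  b <- initialize_population(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$registry, b$registry)
  # mean sample pi over replicates ~ 4 N mu (closed form)
  cfg2 <- sim_config(n = 200, sequence_length_bp = 5e5,
                     mutation_rate = 5e-7, recomb_rate_cM_Mb = 1,
                     model = "neutral", n_generations = 0,
                     sample_size = 50)
  pis <- vapply(1:20, function(r) {
    cfg2$seed <- 7000 + r
    run_simulation(cfg2)$diversity$pi
  }, numeric(1))
  expect_equal(mean(pis), 4 * 200 * 5e-7, tolerance = 0.15)
  # refuses absurd expected site counts
  expect_error(initialize_population(tiny_config(max_sites = 10)),
               "max_sites")
})

test_that("one generation of reproduction conserves gametes and selfing", {
  cfg <- tiny_config()
  pop <- initialize_population(cfg)
  off <- step_generation(pop, cfg)
  expect_equal(sum(off$family_sizes), 2 * 60)
  expect_equal(off$generation, 1L)
  # beta = 1: both gametes always come from a single parent, so every
  # parent's gamete count is even
  cfg_self <- tiny_config(selfing = 1)
  off_self <- step_generation(initialize_population(cfg_self), cfg_self)
  expect_true(all(off_self$family_sizes %% 2 == 0))
})

test_that("neutral family-size variance matches the multinomial oracle", {
  # oracle: Monte-Carlo of multinomial parent sampling
  set.seed(99)
  N <- 100
  oracle_vk <- mean(replicate(500, {
    var(tabulate(sample.int(N, 2 * N, replace = TRUE), nbins = N))
  }))
  cfg <- sim_config(n = N, sequence_length_bp = 1e5, mutation_rate = 1e-7,
                    recomb_rate_cM_Mb = 1, model = "neutral",
                    n_generations = 400, sample_size = 20, seed = 5)
  sim <- run_simulation(cfg)
  expect_equal(mean(sim$pedigree$vk), oracle_vk, tolerance = 0.05)
  expect_equal(oracle_vk, 2, tolerance = 0.05)  # binomial/Poisson limit
})

test_that("neutral allele-frequency changes are mean-zero (martingale)", {
  cfg <- tiny_config(n = 50, sequence_length_bp = 2e5,
                     mutation_rate = 5e-7, n_generations = 0)
  set.seed(31)
  deltas <- unlist(lapply(1:40, function(r) {
    cfg$seed <- 300 + r
    pop <- initialize_population(cfg)
    act0 <- pop$registry$active
    p0 <- tabulate(unlist(pop$haplotypes), nbins = nrow(pop$registry)) / 100
    off <- step_generation(pop, cfg)
    # frequencies after one generation, in the parent indexing
    id0 <- which(act0)
    p1 <- numeric(length(id0))
    pos_new <- off$registry$position_bp[off$registry$active]
    cnt_new <- tabulate(unlist(off$haplotypes), nbins = nrow(off$registry))
    freq_new <- cnt_new[off$registry$active] / 100
    m <- match(pop$registry$position_bp[id0], pos_new)
    p1[!is.na(m)] <- freq_new[m[!is.na(m)]]
    # lost sites have p1 = 0; fixed sites need p1 = 1
    fixed <- is.na(m) & p0[id0] > 0.5
    p1[fixed] <- 1
    p1 - p0[id0]
  }))
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)) + 0.002)
})

test_that("run_simulation honours the census trajectory and sampling", {
  cfg <- tiny_config(
    census_trajectory = tibble::tibble(generation = c(0L, 10L),
                                       n = c(60L, 30L)),
    n_generations = 15, sample_size = 30)
  sim <- run_simulation(cfg)
  expect_equal(sim$pedigree$census, c(rep(60L, 9), rep(30L, 6)))
  expect_equal(sim$diversity$final_census, 30)
  expect_error(run_simulation(tiny_config(sample_size = 100)),
               "exceeds final census")
})

test_that("seeded full runs are bit-reproducible", {
  cfg <- tiny_config()
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$sample$matrix, s2$sample$matrix)
  expect_identical(s1$sample$positions_bp, s2$sample$positions_bp)
  expect_identical(s1$pedigree, s2$pedigree)
})

test_that("an inviable population aborts with a clear error", {
  # every new mutation is lethal in the heterozygote; after one
  # generation of heavy mutation every parent has fitness zero
  lethal <- dfe_config("od", p_selected = 1, fixed_s = -1, fixed_h = 1)
  cfg <- tiny_config(model = "od", dfe = lethal, mutation_rate = 1e-3,
                     sequence_length_bp = 1e4, n_generations = 5,
                     burn_in = "full")
  expect_error(run_simulation(cfg), "inviable")
})
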