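test_that("noise-free configuration reproduces the deterministic mean structure", {
  cfg <- sim_config(n_years = 3, entries_per_year = 10, n_sites_per_year = 2,
                    true_annual_gain = 0, var_genotype = 0, var_rep = 0,
                    var_block = 0, var_residual = 0, var_site = 0,
                    fa_loadings = 0, fa_specific_vars = 0,
                    local_check_lag = 0, local_check_lag_trend = 0,
                    seed = 1)
  sim <- simulate_program(cfg)
  expect_true(all(abs(sim$plots$gy_t_ha - cfg$baseline_yield) < 1e-12))
  ## every plot of a genotype equals mu + its genetic value
  per_geno <- tapply(sim$plots$gy_t_ha, sim$plots$genotype_name, function(v)
    max(v) - min(v))
  expect_true(all(per_geno < 1e-12))
})

test_that("a pure trend with zero noise forces consecutive-year elite mean differences", {
  cfg <- sim_config(n_years = 4, entries_per_year = 8, n_sites_per_year = 2,
                    true_annual_gain = 0.1, var_genotype = 0, var_rep = 0,
                    var_block = 0, var_residual = 0, var_site = 0,
                    fa_loadings = 0, fa_specific_vars = 0, seed = 2)
  sim <- simulate_program(cfg)
  elite <- sim$plots[!sim$plots$is_local_check, ]
  ym <- tapply(elite$gy_t_ha, elite$year, mean)
  expect_equal(as.numeric(diff(ym)), rep(0.1, 3), tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_years = 2, entries_per_year = 12, n_sites_per_year = 3,
                    seed = 99)
  a <- simulate_program(cfg)
  b <- simulate_program(cfg)
  expect_identical(a$plots, b$plots)
  expect_identical(a$climate, b$climate)
})

test_that("each site-replicate partitions all entries into disjoint blocks", {
  cfg <- sim_config(n_years = 2, entries_per_year = 23, n_sites_per_year = 3,
                    n_blocks_per_rep = 5, seed = 5)
  sim <- simulate_program(cfg)
  d <- sim$plots
  for (key in unique(paste(d$site_id, d$rep))) {
    sub <- d[paste(d$site_id, d$rep) == key, ]
    ## each genotype appears exactly once in the replicate
    expect_true(all(table(sub$genotype_name) == 1))
    ## blocks are non-empty and contiguous in index
    expect_setequal(unique(sub$block), seq_len(5))
  }
  expect_true(sim$truth$block_sizes_adjusted)  # 24 entries over 5 blocks
})

test_that("simulated residual and genetic covariance match their generating values", {
  ## residual variance: isolate it with all other components zero
  cfg <- sim_config(n_years = 1, entries_per_year = 100, n_sites_per_year = 10,
                    n_reps = 10, true_annual_gain = 0, var_genotype = 0,
                    var_rep = 0, var_block = 0, var_residual = 0.4,
                    var_site = 0, fa_loadings = 0, fa_specific_vars = 0,
                    seed = 7)
  sim <- simulate_program(cfg)
  n <- nrow(sim$plots)
  expect_gt(n, 1e4)
  v <- var(sim$plots$gy_t_ha - ave(sim$plots$gy_t_ha, sim$plots$genotype_name))
  ## sampling sd of a variance estimate ~ var * sqrt(2/n)
  expect_lt(abs(v - 0.4), 3 * 0.4 * sqrt(2 / n) + 0.4 * 2 / 100)

  ## empirical cross-site covariance of genetic deviations ~ Lambda Lambda' + Psi
  cfg2 <- sim_config(n_years = 1, entries_per_year = 4000,
                     n_sites_per_year = 4, n_reps = 2,
                     n_blocks_per_rep = 2, var_genotype = 0, var_rep = 0,
                     var_block = 0, var_residual = 0, var_site = 0,
                     true_annual_gain = 0, seed = 8)
  sim2 <- simulate_program(cfg2)
  el <- sim2$plots[!sim2$plots$is_local_check & sim2$plots$rep == 1, ]
  M <- tapply(el$gy_t_ha, list(el$genotype_name, el$site_id), mean)
  emp <- cov(M)
  tru <- sim2$truth$sigma_s
  expect_lt(max(abs(emp - tru)), 0.05)  # ~3 sd at n = 4000 genotypes
})

test_that("climate generation respects centers, mixing fraction and spread", {
  ## zero spread puts every site exactly on its centre
  cl <- generate_site_climate(30, env_mix = 0.5, spread = c(0, 0, 0), seed = 3)
  hi <- cl[cl$true_env == "high_rainfall", ]
  lo <- cl[cl$true_env == "low_rainfall", ]
  expect_true(all(hi$precip_coolest_quarter_mm == 282))
  expect_true(all(lo$precip_coolest_quarter_mm == 53))
  expect_true(all(hi$altitude_m == 781) && all(lo$altitude_m == 329))

  ## env_mix 1 gives only high-rainfall sites
  cl1 <- generate_site_climate(25, env_mix = 1, seed = 4)
  expect_true(all(cl1$true_env == "high_rainfall"))

  ## binomial expectation of the high fraction at env_mix 0.577
  n <- 4000
  cln <- generate_site_climate(n, env_mix = 0.577, seed = 5)
  frac <- mean(cln$true_env == "high_rainfall")
  expect_lt(abs(frac - 0.577), 3 * sqrt(0.577 * (1 - 0.577) / n))

  expect_error(generate_site_climate(0), "positive")
})
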