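small_instance <- function(seed = 101) random_met_instance(seed)

test_that("MME solutions match the dense GLS oracle", {
  inst <- small_instance()
  mme <- solve_mme(inst$plots, inst$pars)
  orc <- dense_gls_oracle(inst$plots, "gy_t_ha", inst$pars)
  expect_equal(mme$beta, orc$beta, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(mme$u_g[orc$geno_ids], orc$u_g, tolerance = 1e-8)
  uge <- as.vector(t(mme$u_ge[orc$geno_ids, orc$site_ids]))
  expect_equal(uge, orc$u_ge_site_fast, tolerance = 1e-8)
})

test_that("the restricted likelihood equals the dense marginal-covariance formula", {
  inst <- small_instance(102)
  dd <- metgain:::met_design(inst$plots, "gy_t_ha")
  par <- metgain:::fa_pack(inst$pars$var_rep, inst$pars$var_block,
                           inst$pars$var_genotype, inst$pars$var_residual,
                           matrix(inst$pars$loadings, ncol = 1),
                           inst$pars$specific_variances)
  orc <- dense_gls_oracle(inst$plots, "gy_t_ha", inst$pars)
  expect_equal(metgain:::fa_m2ll(par, dd, 1), orc$m2ll, tolerance = 1e-8)
})

test_that("vanishing random-effect variance forces its BLUPs to zero", {
  inst <- small_instance(103)
  pars <- inst$pars
  pars$var_genotype <- 0
  mme <- solve_mme(inst$plots, pars)
  expect_lt(max(abs(mme$u_g)), 1e-8)
  pars2 <- inst$pars
  pars2$loadings <- rep(0, 3)
  pars2$specific_variances <- rep(0, 3)
  mme2 <- solve_mme(inst$plots, pars2)
  expect_lt(max(abs(mme2$u_ge)), 1e-6)
})

test_that("with no residual noise predictions approach observed cell means", {
  ## data with no within-cell variation: the no-shrinkage limit must
  ## reproduce each genotype-by-site cell exactly
  cfg <- sim_config(n_years = 1, entries_per_year = 8, n_sites_per_year = 3,
                    n_blocks_per_rep = 2, var_rep = 0, var_block = 0,
                    var_residual = 0, seed = 104)
  d <- simulate_program(cfg)$plots
  pars <- list(var_rep = 1e-8, var_block = 1e-8, var_genotype = 0.3,
               var_residual = 1e-8, loadings = rep(0.4, 3),
               specific_variances = rep(0.1, 3))
  mme <- solve_mme(d, pars)
  cell <- aggregate(gy_t_ha ~ genotype_name + site_id, d, mean)
  pred <- mme$mu + mme$site_effects[cell$site_id] +
    mme$u_g[cell$genotype_name] +
    mme$u_ge[cbind(cell$genotype_name, cell$site_id)]
  expect_equal(pred, cell$gy_t_ha, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("single-site input is rejected with guidance", {
  inst <- small_instance(105)
  one <- inst$plots[inst$plots$site_id == inst$plots$site_id[1], ]
  expect_error(reml_fit_fa(one), "fit_site_model")
})

test_that("the likelihood is invariant to a sign flip of the loadings and the fit canonicalizes", {
  inst <- small_instance(106)
  dd <- metgain:::met_design(inst$plots, "gy_t_ha")
  lam <- matrix(inst$pars$loadings, ncol = 1)
  mk <- function(L) metgain:::fa_pack(inst$pars$var_rep, inst$pars$var_block,
                                      inst$pars$var_genotype,
                                      inst$pars$var_residual, L,
                                      inst$pars$specific_variances)
  expect_equal(metgain:::fa_m2ll(mk(lam), dd, 1),
               metgain:::fa_m2ll(mk(-lam), dd, 1), tolerance = 1e-10)
  fit <- reml_fit_fa(inst$plots, k_factors = 1, maxit = 150)
  nz <- which(abs(fit$loadings[, 1]) > 1e-10)
  if (length(nz)) expect_gt(fit$loadings[nz[1], 1], 0)
})

test_that("increasing the FA order never decreases the maximized likelihood", {
  set.seed(9)
  cfg <- sim_config(n_years = 1, entries_per_year = 15, n_sites_per_year = 4,
                    n_blocks_per_rep = 2, seed = 19)
  plots <- simulate_program(cfg)$plots
  f1 <- reml_fit_fa(plots, k_factors = 1, maxit = 200)
  f2 <- reml_fit_fa(plots, k_factors = 2, maxit = 200,
                    start = list(s2r = f1$var_rep, s2b = f1$var_block,
                                 s2g = f1$var_genotype, s2e = f1$var_residual,
                                 Lambda = cbind(f1$loadings,
                                                c(0, rep(0.05, 3))),
                                 psi = f1$specific_variances))
  expect_gte(f2$reml_loglik, f1$reml_loglik - 1e-6)
})

test_that("the REML optimum is at least as likely as the generating parameters", {
  cfg <- sim_config(n_years = 1, entries_per_year = 25, n_sites_per_year = 4,
                    seed = 23)
  sim <- simulate_program(cfg)
  fit <- reml_fit_fa(sim$plots, k_factors = 1, maxit = 200)
  dd <- fit$design
  par_true <- metgain:::fa_pack(cfg$var_rep, cfg$var_block, cfg$var_genotype,
                                cfg$var_residual,
                                matrix(cfg$fa_loadings, ncol = 1),
                                cfg$fa_specific_vars)
  ll_true <- -metgain:::fa_m2ll(par_true, dd, 1) / 2
  expect_gte(fit$reml_loglik, ll_true - 1e-6)
})

test_that("genetic covariance obeys its structural identities", {
  f <- list(loadings = matrix(0, 3, 1), specific_variances = c(1, 2, 3),
            var_genotype = 0, site_ids = c("A", "B", "C"))
  class(f) <- "fa_fit"
  gc <- genetic_covariance(f)
  expect_equal(gc$covariance, diag(c(1, 2, 3)), ignore_attr = TRUE)

  f2 <- list(loadings = matrix(1, 2, 1), specific_variances = c(0, 0),
             var_genotype = 0, site_ids = c("A", "B"))
  class(f2) <- "fa_fit"
  expect_equal(genetic_covariance(f2)$correlation,
               matrix(1, 2, 2), ignore_attr = TRUE)

  inst <- small_instance(107)
  fit <- reml_fit_fa(inst$plots, maxit = 120)
  gc3 <- genetic_covariance(fit)
  expect_true(all(abs(gc3$correlation) <= 1 + 1e-10))
  expect_true(min(eigen(gc3$covariance, symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-10)
})

test_that("a perfectly correlated unobserved site borrows the full deviation", {
  inst <- small_instance(108)
  d <- inst$plots
  sites <- sort(unique(d$site_id))
  gA <- sort(unique(d$genotype_name))[1]
  d <- d[!(d$genotype_name == gA & d$site_id != sites[1]), ]
  pars <- inst$pars
  pars$loadings <- rep(0.5, 3)        # correlation(A, B) = 1, equal variances
  pars$specific_variances <- rep(0, 3)
  mme <- solve_mme(d, pars)
  expect_equal(mme$u_ge[gA, sites[2]], mme$u_ge[gA, sites[1]],
               tolerance = 1e-6)
})

test_that("BLUP tables carry shrunken means, local-check means and zero-variance limits", {
  inst <- small_instance(109)
  fit <- reml_fit_fa(inst$plots, maxit = 150)
  bt <- compute_blups(fit)
  ## genotype main BLUPs shrink around zero
  expect_lt(abs(mean(bt$genotype_means$blup_main)), 0.15)
  ## every genotype x site combination predicted
  expect_equal(nrow(bt$cells),
               length(fit$geno_ids) * length(fit$site_ids))
  expect_true(any(bt$genotype_means$is_local_check))
  expect_true(is.finite(bt$lc_mean))
  ## all random variances zero: predictions collapse to mu + site effect
  pars0 <- list(var_rep = 0, var_block = 0, var_genotype = 0,
                var_residual = inst$pars$var_residual,
                loadings = rep(0, 3), specific_variances = rep(0, 3))
  fit0 <- fit
  fit0$mme <- solve_mme(fit$design, pars0)
  fit0$var_genotype <- 0
  bt0 <- compute_blups(fit0)
  expect_lt(max(abs(bt0$cells$blup)), 1e-6)
  expect_lt(max(abs(bt0$genotype_means$across_site_mean -
                      (fit0$mme$mu + mean(fit0$mme$site_effects)))), 1e-6)
})
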