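# Independent oracles used across the suite. These are deliberately
# brute-force (dense marginal-covariance inversion, closed-form ANOVA,
# normal-equation OLS) and share no code with the package's solvers.

## Dense generalized-least-squares oracle for the multi-site model:
## builds the full marginal covariance V and inverts it directly.
dense_gls_oracle <- function(plots, trait, pars) {
  d <- plots[!is.na(plots[[trait]]), ]
  site_ids <- sort(unique(d$site_id))
  geno_ids <- sort(unique(d$genotype_name))
  s <- length(site_ids); g <- length(geno_ids); n <- nrow(d)
  X <- stats::model.matrix(~factor(d$site_id, site_ids))
  Zr <- stats::model.matrix(~0 + factor(paste(d$site_id, d$rep)))
  Zb <- stats::model.matrix(~0 + factor(paste(d$site_id, d$rep, d$block)))
  Zg <- stats::model.matrix(~0 + factor(d$genotype_name, geno_ids))
  gi <- as.integer(factor(d$genotype_name, geno_ids))
  si <- as.integer(factor(d$site_id, site_ids))
  Zge <- matrix(0, n, s * g)
  Zge[cbind(seq_len(n), (gi - 1) * s + si)] <- 1
  lam <- matrix(pars$loadings, nrow = s)
  Sig <- tcrossprod(lam) + diag(pars$specific_variances, s)
  V <- pars$var_rep * tcrossprod(Zr) + pars$var_block * tcrossprod(Zb) +
    pars$var_genotype * tcrossprod(Zg) +
    Zge %*% (diag(g) %x% Sig) %*% t(Zge) +
    pars$var_residual * diag(n)
  Vi <- solve(V)
  y <- d[[trait]]
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid <- y - X %*% beta
  u_g <- pars$var_genotype * t(Zg) %*% Vi %*% resid
  u_ge <- (diag(g) %x% Sig) %*% t(Zge) %*% Vi %*% resid
  P <- Vi - Vi %*% X %*% solve(XtVi %*% X, XtVi)
  m2ll <- (n - ncol(X)) * log(2 * pi) +
    as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(XtVi %*% X)$modulus) +
    as.numeric(t(y) %*% P %*% y)
  list(beta = as.numeric(beta),
       u_g = stats::setNames(as.numeric(u_g), geno_ids),
       u_ge_site_fast = as.numeric(u_ge),  # site varies fastest per genotype
       m2ll = m2ll, reml_loglik = -m2ll / 2,
       geno_ids = geno_ids, site_ids = site_ids)
}

## Closed-form ANOVA (expected mean squares) variance components for
## balanced genotype x replicate data without incomplete blocks.
anova_mom_oracle <- function(y, genotype, rep) {
  a <- stats::anova(stats::lm(y ~ factor(genotype) + factor(rep)))
  mse <- a["Residuals", "Mean Sq"]
  msg <- a["factor(genotype)", "Mean Sq"]
  r <- length(unique(rep))
  list(var_genotype = max(0, (msg - mse) / r), var_residual = mse)
}

## Normal-equation OLS with t-based slope p-value.
ols_oracle <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  e <- y - X %*% b
  s2 <- sum(e^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tval <- b[2] / se
  list(intercept = b[1], slope = b[2],
       p_value = 2 * stats::pt(-abs(tval), n - 2),
       r_squared = 1 - sum(e^2) / sum((y - mean(y))^2))
}

## Small random multi-site dataset with arbitrary variance parameters,
## for MME oracle-equivalence checks.
random_met_instance <- function(seed, n_sites = 3, n_geno = 8, n_reps = 2,
                                n_blocks = 2) {
  set.seed(seed)
  cfg <- sim_config(n_years = 1, entries_per_year = n_geno,
                    n_sites_per_year = n_sites, n_reps = n_reps,
                    n_blocks_per_rep = n_blocks, seed = seed)
  plots <- simulate_program(cfg)$plots
  s <- n_sites
  pars <- list(var_rep = runif(1, 0.01, 0.2),
               var_block = runif(1, 0.01, 0.2),
               var_genotype = runif(1, 0.05, 0.5),
               var_residual = runif(1, 0.1, 0.8),
               loadings = runif(s, -0.6, 0.8),
               specific_variances = runif(s, 0.01, 0.3))
  list(plots = plots, pars = pars)
}

## Balanced single-site dataset (one block per rep) with known components.
balanced_site_data <- function(seed, g = 25, reps = 2, sg = 1, se = 0.5,
                               mu = 5) {
  set.seed(seed)
  geno <- sprintf("G%03d", seq_len(g))
  gv <- stats::rnorm(g, 0, sqrt(sg))
  d <- expand.grid(genotype_name = geno, rep = seq_len(reps),
                   stringsAsFactors = FALSE)
  d$site_id <- "S1"
  d$block <- 1L
  d$gy_t_ha <- mu + gv[match(d$genotype_name, geno)] +
    stats::rnorm(nrow(d), 0, sqrt(se))
  d
}
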