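## Multi-site linear mixed model with factor-analytic genotype-by-site
## covariance, fitted by REML:
##
##   y = 1 mu + X_s s + Z_r r + Z_b b + Z_g g + Z_ge ge + e
##
## sites fixed; replicates within sites, blocks within replicates,
## genotype main effects and genotype-by-site deviations random and
## mutually independent, with
##   var(r) = s2r I, var(b) = s2b I, var(g) = s2g I_g,
##   var(ge) = Sigma_s (x) I_g,   Sigma_s = Lambda Lambda' + Psi,
##   var(e) = s2e I.
##
## The restricted log-likelihood is evaluated through the sparse
## mixed-model-equation coefficient matrix C = W' R^-1 W + diag(0, G^-1):
##   -2 l_R = (n - p) log 2pi + log|R| + log|G| + log|C| + y' P y
## with y'Py = y'R^-1 y - rhs' theta_hat, theta_hat = C^-1 rhs,
## rhs = W' R^-1 y. Maximization is quasi-Newton (L-BFGS-B) on
## transformed parameters: log variances, free loadings (for k > 1 the
## upper-right triangle of Lambda is fixed at zero), log specific
## variances.

#' Build the multi-site mixed-model design
#'
#' Internal: factors, sparse design matrices and their precomputed cross
#' products for one analysis group (a set of sites sharing an entry list).
#' Genotype-by-site columns are ordered site-fastest within genotype so the
#' GE precision is I_g (x) Sigma_s^-1.
#' @keywords internal
met_design <- function(plots, trait = "gy_t_ha") {
  stopifnot(all(c("site_id", "rep", "block", "genotype_name") %in% names(plots)),
            trait %in% names(plots))
  d <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  site_ids <- sort(unique(d$site_id))
  if (length(site_ids) < 2)
    stop("multi-site model needs >= 2 sites; use fit_site_model() for a ",
         "single site")
  geno_ids <- sort(unique(d$genotype_name))
  s <- length(site_ids)
  g <- length(geno_ids)
  n <- nrow(d)

  site_f <- factor(d$site_id, levels = site_ids)
  rep_f <- factor(paste(d$site_id, d$rep, sep = "/"))
  blk_f <- factor(paste(d$site_id, d$rep, d$block, sep = "/"))
  geno_f <- factor(d$genotype_name, levels = geno_ids)
  si <- as.integer(site_f)
  gi <- as.integer(geno_f)

  X <- Matrix::sparse.model.matrix(~site_f)
  Zr <- Matrix::sparse.model.matrix(~0 + rep_f)
  Zb <- Matrix::sparse.model.matrix(~0 + blk_f)
  Zg <- Matrix::sparse.model.matrix(~0 + geno_f)
  ge_col <- (gi - 1L) * s + si
  Zge <- Matrix::sparseMatrix(i = seq_len(n), j = ge_col,
                              x = 1, dims = c(n, s * g))
  W <- cbind(X, Zr, Zb, Zg, Zge)
  p <- ncol(X)
  idx <- list(
    beta = seq_len(p),
    r = p + seq_len(ncol(Zr)),
    b = p + ncol(Zr) + seq_len(ncol(Zb)),
    g = p + ncol(Zr) + ncol(Zb) + seq_len(g),
    ge = p + ncol(Zr) + ncol(Zb) + g + seq_len(s * g))

  y <- d[[trait]]
  list(y = y, W = W, WtW = Matrix::crossprod(W),
       Wty = as.numeric(Matrix::crossprod(W, y)),
       yty = sum(y^2), n = n, p = p,
       q_r = ncol(Zr), q_b = ncol(Zb),
       s = s, g = g, idx = idx,
       site_ids = site_ids, geno_ids = geno_ids,
       rep_levels = levels(rep_f), blk_levels = levels(blk_f),
       data = d, trait = trait)
}

## Number of free loading entries for s sites, k factors with the
## upper-right triangle of Lambda constrained to zero.
n_free_loadings <- function(s, k) s * k - k * (k - 1L) / 2L

fa_pack <- function(s2r, s2b, s2g, s2e, Lambda, psi) {
  k <- ncol(Lambda)
  s <- nrow(Lambda)
  free <- unlist(lapply(seq_len(k), function(j) Lambda[j:s, j]))
  c(log(s2r), log(s2b), log(s2g), log(s2e), free, log(psi))
}

fa_unpack <- function(par, s, k) {
  s2 <- exp(par[1:4])
  nl <- n_free_loadings(s, k)
  lam_free <- par[4 + seq_len(nl)]
  Lambda <- matrix(0, s, k)
  pos <- 0L
  for (j in seq_len(k)) {
    m <- s - j + 1L
    Lambda[j:s, j] <- lam_free[pos + seq_len(m)]
    pos <- pos + m
  }
  psi <- exp(par[4 + nl + seq_len(s)])
  list(s2r = s2[1], s2b = s2[2], s2g = s2[3], s2e = s2[4],
       Lambda = Lambda, psi = psi)
}

## Precomputed evaluator for the restricted likelihood: the sparsity
## pattern of the MME coefficient matrix and its symbolic Cholesky
## analysis are built once; each evaluation only refreshes numeric
## values and refactorizes.
fa_evaluator <- function(dd, k) {
  nq <- dd$p + dd$q_r + dd$q_b + dd$g + dd$s * dd$g
  off <- dd$p + dd$q_r + dd$q_b + dd$g
  ## genotype-block-diagonal pattern of I_g (x) Sigma_s^-1 (column-major
  ## within each s x s block, matching rep(as.vector(Sinv), g))
  blk <- rep(seq_len(dd$g), each = dd$s * dd$s)
  jj <- off + (blk - 1L) * dd$s + rep(rep(seq_len(dd$s), each = dd$s), dd$g)
  ii <- off + (blk - 1L) * dd$s + rep(seq_len(dd$s), dd$s * dd$g)
  Kaug <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nq, nq))
  diag_pos <- c(rep(0L, dd$p), rep(1L, dd$q_r), rep(2L, dd$q_b),
                rep(3L, dd$g), rep(0L, dd$s * dd$g))
  Ch_sym <- NULL

  build_C <- function(th, Sinv) {
    Kaug@x <- rep(as.vector(Sinv), dd$g)
    dvec <- c(0, 1 / th$s2r, 1 / th$s2b, 1 / th$s2g)[diag_pos + 1L]
    Matrix::forceSymmetric(
      dd$WtW / th$s2e + Matrix::Diagonal(nq, dvec) + Kaug)
  }

  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  compute_state <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par))
      return(cache$state)
    th <- fa_unpack(par, dd$s, k)
    sigma_s <- tcrossprod(th$Lambda) + diag(th$psi, nrow = dd$s)
    R <- tryCatch(chol(sigma_s), error = function(e) NULL)
    if (is.null(R)) {
      st <- list(bad = TRUE)
    } else {
      Sinv <- chol2inv(R)
      ldet_sigma <- 2 * sum(log(diag(R)))
      C <- build_C(th, Sinv)
      Ch <- NULL
      if (!is.null(Ch_sym))
        Ch <- tryCatch(Matrix::update(Ch_sym, C), error = function(e) NULL)
      if (is.null(Ch)) {
        Ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                       error = function(e) NULL)
        if (!is.null(Ch)) Ch_sym <<- Ch
      }
      if (is.null(Ch)) {
        st <- list(bad = TRUE)
      } else {
        ldetC <- as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                                sqrt = FALSE)$modulus)
        rhs <- dd$Wty / th$s2e
        theta <- as.numeric(Matrix::solve(Ch, rhs))
        quad <- dd$yty / th$s2e - sum(rhs * theta)
        ldetG <- dd$q_r * log(th$s2r) + dd$q_b * log(th$s2b) +
          dd$g * log(th$s2g) + dd$g * ldet_sigma
        val <- (dd$n - dd$p) * log(2 * pi) + dd$n * log(th$s2e) +
          ldetG + ldetC + quad
        st <- list(bad = !is.finite(val), value = val, th = th,
                   Sinv = Sinv, Ch = Ch, theta = theta)
      }
    }
    cache$par <- par
    cache$state <- st
    st
  }

  fn <- function(par) {
    st <- compute_state(par)
    if (st$bad) 1e10 else st$value
  }

  ## analytic gradient of -2 l_R on the transformed scale, from the
  ## standard identities Z'PZ = G^-1 - G^-1 C^uu G^-1 and u_hat = G Z'Py:
  ## only the diagonal of C^-1 (scalar-variance blocks) and the s x s
  ## genotype blocks (FA part) are needed.
  gr <- function(par) {
    st <- compute_state(par)
    if (st$bad) return(rep(0, length(par)))
    th <- st$th
    theta <- st$theta
    nq_ <- nq
    Cinv <- as.matrix(Matrix::solve(st$Ch, Matrix::Diagonal(nq_)))
    dCinv <- diag(Cinv)
    i_r <- dd$p + seq_len(dd$q_r)
    i_b <- dd$p + dd$q_r + seq_len(dd$q_b)
    i_g <- dd$p + dd$q_r + dd$q_b + seq_len(dd$g)

    g_scalar <- function(idx, v) {
      q <- length(idx)
      (q / v - sum(dCinv[idx]) / v^2 - sum(theta[idx]^2) / v^2) * v
    }
    d_lr <- g_scalar(i_r, th$s2r)
    d_lb <- g_scalar(i_b, th$s2b)
    d_lg <- g_scalar(i_g, th$s2g)

    ## FA block: B = sum_b C^{ge_b, ge_b}, M = sum_b v_b v_b'
    U <- matrix(theta[off + seq_len(dd$s * dd$g)], nrow = dd$s)  # s x g
    V <- st$Sinv %*% U
    M <- tcrossprod(V)
    B <- matrix(0, dd$s, dd$s)
    for (b in seq_len(dd$g)) {
      ib <- off + (b - 1L) * dd$s + seq_len(dd$s)
      B <- B + Cinv[ib, ib]
    }
    Gmat <- dd$g * st$Sinv - st$Sinv %*% B %*% st$Sinv - M
    dLam <- 2 * (Gmat %*% th$Lambda)
    d_lam <- unlist(lapply(seq_len(k), function(j) dLam[j:dd$s, j]))
    d_lpsi <- diag(Gmat) * th$psi

    ## residual: tr(P) = (n - nq + tr(Cinv D)) / s2e; e = y - W theta
    trCD <- sum(dCinv[i_r]) / th$s2r + sum(dCinv[i_b]) / th$s2b +
      sum(dCinv[i_g]) / th$s2g +
      sum(st$Sinv * B)
    ee <- dd$yty - 2 * sum(theta * dd$Wty) +
      sum(theta * as.numeric(dd$WtW %*% theta))
    d_s2e <- (dd$n - nq_ + trCD) / th$s2e - ee / th$s2e^2
    d_le <- d_s2e * th$s2e

    c(d_lr, d_lb, d_lg, d_le, d_lam, d_lpsi)
  }

  list(fn = fn, gr = gr)
}

## -2 * restricted log-likelihood at the given parameters (one-shot
## convenience wrapper around the evaluator)
fa_m2ll <- function(par, dd, k) fa_evaluator(dd, k)$fn(par)

## Method-of-moments starting values: the cross-site covariance of
## genotype means carries sigma^2_g + Lambda Lambda' + Psi off the
## diagonal of residual noise; its leading eigenvector seeds Lambda.
fa_start_values <- function(dd, k) {
  d <- dd$data
  y <- d[[dd$trait]]
  cell <- tapply(y, list(d$genotype_name, d$site_id), mean)
  within_var <- tapply(y, list(d$genotype_name, d$site_id), stats::var)
  s2e0 <- mean(within_var, na.rm = TRUE)
  if (!is.finite(s2e0) || s2e0 <= 0) s2e0 <- stats::var(y) / 2
  r_bar <- max(1, mean(table(d$genotype_name, d$site_id)[
    table(d$genotype_name, d$site_id) > 0]))
  Cm <- stats::cov(cell, use = "pairwise.complete.obs")
  Cm[!is.finite(Cm)] <- 0
  offd <- Cm[upper.tri(Cm)]
  s2g0 <- max(stats::var(y) / 50, min(offd[offd > 0], na.rm = TRUE) / 2,
              na.rm = TRUE)
  if (!is.finite(s2g0)) s2g0 <- stats::var(y) / 50
  Cg <- Cm - s2g0
  diag(Cg) <- pmax(diag(Cm) - s2e0 / r_bar - s2g0, stats::var(y) / 100)
  eg <- eigen((Cg + t(Cg)) / 2, symmetric = TRUE)
  Lambda <- matrix(0, dd$s, k)
  for (j in seq_len(k)) {
    ev <- max(eg$values[j], stats::var(y) / 100)
    Lambda[, j] <- eg$vectors[, j] * sqrt(ev)
    if (j > 1) Lambda[seq_len(j - 1), j] <- 0
  }
  Lambda <- canonicalize_loadings(Lambda)
  psi0 <- pmax(diag(Cg) - rowSums(Lambda^2), stats::var(y) / 100)
  list(s2r = stats::var(y) / 20, s2b = stats::var(y) / 20,
       s2g = s2g0, s2e = s2e0, Lambda = Lambda, psi = psi0)
}

## Canonicalize loading signs: first nonzero entry of each factor positive.
canonicalize_loadings <- function(Lambda, tol = 1e-10) {
  for (j in seq_len(ncol(Lambda))) {
    nz <- which(abs(Lambda[, j]) > tol)
    if (length(nz) && Lambda[nz[1], j] < 0) Lambda[, j] <- -Lambda[, j]
  }
  Lambda
}

#' Fit the multi-site factor-analytic mixed model by REML
#'
#' Maximizes the restricted likelihood of the multi-site model with fixed
#' site effects, independent random replicate, block and genotype terms,
#' and a genotype-by-site term with covariance
#' (Lambda Lambda' + Psi) (x) I_g. Optimization is quasi-Newton on log
#' variances, free loadings and log specific variances; for k > 1 the
#' upper-right triangle of Lambda is fixed at zero (rotation constraint)
#' and loadings are sign-canonicalized (first nonzero loading of each
#' factor positive).
#'
#' @param plots plot observations spanning >= 2 sites of one analysis
#'   group (an environment label x nursery year).
#' @param trait trait column name.
#' @param k_factors factor-analytic order (default 1); must be < number of
#'   sites.
#' @param group optional list/character tagging the group (label, year).
#' @param start optional named list of starting values (s2r, s2b, s2g,
#'   s2e, Lambda, psi).
#' @param maxit maximum quasi-Newton iterations (default 300).
#' @param reltol relative convergence tolerance on -2 log L (default 1e-8).
#' @return list of class `fa_fit` with loadings, specific_variances,
#'   var_rep, var_block, var_genotype, var_residual, reml_loglik, aic,
#'   bic, n_iterations, converged, site_ids, k_factors, the design, and
#'   the solved mixed-model effects (see [solve_mme()]).
#' @export
reml_fit_fa <- function(plots, trait = "gy_t_ha", k_factors = 1L,
                        group = NULL, start = NULL, maxit = 300L,
                        reltol = 1e-8) {
  dd <- met_design(plots, trait)
  s <- dd$s
  k <- as.integer(k_factors)
  if (k >= s) stop("k_factors must be smaller than the number of sites")
  if (k < 1) stop("k_factors must be >= 1")

  if (is.null(start)) start <- fa_start_values(dd, k)
  par0 <- fa_pack(start$s2r, start$s2b, start$s2g, start$s2e,
                  start$Lambda, start$psi)
  nl <- n_free_loadings(s, k)
  lower <- c(rep(-18, 4), rep(-50, nl), rep(-18, s))
  upper <- c(rep(12, 4), rep(50, nl), rep(12, s))
  par0 <- pmin(pmax(par0, lower), upper)

  obj <- fa_evaluator(dd, k)
  opt <- stats::optim(par0, obj$fn, obj$gr,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = reltol / 1e-15))
  th <- fa_unpack(opt$par, s, k)
  th$Lambda <- canonicalize_loadings(th$Lambda)
  at_bound <- th$psi <= exp(-18) * 1.01
  flags <- character(0)
  if (any(at_bound))
    flags <- c(flags, paste0("psi_at_boundary:",
                             paste(dd$site_ids[at_bound], collapse = ",")))
  converged <- opt$convergence == 0
  if (!converged) flags <- c(flags, "optimizer_not_converged")

  m2ll <- opt$value
  n_par <- length(par0)
  fit <- list(group = group,
              site_ids = dd$site_ids,
              geno_ids = dd$geno_ids,
              k_factors = k,
              loadings = th$Lambda,
              specific_variances = th$psi,
              var_rep = th$s2r, var_block = th$s2b,
              var_genotype = th$s2g, var_residual = th$s2e,
              reml_loglik = -m2ll / 2,
              aic = m2ll + 2 * n_par,
              bic = m2ll + log(dd$n) * n_par,
              n_par = n_par,
              n_iterations = unname(opt$counts[1]),
              converged = converged,
              flags = flags,
              design = dd)
  fit$mme <- solve_mme(dd, fit)
  class(fit) <- "fa_fit"
  fit
}

#' Solve the mixed-model equations at fixed variance parameters
#'
#' Henderson's equations for the multi-site model: returns fixed-effect
#' estimates and BLUPs of every random term at the supplied variance
#' parameters. Exact (sparse Cholesky) for the dense small problems used
#' in validation and for routine group sizes alike.
#'
#' @param design a design from [met_design()] (or plot data, from which
#'   one is built with `trait`).
#' @param pars list with var_rep, var_block, var_genotype, var_residual,
#'   loadings (site x k), specific_variances.
#' @param trait trait used if `design` is a data.frame.
#' @param se whether to return prediction variances (dense inverse of the
#'   coefficient matrix; skipped with NA above 4000 equations).
#' @return list: beta (named fixed effects), mu, site_effects, u_r, u_b,
#'   u_g (named genotype BLUPs), u_ge (genotype x site matrix), fitted,
#'   and (if `se`) pev_g, pev_ge, pev_tot (prediction error variances).
#' @export
solve_mme <- function(design, pars, trait = "gy_t_ha", se = TRUE) {
  dd <- if (is.data.frame(design)) met_design(design, trait) else design
  lam <- pars$loadings
  if (is.null(dim(lam))) lam <- matrix(lam, ncol = 1)
  psi <- pars$specific_variances
  sigma_s <- tcrossprod(lam) + diag(psi, nrow = dd$s)
  ## guard a singular Sigma_s (e.g. psi = 0 with rank-deficient Lambda)
  ev <- eigen(sigma_s, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) < 1e-10 * max(max(ev), 1)) ridge <- 1e-8 * max(max(ev), 1)
  Sinv <- chol2inv(chol(sigma_s + diag(ridge, dd$s)))

  ## vanishing variances: treat as hard-zero effects (infinite shrinkage)
  eps <- 1e-12
  inv_or_huge <- function(v) if (v < eps) 1e12 else 1 / v
  Ginv <- Matrix::bdiag(
    Matrix::Diagonal(dd$p, 0),
    Matrix::Diagonal(dd$q_r, inv_or_huge(pars$var_rep)),
    Matrix::Diagonal(dd$q_b, inv_or_huge(pars$var_block)),
    Matrix::Diagonal(dd$g, inv_or_huge(pars$var_genotype)),
    Matrix::Diagonal(dd$g) %x% Matrix::Matrix(Sinv))
  s2e <- pars$var_residual
  if (s2e < eps) s2e <- eps
  C <- Matrix::forceSymmetric(dd$WtW / s2e + Ginv)
  Ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(Ch)) {
    warning("singular mixed-model equations; using minimum-norm solution")
    theta <- as.numeric(MASS_ginv_solve(as.matrix(C), dd$Wty / s2e))
  } else {
    theta <- as.numeric(Matrix::solve(Ch, dd$Wty / s2e))
  }

  beta <- theta[dd$idx$beta]
  names(beta) <- colnames(dd$W)[dd$idx$beta]
  mu <- beta[1]
  site_eff <- c(0, beta[-1])
  names(site_eff) <- dd$site_ids
  u_g <- theta[dd$idx$g]
  names(u_g) <- dd$geno_ids
  u_ge <- matrix(theta[dd$idx$ge], nrow = dd$s, ncol = dd$g)
  dimnames(u_ge) <- list(dd$site_ids, dd$geno_ids)
  u_ge <- t(u_ge)  # genotype x site

  out <- list(beta = beta, mu = unname(mu), site_effects = site_eff,
              u_r = stats::setNames(theta[dd$idx$r], dd$rep_levels),
              u_b = stats::setNames(theta[dd$idx$b], dd$blk_levels),
              u_g = u_g, u_ge = u_ge,
              fitted = as.numeric(dd$W %*% theta))
  if (se) {
    nq <- nrow(C)
    if (nq <= 4000 && !is.null(Ch)) {
      Cinv <- as.matrix(Matrix::solve(Ch, Matrix::Diagonal(nq)))
      pev_g <- diag(Cinv)[dd$idx$g]
      names(pev_g) <- dd$geno_ids
      pev_ge <- matrix(diag(Cinv)[dd$idx$ge], nrow = dd$s)
      ## PEV of the total genetic prediction g + ge per cell
      pev_tot <- matrix(NA_real_, dd$g, dd$s,
                        dimnames = list(dd$geno_ids, dd$site_ids))
      for (ig in seq_len(dd$g)) {
        rg <- dd$idx$g[ig]
        for (is_ in seq_len(dd$s)) {
          rge <- dd$idx$ge[(ig - 1L) * dd$s + is_]
          pev_tot[ig, is_] <- Cinv[rg, rg] + Cinv[rge, rge] +
            2 * Cinv[rg, rge]
        }
      }
      out$pev_g <- pev_g
      out$pev_tot <- pev_tot
    } else {
      out$pev_g <- stats::setNames(rep(NA_real_, dd$g), dd$geno_ids)
      out$pev_tot <- matrix(NA_real_, dd$g, dd$s,
                            dimnames = list(dd$geno_ids, dd$site_ids))
    }
  }
  out
}

## tiny pseudo-inverse solve, only reached on singular systems
MASS_ginv_solve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], b))
}

#' BLUP table from a fitted multi-site model
#'
#' Per-genotype-per-site total genetic predictions (g + ge), per-genotype
#' across-site predicted means (mu + average site effect + g + average
#' ge), and the predicted local-check mean of the group.
#'
#' @param fit an `fa_fit` from [reml_fit_fa()].
#' @param plots optional plot data identifying local checks (defaults to
#'   the data the model was fitted to).
#' @return list of class `blup_table`: `cells` (genotype, site, blup,
#'   predicted, se), `genotype_means` (genotype, is_local_check,
#'   blup_main, across_site_mean, se), `lc_mean`, `group`.
#' @export
compute_blups <- function(fit, plots = NULL) {
  stopifnot(inherits(fit, "fa_fit"))
  dd <- fit$design
  mme <- fit$mme
  if (is.null(plots)) plots <- dd$data
  lc_map <- tapply(plots$is_local_check, plots$genotype_name, any)
  is_lc <- as.logical(lc_map[dd$geno_ids])
  is_lc[is.na(is_lc)] <- FALSE

  tot <- sweep(mme$u_ge, 1, mme$u_g, "+")   # genotype x site, g + ge
  mean_site <- mean(mme$site_effects)
  pred_cell <- mme$mu +
    matrix(mme$site_effects, nrow = dd$g, ncol = dd$s, byrow = TRUE) + tot
  cells <- data.frame(
    genotype = rep(dd$geno_ids, times = dd$s),
    site_id = rep(dd$site_ids, each = dd$g),
    blup = as.vector(tot),
    predicted = as.vector(pred_cell),
    se = as.vector(sqrt(pmax(0, mme$pev_tot))),
    stringsAsFactors = FALSE)

  across <- mme$mu + mean_site + mme$u_g + rowMeans(mme$u_ge)
  genotype_means <- data.frame(
    genotype = dd$geno_ids,
    is_local_check = is_lc,
    blup_main = unname(mme$u_g),
    across_site_mean = unname(across),
    se = unname(sqrt(pmax(0, mme$pev_g))),
    stringsAsFactors = FALSE)

  lc_mean <- if (any(is_lc)) mean(across[is_lc]) else NA_real_
  out <- list(cells = cells, genotype_means = genotype_means,
              lc_mean = lc_mean, group = fit$group,
              site_ids = dd$site_ids)
  class(out) <- "blup_table"
  out
}

#' Site-wise genetic covariance and correlation of a fitted model
#'
#' Sigma_s = Lambda Lambda' + Psi; correlations use the total per-site
#' genetic variance sigma^2_g + Sigma_s[j, j], so that the genotype main
#' effect contributes a common (perfectly correlated) component.
#'
#' @param fit an `fa_fit`.
#' @return list with `covariance` (Sigma_s), `total_covariance`
#'   (sigma^2_g + Sigma_s), `correlation`.
#' @export
genetic_covariance <- function(fit) {
  lam <- fit$loadings
  if (is.null(dim(lam))) lam <- matrix(lam, ncol = 1)
  s <- length(fit$specific_variances)
  sigma_s <- tcrossprod(lam) + diag(fit$specific_variances, nrow = s)
  dimnames(sigma_s) <- list(fit$site_ids, fit$site_ids)
  tot <- sigma_s + fit$var_genotype
  d <- sqrt(diag(tot))
  corr <- tot / outer(d, d)
  list(covariance = sigma_s, total_covariance = tot, correlation = corr)
}

#' Fit the factor-analytic model for every analysis group
#'
#' Splits retained plots by (environment label, nursery year), fits
#' [reml_fit_fa()] in each group with >= 2 sites, and returns fits plus
#' BLUP tables. Groups with a single site are skipped with a note.
#'
#' @param plots plot observations (already filtered to retained sites).
#' @param env_labels data.frame site_id, label.
#' @param trait trait column.
#' @param k_factors FA order.
#' @param ... passed to [reml_fit_fa()].
#' @return list of per-group lists (fit, blups), named "label/year".
#' @export
fit_fa_groups <- function(plots, env_labels, trait = "gy_t_ha",
                          k_factors = 1L, ...) {
  plots$label <- env_labels$label[match(plots$site_id, env_labels$site_id)]
  plots <- plots[!is.na(plots$label), , drop = FALSE]
  keys <- unique(plots[, c("label", "year")])
  keys <- keys[order(keys$label, keys$year), ]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- plots[plots$label == keys$label[i] & plots$year == keys$year[i], ]
    nm <- paste(keys$label[i], keys$year[i], sep = "/")
    if (length(unique(sub$site_id)) < 2) {
      out[[nm]] <- list(skipped = TRUE,
                        reason = "fewer than 2 sites in group")
      next
    }
    fit <- reml_fit_fa(sub, trait = trait, k_factors = k_factors,
                       group = list(label = keys$label[i],
                                    year = keys$year[i]), ...)
    out[[nm]] <- list(fit = fit, blups = compute_blups(fit))
  }
  out
}
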