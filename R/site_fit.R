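#' Fit the per-site alpha-lattice model for one trait
#'
#' Fits the single-site linear mixed model
#' y_ijk = mu + R_j + B_k(R_j) + G_i + e_ijk with replicates and genotypes
#' fixed and incomplete blocks within replicates random, by REML. Because
#' heritability needs a genotype variance, a companion refit with genotypes
#' random is performed solely to obtain sigma^2_g; adjusted genotype means
#' come from the fixed-genotype fit.
#'
#' @param plots data.frame of plot observations for a single site with
#'   columns rep, block, genotype_name and the trait column.
#' @param trait name of the trait column (default "gy_t_ha").
#' @return a list of class `site_fit`: site_id, grand_mean, rep_effects,
#'   block_variance, genotype_variance, residual_variance, heritability,
#'   n_reps, genotype_adjusted_means, converged, flags.
#' @export
fit_site_model <- function(plots, trait = "gy_t_ha") {
  stopifnot(all(c("rep", "block", "genotype_name") %in% names(plots)),
            trait %in% names(plots))
  d <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  site_id <- if ("site_id" %in% names(d) && nrow(d)) d$site_id[1] else NA_character_
  n_reps <- length(unique(d$rep))
  if (n_reps < 2) stop("fit_site_model needs >= 2 replicates with data")
  if (length(unique(d$genotype_name)) < 2)
    stop("fit_site_model needs >= 2 genotypes with data")

  d$y <- d[[trait]]
  d$rep_f <- factor(d$rep)
  d$geno_f <- factor(d$genotype_name)
  d$blk_f <- factor(paste(d$rep, d$block, sep = ":"))
  contrasts(d$rep_f) <- stats::contr.sum(nlevels(d$rep_f))

  flags <- character(0)
  has_blocks <- any(tapply(d$blk_f, d$rep_f, function(b) length(unique(b))) > 1)
  if (!has_blocks) flags <- c(flags, "no_block_structure")

  ## genotypes observed in a single replicate make the design singular for
  ## rep adjustment; the fit proceeds but is flagged
  reps_per_geno <- tapply(d$rep, d$geno_f, function(r) length(unique(r)))
  if (any(reps_per_geno < 2)) flags <- c(flags, "singular_design")

  if (stats::var(d$y) == 0) {
    mu <- mean(d$y)
    am <- tapply(d$y, d$geno_f, mean)
    fit <- list(site_id = site_id, grand_mean = mu,
                rep_effects = stats::setNames(rep(0, n_reps),
                                              levels(d$rep_f)),
                block_variance = 0, genotype_variance = 0,
                residual_variance = 0, heritability = 0,
                n_reps = n_reps,
                genotype_adjusted_means = as.numeric(am),
                converged = TRUE,
                flags = c(flags, "degenerate_constant_response"))
    names(fit$genotype_adjusted_means) <- names(am)
    class(fit) <- "site_fit"
    return(fit)
  }

  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    calc.derivs = FALSE,
    optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-12))

  ## fixed-genotype fit: adjusted means and block/residual components
  converged <- TRUE
  if (has_blocks) {
    ff <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ rep_f + geno_f + (1 | blk_f), data = d,
                   REML = TRUE, control = ctrl))),
      error = function(e) NULL)
  } else ff <- NULL
  if (is.null(ff)) {
    lmfit <- stats::lm(y ~ rep_f + geno_f, data = d)
    beta <- stats::coef(lmfit)
    blk_var <- 0
    res_var <- stats::sigma(lmfit)^2
    if (has_blocks) {
      converged <- FALSE
      flags <- c(flags, "block_fit_failed")
    } else flags <- unique(c(flags, "no_block_structure"))
  } else {
    beta <- lme4::fixef(ff)
    vc <- as.data.frame(lme4::VarCorr(ff))
    blk_var <- vc$vcov[vc$grp == "blk_f"]
    res_var <- vc$vcov[vc$grp == "Residual"]
  }
  beta[is.na(beta)] <- 0
  mu <- beta[["(Intercept)"]]
  rep_coefs <- beta[grep("^rep_f", names(beta))]
  rep_effects <- c(rep_coefs, -sum(rep_coefs))  # contr.sum: last is -sum
  names(rep_effects) <- levels(d$rep_f)
  geno_lvls <- levels(d$geno_f)
  gcoef <- stats::setNames(rep(0, length(geno_lvls)), geno_lvls)
  gi <- beta[grep("^geno_f", names(beta))]
  gcoef[sub("^geno_f", "", names(gi))] <- gi
  adj_means <- mu + gcoef  # at the average replicate (sum contrasts)

  ## random-genotype refit: sigma^2_g for heritability
  rf_form <- if (has_blocks) y ~ rep_f + (1 | geno_f) + (1 | blk_f)
             else y ~ rep_f + (1 | geno_f)
  rf <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(rf_form, data = d, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  if (is.null(rf)) {
    g_var <- 0
    converged <- FALSE
    flags <- c(flags, "random_genotype_fit_failed")
  } else {
    vcr <- as.data.frame(lme4::VarCorr(rf))
    g_var <- vcr$vcov[vcr$grp == "geno_f"]
    res_var_r <- vcr$vcov[vcr$grp == "Residual"]
  }

  fit <- list(site_id = site_id, grand_mean = unname(mu),
              rep_effects = rep_effects,
              block_variance = max(0, blk_var),
              genotype_variance = max(0, g_var),
              residual_variance = max(0,
                if (exists("res_var_r", inherits = FALSE)) res_var_r else res_var),
              fixed_residual_variance = max(0, res_var),
              n_reps = n_reps,
              genotype_adjusted_means = adj_means,
              converged = converged,
              flags = flags)
  fit$heritability <- estimate_heritability(fit)
  class(fit) <- "site_fit"
  fit
}

#' Entry-mean heritability from a site fit
#'
#' H^2 = sigma^2_g / (sigma^2_g + sigma^2_e / r) on the entry-mean basis
#' (r = number of replicates), clamped to [0, 1]. A plot-basis variant
#' sigma^2_g / (sigma^2_g + sigma^2_e) is available.
#'
#' @param fit a `site_fit`, or any list with genotype_variance,
#'   residual_variance and n_reps.
#' @param basis "entry_mean" (default) or "plot".
#' @return heritability in [0, 1].
#' @export
estimate_heritability <- function(fit, basis = c("entry_mean", "plot")) {
  basis <- match.arg(basis)
  vg <- fit$genotype_variance
  ve <- fit$residual_variance
  r <- fit$n_reps
  denom <- if (basis == "entry_mean") vg + ve / r else vg + ve
  if (denom <= 0) {
    warning("all variance components are zero; heritability set to 0")
    return(0)
  }
  min(1, max(0, vg / denom))
}

#' Heritability-based site filter
#'
#' Sites with H^2 strictly below the threshold are excluded from further
#' analysis; the boundary value is retained.
#'
#' @param fits list of `site_fit` objects (or a data.frame with site_id and
#'   heritability columns).
#' @param threshold exclusion threshold (default 0.05).
#' @return list with `retained` (site ids), `report` (data.frame site_id,
#'   heritability, retained, reason).
#' @export
filter_sites <- function(fits, threshold = 0.05) {
  if (is.data.frame(fits)) {
    tab <- fits[, c("site_id", "heritability")]
  } else {
    if (length(fits) == 0) {
      warning("no site fits supplied; nothing retained")
      return(list(retained = character(0),
                  report = data.frame(site_id = character(0),
                                      heritability = numeric(0),
                                      retained = logical(0),
                                      reason = character(0))))
    }
    tab <- data.frame(
      site_id = vapply(fits, function(f) as.character(f$site_id), ""),
      heritability = vapply(fits, function(f) f$heritability, 0),
      stringsAsFactors = FALSE)
  }
  keep <- tab$heritability >= threshold
  tab$retained <- keep
  tab$reason <- ifelse(keep, "",
                       sprintf("H2 = %.4f < %.4f", tab$heritability, threshold))
  list(retained = tab$site_id[keep], report = tab)
}

#' Site-fit summary table
#'
#' One row per site with variance components, heritability and flags.
#' @param fits list of `site_fit` objects.
#' @return data.frame.
#' @export
site_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    site_id = as.character(f$site_id),
    grand_mean = f$grand_mean,
    block_variance = f$block_variance,
    genotype_variance = f$genotype_variance,
    residual_variance = f$residual_variance,
    heritability = f$heritability,
    n_reps = f$n_reps,
    converged = f$converged,
    flags = paste(f$flags, collapse = ";"),
    stringsAsFactors = FALSE)))
}
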