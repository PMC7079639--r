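#' Simulation configuration for a synthetic international yield-trial program
#'
#' Builds the parameter list that [simulate_program()] consumes. Defaults
#' describe a ten-year high-rainfall nursery program: 50 entries per annual
#' nursery (a fresh set every year) plus one local check per site, an
#' alpha-lattice layout with 2 replicates of 5 incomplete blocks, a linear
#' elite genetic trend of 0.16 t ha-1 yr-1, factor-analytic (rank-1)
#' site-wise genetic covariance, and sites drawn around two climate centres
#' (high rainfall: 282 mm / 9.34 C / 781 m; low rainfall: 53 mm / 9.87 C /
#' 329 m) mixed 57.7:42.3.
#'
#' @param n_years number of annual nursery cycles.
#' @param entries_per_year elite entries distributed each year (>= 2).
#' @param n_sites_per_year trial sites per year.
#' @param n_reps replicates per site (>= 2).
#' @param n_blocks_per_rep incomplete blocks per replicate.
#' @param true_annual_gain elite genetic trend, t ha-1 yr-1.
#' @param baseline_yield overall mean yield mu, t ha-1.
#' @param fa_loadings per-site loadings of the rank-1 genetic factor
#'   (sqrt-variance units, t ha-1); recycled to `n_sites_per_year`.
#' @param fa_specific_vars per-site specific genetic variances (diagonal of
#'   Psi), (t ha-1)^2; recycled to `n_sites_per_year`.
#' @param var_genotype,var_rep,var_block,var_residual,var_site variance
#'   components of the generating model, (t ha-1)^2.
#' @param env_mix fraction of sites drawn from the high-rainfall climate
#'   centre (default 0.577).
#' @param climate_centers 2 x 3 matrix (rows `high`, `low`; columns
#'   precipitation mm, mean minimum temperature C, altitude m).
#' @param climate_spread per-variable standard deviation of sites around
#'   their centre.
#' @param local_check_lag t ha-1 by which a site's local check trails the
#'   elite mean in the first year.
#' @param local_check_lag_trend t ha-1 yr-1 by which the local-check lag
#'   widens, i.e. the elite-minus-check trend (default 0.0651).
#' @param trait_trends named annual slopes for gw_mg (mg yr-1), dm_days,
#'   dh_days (d yr-1) and ph_cm (cm yr-1).
#' @param trait_base named first-year trait means.
#' @param first_year_index nursery index of the first cycle (default 15).
#' @param seed integer seed; all randomness flows from it through named
#'   substreams.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_years = 10L,
                       entries_per_year = 50L,
                       n_sites_per_year = 8L,
                       n_reps = 2L,
                       n_blocks_per_rep = 5L,
                       true_annual_gain = 0.16,
                       baseline_yield = 4.0,
                       fa_loadings = NULL,
                       fa_specific_vars = NULL,
                       var_genotype = 0.15,
                       var_rep = 0.05,
                       var_block = 0.05,
                       var_residual = 0.4,
                       var_site = 0.25,
                       env_mix = 0.577,
                       climate_centers = default_climate_centers(),
                       climate_spread = c(precip = 40, tmin = 2, altitude = 150),
                       local_check_lag = 0.3,
                       local_check_lag_trend = 0.0651,
                       trait_trends = c(gw_mg = 1.08, dm_days = 4.10,
                                        dh_days = 0.0, ph_cm = 0.0),
                       trait_base = c(gw_mg = 38, dm_days = 112,
                                      dh_days = 68, ph_cm = 85),
                       first_year_index = 15L,
                       seed = 1L) {
  if (is.null(fa_loadings))
    fa_loadings <- seq(0.3, 0.8, length.out = n_sites_per_year)
  if (is.null(fa_specific_vars))
    fa_specific_vars <- rep(0.05, n_sites_per_year)
  fa_loadings <- rep_len(fa_loadings, n_sites_per_year)
  fa_specific_vars <- rep_len(fa_specific_vars, n_sites_per_year)

  cfg <- list(
    n_years = as.integer(n_years),
    entries_per_year = as.integer(entries_per_year),
    n_sites_per_year = as.integer(n_sites_per_year),
    n_reps = as.integer(n_reps),
    n_blocks_per_rep = as.integer(n_blocks_per_rep),
    true_annual_gain = true_annual_gain,
    baseline_yield = baseline_yield,
    fa_loadings = fa_loadings,
    fa_specific_vars = fa_specific_vars,
    var_genotype = var_genotype,
    var_rep = var_rep,
    var_block = var_block,
    var_residual = var_residual,
    var_site = var_site,
    env_mix = env_mix,
    climate_centers = climate_centers,
    climate_spread = climate_spread,
    local_check_lag = local_check_lag,
    local_check_lag_trend = local_check_lag_trend,
    trait_trends = trait_trends,
    trait_base = trait_base,
    first_year_index = as.integer(first_year_index),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  vars <- c("var_genotype", "var_rep", "var_block", "var_residual", "var_site")
  for (v in vars)
    if (cfg[[v]] < 0) stop("variance component '", v, "' must be >= 0")
  if (any(cfg$fa_specific_vars < 0)) stop("fa_specific_vars must be >= 0")
  if (cfg$env_mix < 0 || cfg$env_mix > 1) stop("env_mix must be in [0, 1]")
  if (cfg$entries_per_year < 2) stop("entries_per_year must be >= 2")
  if (cfg$n_reps < 2) stop("n_reps must be >= 2")
  if (cfg$n_sites_per_year < 1) stop("need at least one site per year")
  if (cfg$n_years < 1) stop("need at least one year")
  invisible(cfg)
}

#' Table-1 style climate centres
#'
#' High-rainfall sites average 282 mm precipitation and 9.34 C mean minimum
#' temperature in the coolest quarter at 781 m; low-rainfall sites 53 mm,
#' 9.87 C, 329 m.
#' @return 2 x 3 numeric matrix with rows `high`, `low`.
#' @export
default_climate_centers <- function() {
  m <- rbind(high = c(precip = 282, tmin = 9.34, altitude = 781),
             low  = c(precip = 53,  tmin = 9.87, altitude = 329))
  m
}

## Independent substream seeds so design, genetics, climate and residual
## draws can each be regenerated without replaying the others.
sim_substreams <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("climate", "design", "genetics", "traits", "residual")
  s
}

#' Generate site climate covariates around two centres
#'
#' Sites are assigned to the high-rainfall centre with probability
#' `env_mix` and their covariates drawn normally around the centre with the
#' given per-variable spread. Precipitation is truncated at zero.
#'
#' @param n_sites number of sites (> 0).
#' @param env_mix probability a site is high-rainfall.
#' @param centers 2 x 3 matrix as in [default_climate_centers()].
#' @param spread per-variable sd, length 3 (>= 0).
#' @param seed integer seed.
#' @param site_ids optional character vector of site identifiers.
#' @return data.frame with columns site_id, precip_coolest_quarter_mm,
#'   tmin_mean_coolest_C, altitude_m, true_env (generating label).
#' @export
generate_site_climate <- function(n_sites, env_mix = 0.577,
                                  centers = default_climate_centers(),
                                  spread = c(40, 2, 150),
                                  seed = 1L,
                                  site_ids = NULL) {
  if (n_sites <= 0) stop("n_sites must be positive")
  if (any(spread < 0)) stop("spread must be >= 0")
  set.seed(seed)
  lab <- ifelse(stats::runif(n_sites) < env_mix, "high", "low")
  ctr <- centers[lab, , drop = FALSE]
  precip <- pmax(0, stats::rnorm(n_sites, ctr[, 1], spread[1]))
  tmin <- stats::rnorm(n_sites, ctr[, 2], spread[2])
  alt <- pmax(0, stats::rnorm(n_sites, ctr[, 3], spread[3]))
  if (is.null(site_ids)) site_ids <- sprintf("S%03d", seq_len(n_sites))
  data.frame(site_id = site_ids,
             precip_coolest_quarter_mm = precip,
             tmin_mean_coolest_C = tmin,
             altitude_m = alt,
             true_env = ifelse(lab == "high", "high_rainfall", "low_rainfall"),
             stringsAsFactors = FALSE)
}

## Partition a shuffled entry vector into n_blocks incomplete blocks with
## sizes as equal as possible; returns the block index per entry.
alpha_lattice_blocks <- function(n_entries, n_blocks) {
  base <- n_entries %/% n_blocks
  extra <- n_entries %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, extra), rep(0L, n_blocks - extra))
  rep(seq_len(n_blocks), times = sizes)
}

#' Simulate a multi-year, multi-site yield-trial program
#'
#' Generates plot-level data emulating an international nursery: each year a
#' fresh set of elite entries plus one distinct local check per site, laid
#' out as an alpha-lattice (replicates subdivided into incomplete blocks).
#' A plot's yield is mu + site effect + replicate effect + block effect +
#' the entry's genetic value (carrying the year-indexed elite trend) + a
#' factor-analytic site-specific genetic deviation + residual. Grain weight,
#' days to maturity, days to heading and plant height are generated with
#' configurable annual trends and a positive genetic association of grain
#' weight and maturity with yield.
#'
#' @param config a [sim_config()] list.
#' @return list with `plots` (one row per plot: year, site_id, rep, block,
#'   entry, genotype_name, is_local_check, gy_g_m2, gy_t_ha, dh, dm, ph_cm,
#'   gw_mg), `climate` (per-site covariates and generating labels) and
#'   `truth` (true genetic values, site labels, generating slopes, variance
#'   components and the site-wise genetic covariance
#'   Sigma_s = Lambda Lambda' + Psi).
#' @export
simulate_program <- function(config) {
  validate_sim_config(config)
  cfg <- config
  ss <- sim_substreams(cfg$seed)

  years <- cfg$first_year_index + seq_len(cfg$n_years) - 1L
  s <- cfg$n_sites_per_year
  lam <- cfg$fa_loadings
  psi <- cfg$fa_specific_vars
  sigma_s <- tcrossprod(lam) + diag(psi, nrow = s)

  ## climate + generating environment labels, one set of sites per year
  site_ids <- as.vector(vapply(years, function(y)
    sprintf("Y%02d_S%02d", y, seq_len(s)), character(s)))
  climate <- generate_site_climate(length(site_ids), cfg$env_mix,
                                   cfg$climate_centers, cfg$climate_spread,
                                   seed = ss[["climate"]],
                                   site_ids = site_ids)

  ## genetics: per-year entry genetic values and FA site deviations
  set.seed(ss[["genetics"]])
  truth_geno <- list()
  geno_vals <- list()     # named genetic values per year
  ge_dev <- list()        # entries x sites matrices per year
  site_eff <- list()
  for (yi in seq_len(cfg$n_years)) {
    y <- years[yi]
    elite <- sprintf("Y%02d_L%02d", y, seq_len(cfg$entries_per_year))
    lcs <- sprintf("LC_Y%02d_S%02d", y, seq_len(s))
    year_mean <- cfg$true_annual_gain * (yi - 1L)
    g_elite <- year_mean +
      stats::rnorm(cfg$entries_per_year, 0, sqrt(cfg$var_genotype))
    lc_mean <- year_mean - cfg$local_check_lag -
      cfg$local_check_lag_trend * (yi - 1L)
    g_lc <- lc_mean + stats::rnorm(s, 0, sqrt(cfg$var_genotype))
    g <- c(g_elite, g_lc)
    names(g) <- c(elite, lcs)
    geno_vals[[yi]] <- g
    ## site-specific genetic deviations: rank-1 factor + specific part
    f <- stats::rnorm(length(g))
    dev <- outer(f, lam) +
      matrix(stats::rnorm(length(g) * s), length(g), s) %*%
        diag(sqrt(psi), nrow = s)
    rownames(dev) <- names(g)
    ge_dev[[yi]] <- dev
    site_eff[[yi]] <- stats::rnorm(s, 0, sqrt(cfg$var_site))
    truth_geno[[yi]] <- data.frame(
      year = y, genotype_name = names(g),
      is_local_check = grepl("^LC_", names(g)),
      true_value = unname(g), stringsAsFactors = FALSE)
  }

  ## genotype-level trait deviations, correlated with the yield deviation
  set.seed(ss[["traits"]])
  trait_names <- c("gw_mg", "dm_days", "dh_days", "ph_cm")
  ## loading of each trait on the genotype yield deviation (module
  ## constants, arbitrary but positive for GW/DM so the contribution
  ## analysis has signal); plus independent genotype and plot noise sds
  trait_beta <- c(gw_mg = 3.0, dm_days = 4.0, dh_days = 1.0, ph_cm = 2.0)
  trait_sd_geno <- c(gw_mg = 1.5, dm_days = 2.0, dh_days = 2.0, ph_cm = 4.0)
  trait_sd_plot <- c(gw_mg = 1.5, dm_days = 2.0, dh_days = 1.5, ph_cm = 3.0)
  trait_geno <- list()
  for (yi in seq_len(cfg$n_years)) {
    g <- geno_vals[[yi]]
    ydev <- g - mean(g)
    tg <- sapply(trait_names, function(tr) {
      cfg$trait_base[[tr]] + cfg$trait_trends[[tr]] * (yi - 1L) +
        trait_beta[[tr]] * ydev +
        stats::rnorm(length(g), 0, trait_sd_geno[[tr]])
    })
    rownames(tg) <- names(g)
    trait_geno[[yi]] <- tg
  }

  ## design: alpha-lattice layout per (site, rep)
  set.seed(ss[["design"]])
  block_note <- (cfg$entries_per_year + 1L) %% cfg$n_blocks_per_rep != 0L
  rows <- vector("list", cfg$n_years)
  for (yi in seq_len(cfg$n_years)) {
    y <- years[yi]
    per_site <- vector("list", s)
    for (sj in seq_len(s)) {
      sid <- sprintf("Y%02d_S%02d", y, sj)
      genos <- c(sprintf("Y%02d_L%02d", y, seq_len(cfg$entries_per_year)),
                 sprintf("LC_Y%02d_S%02d", y, sj))
      ne <- length(genos)
      per_rep <- vector("list", cfg$n_reps)
      for (r in seq_len(cfg$n_reps)) {
        ord <- sample.int(ne)
        per_rep[[r]] <- data.frame(
          year = y, site_id = sid, rep = r,
          block = alpha_lattice_blocks(ne, cfg$n_blocks_per_rep),
          entry = ord,
          genotype_name = genos[ord],
          stringsAsFactors = FALSE)
      }
      per_site[[sj]] <- do.call(rbind, per_rep)
    }
    rows[[yi]] <- do.call(rbind, per_site)
  }
  plots <- do.call(rbind, rows)
  plots$is_local_check <- grepl("^LC_", plots$genotype_name)

  ## rep and block effects per (site, rep[, block]); residuals
  set.seed(ss[["residual"]])
  rep_key <- paste(plots$site_id, plots$rep)
  rep_lvls <- unique(rep_key)
  rep_fx <- stats::rnorm(length(rep_lvls), 0, sqrt(cfg$var_rep))
  names(rep_fx) <- rep_lvls
  blk_key <- paste(plots$site_id, plots$rep, plots$block)
  blk_lvls <- unique(blk_key)
  blk_fx <- stats::rnorm(length(blk_lvls), 0, sqrt(cfg$var_block))
  names(blk_fx) <- blk_lvls

  yi_of <- match(plots$year, years)
  sj_of <- as.integer(sub("^Y\\d+_S", "", plots$site_id))
  gval <- numeric(nrow(plots))
  gedev <- numeric(nrow(plots))
  seff <- numeric(nrow(plots))
  tg <- matrix(NA_real_, nrow(plots), length(trait_names),
               dimnames = list(NULL, trait_names))
  for (yi in seq_len(cfg$n_years)) {
    idx <- which(yi_of == yi)
    gv <- geno_vals[[yi]]
    gval[idx] <- gv[plots$genotype_name[idx]]
    gedev[idx] <- ge_dev[[yi]][cbind(match(plots$genotype_name[idx],
                                           rownames(ge_dev[[yi]])),
                                     sj_of[idx])]
    seff[idx] <- site_eff[[yi]][sj_of[idx]]
    tg[idx, ] <- trait_geno[[yi]][plots$genotype_name[idx], ]
  }
  resid <- stats::rnorm(nrow(plots), 0, sqrt(cfg$var_residual))
  plots$gy_t_ha <- cfg$baseline_yield + seff + rep_fx[rep_key] +
    blk_fx[blk_key] + gval + gedev + resid
  plots$gy_g_m2 <- plots$gy_t_ha * 100

  for (tr in trait_names) {
    noise <- stats::rnorm(nrow(plots), 0, trait_sd_plot[[tr]])
    tg[, tr] <- tg[, tr] + noise
  }
  plots$gw_mg <- tg[, "gw_mg"]
  plots$dm <- tg[, "dm_days"]
  plots$dh <- tg[, "dh_days"]
  plots$ph_cm <- tg[, "ph_cm"]
  rownames(plots) <- NULL
  plots <- plots[, c("year", "site_id", "rep", "block", "entry",
                     "genotype_name", "is_local_check",
                     "gy_g_m2", "gy_t_ha", "dh", "dm", "ph_cm", "gw_mg")]

  truth <- list(
    genotypes = do.call(rbind, truth_geno),
    site_env = climate[, c("site_id", "true_env")],
    true_gain = cfg$true_annual_gain,
    true_lc_gap_trend = cfg$local_check_lag_trend,
    trait_trends = cfg$trait_trends,
    variance_components = c(var_genotype = cfg$var_genotype,
                            var_rep = cfg$var_rep,
                            var_block = cfg$var_block,
                            var_residual = cfg$var_residual,
                            var_site = cfg$var_site),
    fa_loadings = lam,
    fa_specific_vars = psi,
    sigma_s = sigma_s,
    block_sizes_adjusted = block_note,
    years = years
  )
  list(plots = plots, climate = climate, truth = truth)
}
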