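## Serialization policy: all tables are comma-separated text with a
## header row; numerics are written at 10 significant digits so reruns
## produce byte-identical files across platforms.
SERIALIZATION_DIGITS <- 10L

#' Write a table as delimited text
#'
#' Comma-separated with header; numeric columns rounded to 10 significant
#' digits for reproducible checksums.
#' @param df data.frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], SERIALIZATION_DIGITS)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a plot-level trial table
#'
#' Comma-separated text with a header. Required columns: year, site_id,
#' rep, block, entry, genotype_name, is_local_check and at least one
#' trait column. Where both gy_g_m2 and gy_t_ha are present their
#' consistency (t ha-1 = g m-2 x 0.01) is cross-checked per row; rows
#' whose key fields cannot be parsed are dropped and counted.
#'
#' @param path csv path.
#' @param gy_tol relative tolerance of the unit cross-check (default 1e-6).
#' @return data.frame of typed plot observations with attribute
#'   "validation": list(n_read, n_dropped, n_gy_inconsistent,
#'   gy_inconsistent_rows, warnings).
#' @export
read_plot_table <- function(path, gy_tol = 1e-6) {
  required <- c("year", "site_id", "rep", "block", "entry",
                "genotype_name", "is_local_check")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("plot table is missing required column(s): ",
         paste(missing, collapse = ", "))
  trait_cols <- setdiff(names(d), required)
  if (length(trait_cols) == 0)
    stop("plot table has no trait columns")
  n_read <- nrow(d)
  warn <- character(0)
  if (n_read == 0) warn <- c(warn, "empty plot table")

  ## coerce key columns; unparseable rows are dropped, not fatal
  suppressWarnings({
    d$year <- as.integer(d$year)
    d$rep <- as.integer(d$rep)
    d$block <- as.integer(d$block)
    d$entry <- as.integer(d$entry)
    d$is_local_check <- as.logical(d$is_local_check)
  })
  bad <- is.na(d$year) | is.na(d$rep) | is.na(d$block) |
    is.na(d$site_id) | is.na(d$genotype_name) | is.na(d$is_local_check)
  n_dropped <- sum(bad)
  if (n_dropped) {
    warn <- c(warn, sprintf("%d row(s) dropped: unparseable key fields",
                            n_dropped))
    d <- d[!bad, , drop = FALSE]
  }
  for (cc in trait_cols)
    suppressWarnings(d[[cc]] <- as.numeric(d[[cc]]))

  gy_bad <- integer(0)
  if (all(c("gy_g_m2", "gy_t_ha") %in% names(d))) {
    both <- !is.na(d$gy_g_m2) & !is.na(d$gy_t_ha)
    rel <- abs(d$gy_t_ha - d$gy_g_m2 * 0.01) /
      pmax(abs(d$gy_g_m2 * 0.01), 1e-12)
    gy_bad <- which(both & rel > gy_tol)
    if (length(gy_bad))
      warn <- c(warn, sprintf("%d row(s) flagged: gy_t_ha != gy_g_m2 x 0.01",
                              length(gy_bad)))
  }
  if (length(warn)) for (w in warn) warning(w, call. = FALSE)
  attr(d, "validation") <- list(n_read = n_read, n_kept = nrow(d),
                                n_dropped = n_dropped,
                                n_gy_inconsistent = length(gy_bad),
                                gy_inconsistent_rows = gy_bad,
                                warnings = warn)
  d
}

#' Read a site climate table
#' @param path csv with site_id, precip_coolest_quarter_mm,
#'   tmin_mean_coolest_C, altitude_m.
#' @return data.frame.
#' @export
read_climate_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "precip_coolest_quarter_mm")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("climate table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(d$precip_coolest_quarter_mm < 0, na.rm = TRUE))
    stop("negative precipitation in climate table")
  if ("altitude_m" %in% names(d) &&
      any(d$altitude_m < -500 | d$altitude_m > 9000, na.rm = TRUE))
    warning("implausible altitude value(s) in climate table")
  d
}

#' Run configuration for the full analysis pipeline
#'
#' @param trait primary yield trait column (default "gy_t_ha").
#' @param physiological_traits trait columns analyzed in the trait stage.
#' @param h2_threshold heritability exclusion threshold (default 0.05).
#' @param kmeans_k,kmeans_restarts k-means settings.
#' @param k_factors FA order of the multi-site model.
#' @param top_n highest-yielding lines per year (default 5).
#' @param percent_denominator see [estimate_gyp_gain()].
#' @param seed integer seed recorded in the manifest and used by every
#'   random stage.
#' @param out_dir output directory (NULL: nothing written).
#' @param verbose print per-stage progress lines.
#' @return list of class `run_config`.
#' @export
run_config <- function(trait = "gy_t_ha",
                       physiological_traits = c("gw_mg", "dm", "dh", "ph_cm"),
                       h2_threshold = 0.05,
                       kmeans_k = 2, kmeans_restarts = 25,
                       k_factors = 1L,
                       top_n = 5,
                       percent_denominator = "hyl_mean",
                       seed = 1L,
                       out_dir = NULL,
                       verbose = FALSE) {
  stopifnot(h2_threshold >= 0, h2_threshold <= 1, top_n >= 1)
  cfg <- list(trait = trait, physiological_traits = physiological_traits,
              h2_threshold = h2_threshold, kmeans_k = kmeans_k,
              kmeans_restarts = kmeans_restarts, k_factors = k_factors,
              top_n = top_n, percent_denominator = percent_denominator,
              seed = as.integer(seed), out_dir = out_dir,
              verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(cfg, ...) if (cfg$verbose) message("[metgain] ", ...)

#' Run the full genetic-gain pipeline
#'
#' Stage order: per-site fits -> heritability filter -> climate
#' classification of retained sites -> per-(environment, year)
#' factor-analytic fits and BLUPs -> gain regressions per environment
#' (per se and relative to local checks) plus yearly yield distributions
#' -> physiological-trait trends, contribution decomposition and biplot
#' in the high-rainfall environment. Every intermediate table is kept in
#' the returned object (and written under `out_dir` when set) together
#' with a manifest describing the run.
#'
#' @param plots plot observations (a data.frame or a csv path).
#' @param climate site climate covariates (data.frame or csv path).
#' @param config a [run_config()].
#' @return list of class `met_run`: site_fits, retained, filter_report,
#'   env_assignment, fa_fits, gains, distributions, traits, manifest.
#' @export
run_pipeline <- function(plots, climate, config = run_config()) {
  t0 <- Sys.time()
  if (is.character(plots)) plots <- read_plot_table(plots)
  if (is.character(climate)) climate <- read_climate_table(climate)
  cfg <- config
  warnings_log <- character(0)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("metgain")),
                   seed = cfg$seed,
                   started = format(t0, "%Y-%m-%d %H:%M:%S"),
                   stages = list())

  ## stage 1: per-site fits + heritability filter
  stage_log(cfg, "stage site_fits")
  keys <- unique(plots[, c("year", "site_id")])
  fits <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- plots[plots$site_id == keys$site_id[i] &
                   plots$year == keys$year[i], ]
    withCallingHandlers(
      fit_site_model(sub, trait = cfg$trait),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  site_table <- site_fit_table(fits)
  flt <- filter_sites(fits, threshold = cfg$h2_threshold)
  manifest$stages$site_fits <- list(n_sites = nrow(keys),
                                    n_retained = length(flt$retained))
  if (length(flt$retained) == 0)
    stop("no sites retained at H2 threshold ", cfg$h2_threshold,
         "; pipeline stopped")
  kept_plots <- plots[plots$site_id %in% flt$retained, , drop = FALSE]

  ## stage 2: climate classification of retained sites
  stage_log(cfg, "stage classify")
  clim_kept <- climate[climate$site_id %in% flt$retained, , drop = FALSE]
  assign_ <- classify_sites(clim_kept, k = cfg$kmeans_k,
                            restarts = cfg$kmeans_restarts, seed = cfg$seed)
  assign_ <- label_clusters(assign_, clim_kept)
  env_labels <- assign_$assignments
  manifest$stages$classify <- list(
    n_high = sum(env_labels$label == "high_rainfall"),
    n_low = sum(env_labels$label == "low_rainfall"))

  ## stage 3: per-group FA fits and BLUPs for the yield trait
  stage_log(cfg, "stage fa_fits")
  fa <- fit_fa_groups(kept_plots, env_labels, trait = cfg$trait,
                      k_factors = cfg$k_factors)
  n_ok <- sum(vapply(fa, function(x) is.null(x$skipped), TRUE))
  manifest$stages$fa_fits <- list(n_groups = length(fa), n_fitted = n_ok)
  if (n_ok == 0) stop("no analysis group had >= 2 sites; pipeline stopped")

  ## stage 4: gains per environment
  stage_log(cfg, "stage gains")
  gains <- list()
  distributions <- list()
  hyl_by_env <- list()
  for (env in unique(env_labels$label)) {
    grp <- fa[vapply(fa, function(x)
      is.null(x$skipped) && x$fit$group$label == env, TRUE)]
    if (length(grp) == 0) next
    yearly <- do.call(rbind, lapply(grp, function(x) {
      sel <- select_top_lines(x$blups$genotype_means, n = cfg$top_n)
      data.frame(year = x$fit$group$year,
                 hyl_mean = mean(sel$means),
                 lc_mean = x$blups$lc_mean,
                 hyl = I(list(sel$genotypes)))
    }))
    hyl_by_env[[env]] <- unique(unlist(yearly$hyl))
    if (nrow(yearly) >= 2) {
      gyp <- estimate_gyp_gain(data.frame(year = yearly$year,
                                          value = yearly$hyl_mean),
                               percent_denominator = cfg$percent_denominator)
      gylc <- if (all(yearly$lc_mean > 0, na.rm = TRUE) &&
                  !anyNA(yearly$lc_mean))
        estimate_gylc_gain(yearly[, c("year", "hyl_mean", "lc_mean")])
      else NULL
      gains[[env]] <- list(gyp = gyp, gylc = gylc,
                           hyl_years = yearly[, c("year", "hyl_mean",
                                                  "lc_mean")])
    }
    allb <- do.call(rbind, lapply(grp, function(x) {
      gm <- x$blups$genotype_means
      data.frame(year = x$fit$group$year,
                 value = gm$across_site_mean[!gm$is_local_check])
    }))
    distributions[[env]] <- yearly_yield_distribution(allb)
  }
  if (length(hyl_by_env) == 2) {
    envs <- names(hyl_by_env)
    gains$hyl_overlap <- hyl_overlap(hyl_by_env[[1]], hyl_by_env[[2]])
  }
  manifest$stages$gains <- list(environments = names(gains))

  ## stage 5: physiological traits in the high-rainfall environment
  stage_log(cfg, "stage traits")
  traits_out <- NULL
  if ("high_rainfall" %in% env_labels$label &&
      length(cfg$physiological_traits)) {
    traits_out <- run_trait_stage(kept_plots, env_labels, fa, cfg)
  }
  manifest$stages$traits <- list(ran = !is.null(traits_out))
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  manifest$warnings <- unique(warnings_log)

  out <- list(site_fits = site_table, filter_report = flt$report,
              retained = flt$retained, env_assignment = env_labels,
              fa_fits = fa, gains = gains, distributions = distributions,
              traits = traits_out, manifest = manifest)
  class(out) <- "met_run"
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

## Trait stage: per-trait FA BLUPs in high-rainfall groups, yearly HYL
## trait means, trends, sequential R2 decomposition and biplot.
run_trait_stage <- function(kept_plots, env_labels, fa_yield, cfg) {
  high_groups <- fa_yield[vapply(fa_yield, function(x)
    is.null(x$skipped) && x$fit$group$label == "high_rainfall", TRUE)]
  if (length(high_groups) == 0) return(NULL)
  avail <- intersect(cfg$physiological_traits, names(kept_plots))
  trait_blups <- list()
  for (tr in avail) {
    per_year <- lapply(high_groups, function(x) {
      sub <- kept_plots[kept_plots$site_id %in% x$fit$site_ids &
                          kept_plots$year == x$fit$group$year, ]
      if (all(is.na(sub[[tr]]))) return(NULL)
      f <- reml_fit_fa(sub, trait = tr, k_factors = cfg$k_factors,
                       group = x$fit$group)
      b <- compute_blups(f)
      data.frame(year = x$fit$group$year,
                 genotype = b$genotype_means$genotype,
                 is_local_check = b$genotype_means$is_local_check,
                 value = b$genotype_means$across_site_mean)
    })
    trait_blups[[tr]] <- do.call(rbind, per_year)
  }
  ## HYL per year from the yield fits, then trait means of those lines
  hyl_per_year <- lapply(high_groups, function(x)
    list(year = x$fit$group$year,
         hyl = select_top_lines(x$blups$genotype_means,
                                n = cfg$top_n)$genotypes,
         gy = x$blups$genotype_means))
  rows <- lapply(hyl_per_year, function(h) {
    r <- data.frame(year = h$year,
                    gy_t_ha = mean(h$gy$across_site_mean[
                      h$gy$genotype %in% h$hyl]))
    for (tr in names(trait_blups)) {
      tb <- trait_blups[[tr]]
      v <- tb$value[tb$year == h$year & tb$genotype %in% h$hyl]
      r[[tr]] <- if (length(v)) mean(v) else NA_real_
    }
    r
  })
  hyl_traits <- do.call(rbind, rows)
  ## derived traits on the BLUP scale
  names(hyl_traits)[names(hyl_traits) == "dm"] <- "dm_days"
  names(hyl_traits)[names(hyl_traits) == "dh"] <- "dh_days"
  if (all(c("dm_days", "dh_days") %in% names(hyl_traits)))
    hyl_traits$dhm_days <- hyl_traits$dm_days - hyl_traits$dh_days
  if (all(c("gy_t_ha", "gw_mg") %in% names(hyl_traits)))
    hyl_traits$gn_per_m2 <- (hyl_traits$gy_t_ha * 100) /
      (hyl_traits$gw_mg / 1000)

  trait_cols <- setdiff(names(hyl_traits), c("year", "gy_t_ha"))
  trends <- lapply(trait_cols, function(tr) {
    ok <- !is.na(hyl_traits[[tr]])
    if (sum(ok) < 2) return(NULL)
    trait_trend(data.frame(year = hyl_traits$year[ok],
                           value = hyl_traits[[tr]][ok]), trait = tr)
  })
  trends <- do.call(rbind, lapply(Filter(Negate(is.null), trends),
                                  as.data.frame))

  contribution <- NULL
  bip <- NULL
  cc <- stats::complete.cases(hyl_traits[, c("gy_t_ha", trait_cols)])
  if (sum(cc) >= length(trait_cols) + 2) {
    contribution <- tryCatch(
      sequential_r2(hyl_traits$gy_t_ha[cc],
                    hyl_traits[cc, trait_cols, drop = FALSE]),
      error = function(e) NULL)
  }
  if (sum(cc) >= 3 && length(trait_cols) >= 1) {
    bip <- tryCatch(
      biplot_decomposition(hyl_traits[cc, c("gy_t_ha", trait_cols)]),
      error = function(e) NULL)
  }
  list(hyl_trait_means = hyl_traits, trends = trends,
       contribution = contribution, biplot = bip)
}

#' Persist a pipeline run as delimited text plus a manifest
#'
#' @param run a `met_run`.
#' @param out_dir directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table(df, p)
    paths <<- c(paths, p)
  }
  wr(run$site_fits, "site_fits.csv")
  wr(run$filter_report, "site_filter.csv")
  wr(run$env_assignment, "env_assignment.csv")
  gains_rows <- list()
  for (env in setdiff(names(run$gains), "hyl_overlap")) {
    g <- run$gains[[env]]
    gains_rows[[paste0(env, "_gyp")]] <- data.frame(
      environment = env, mode = "GYP", slope_t_ha_yr = g$gyp$slope,
      slope_kg_ha_yr = g$gyp$slope_kg_per_ha_yr,
      percent_rate = g$gyp$percent_rate,
      r_squared = g$gyp$r_squared, p_value = g$gyp$p_value,
      n_years = g$gyp$n_years)
    if (!is.null(g$gylc))
      gains_rows[[paste0(env, "_gylc")]] <- data.frame(
        environment = env, mode = "GYLC", slope_t_ha_yr = g$gylc$slope,
        slope_kg_ha_yr = g$gylc$slope_kg_per_ha_yr,
        percent_rate = g$gylc$percent_rate,
        r_squared = g$gylc$r_squared, p_value = g$gylc$p_value,
        n_years = g$gylc$n_years)
  }
  if (length(gains_rows)) wr(do.call(rbind, gains_rows), "gains.csv")
  if (!is.null(run$traits)) {
    wr(run$traits$hyl_trait_means, "hyl_trait_means.csv")
    if (!is.null(run$traits$trends)) wr(run$traits$trends, "trait_trends.csv")
    if (!is.null(run$traits$contribution))
      wr(run$traits$contribution$table, "trait_contribution.csv")
  }
  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(run$manifest, mp)
  paths <- c(paths, mp)
  invisible(paths)
}
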