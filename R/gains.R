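#' Select the highest-yielding lines of a nursery year
#'
#' Top `n` non-local-check genotypes by across-site predicted mean; ties
#' broken by genotype name (lexicographically smaller first), so the
#' selection is deterministic.
#'
#' @param genotype_means data.frame with columns genotype,
#'   is_local_check, across_site_mean (a `blup_table$genotype_means`, or
#'   equivalent).
#' @param n lines to select (default 5).
#' @return list of class `hyl_selection`: genotypes, means, n_requested,
#'   flagged (TRUE when fewer than `n` candidates existed).
#' @export
select_top_lines <- function(genotype_means, n = 5) {
  stopifnot(all(c("genotype", "is_local_check", "across_site_mean") %in%
                  names(genotype_means)))
  cand <- genotype_means[!genotype_means$is_local_check, , drop = FALSE]
  ord <- order(-cand$across_site_mean, cand$genotype)
  cand <- cand[ord, , drop = FALSE]
  flagged <- nrow(cand) < n
  if (flagged)
    warning("only ", nrow(cand), " candidate lines available; returning all")
  top <- utils::head(cand, n)
  out <- list(genotypes = top$genotype,
              means = stats::setNames(top$across_site_mean, top$genotype),
              n_requested = n, flagged = flagged)
  class(out) <- "hyl_selection"
  out
}

## OLS of value on centered year with the reporting conventions shared by
## the gain and trait-trend estimators.
ols_trend <- function(year, value) {
  if (length(year) < 2) stop("regression needs >= 2 years")
  yc <- year - mean(year)
  fit <- stats::lm(value ~ yc)
  ## an exactly linear series triggers a benign precision diagnostic
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- unname(stats::coef(fit)[2])
  p <- if (length(year) >= 3) sm$coefficients[2, 4] else NA_real_
  r2 <- if (sm$r.squared >= 0 && !is.nan(sm$r.squared)) sm$r.squared else 0
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       p_value = p, r_squared = r2, n_years = length(year))
}

#' Genetic gain per se from yearly top-line means
#'
#' Ordinary least squares of the yearly mean predicted yield of the
#' highest-yielding lines on the (centered) nursery year. The percentage
#' rate divides the slope by the mean of the yearly means over the
#' analyzed period.
#'
#' @param yearly data.frame with columns year and value (t ha-1), one row
#'   per year.
#' @param percent_denominator "hyl_mean" (default: mean of the yearly
#'   top-line means) or "grand_mean" via the `grand_mean` argument.
#' @param grand_mean optional all-line grand mean used when
#'   `percent_denominator = "grand_mean"`.
#' @return list of class `gain_estimate`: mode, slope (t ha-1 yr-1),
#'   slope_kg_per_ha_yr, percent_rate (% yr-1), intercept, r_squared,
#'   p_value, n_years, yearly_points.
#' @export
estimate_gyp_gain <- function(yearly,
                              percent_denominator = c("hyl_mean", "grand_mean"),
                              grand_mean = NULL) {
  percent_denominator <- match.arg(percent_denominator)
  stopifnot(all(c("year", "value") %in% names(yearly)))
  tr <- ols_trend(yearly$year, yearly$value)
  denom <- if (percent_denominator == "hyl_mean") mean(yearly$value)
           else grand_mean
  if (is.null(denom) || denom <= 0)
    stop("invalid denominator for the percentage rate")
  out <- list(mode = "GYP",
              slope = tr$slope,
              slope_kg_per_ha_yr = tr$slope * 1000,
              percent_rate = tr$slope / denom * 100,
              intercept = tr$intercept,
              r_squared = tr$r_squared,
              p_value = tr$p_value,
              n_years = tr$n_years,
              yearly_points = yearly)
  class(out) <- "gain_estimate"
  out
}

#' Yield of the top lines relative to the local checks, in percent
#'
#' 100 * (hyl_mean - lc_mean) / lc_mean. Scale-invariant: multiplying
#' both inputs by the same positive constant leaves the result unchanged.
#'
#' @param hyl_blup_mean mean predicted yield of the top lines (t ha-1).
#' @param lc_mean predicted local-check mean (t ha-1, > 0).
#' @return percent.
#' @export
compute_gylc <- function(hyl_blup_mean, lc_mean) {
  if (any(lc_mean <= 0)) stop("local-check mean must be positive")
  100 * (hyl_blup_mean - lc_mean) / lc_mean
}

#' Genetic gain relative to local checks
#'
#' Two regressions on the centered year: the percent series
#' 100 * (hyl - lc) / lc gives the rate in percentage points per year;
#' the absolute series (hyl - lc) gives the slope in kg ha-1 yr-1. Both
#' are first-class results computed from their own series.
#'
#' @param yearly data.frame with columns year, hyl_mean, lc_mean (t ha-1;
#'   lc_mean > 0 each year).
#' @return list of class `gain_estimate`: mode "GYLC", percent_rate
#'   (points yr-1) with its p-value and r-squared, slope (t ha-1 yr-1 of
#'   the absolute series), slope_kg_per_ha_yr, abs_p_value, n_years,
#'   yearly_points (with the gylc_percent column).
#' @export
estimate_gylc_gain <- function(yearly) {
  stopifnot(all(c("year", "hyl_mean", "lc_mean") %in% names(yearly)))
  yearly$gylc_percent <- compute_gylc(yearly$hyl_mean, yearly$lc_mean)
  tp <- ols_trend(yearly$year, yearly$gylc_percent)
  ta <- ols_trend(yearly$year, yearly$hyl_mean - yearly$lc_mean)
  out <- list(mode = "GYLC",
              percent_rate = tp$slope,
              p_value = tp$p_value,
              r_squared = tp$r_squared,
              slope = ta$slope,
              slope_kg_per_ha_yr = ta$slope * 1000,
              abs_p_value = ta$p_value,
              intercept = tp$intercept,
              n_years = tp$n_years,
              yearly_points = yearly)
  class(out) <- "gain_estimate"
  out
}

#' Per-year yield distribution of all lines
#'
#' Mean, sd, quantiles and a kernel-density curve (Silverman's rule by
#' default) of the predicted yields of every line, per nursery year.
#'
#' @param blups data.frame with columns year, value (one row per line and
#'   year; local checks normally excluded by the caller).
#' @param bw bandwidth rule passed to [stats::density()] (default "nrd0",
#'   Silverman).
#' @param n_grid density grid size.
#' @return data.frame of per-year summaries plus a `density` list-column
#'   substitute: attribute "densities", a named list of data.frames (x, y).
#' @export
yearly_yield_distribution <- function(blups, bw = "nrd0", n_grid = 256) {
  stopifnot(all(c("year", "value") %in% names(blups)))
  years <- sort(unique(blups$year))
  dens <- list()
  rows <- lapply(years, function(y) {
    v <- blups$value[blups$year == y]
    if (length(v) < 5)
      warning("year ", y, " has fewer than 5 lines; summaries may be unstable")
    degenerate <- stats::sd(v) == 0
    if (!degenerate) {
      d <- stats::density(v, bw = bw, n = n_grid)
      dens[[as.character(y)]] <<- data.frame(x = d$x, y = d$y)
    } else {
      dens[[as.character(y)]] <<- data.frame(x = v[1], y = Inf)
    }
    data.frame(year = y, n = length(v), mean = mean(v), sd = stats::sd(v),
               q05 = stats::quantile(v, 0.05, names = FALSE),
               q25 = stats::quantile(v, 0.25, names = FALSE),
               median = stats::median(v),
               q75 = stats::quantile(v, 0.75, names = FALSE),
               q95 = stats::quantile(v, 0.95, names = FALSE),
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "densities") <- dens
  out
}

#' Overlap of top lines between two environment groups
#'
#' Fraction of one environment's highest-yielding lines that also appear
#' among the other environment's highest-yielding lines (e.g. shared elite
#' germplasm between high- and low-rainfall groups).
#'
#' @param hyl_a,hyl_b character vectors of genotype names (or
#'   `hyl_selection` objects).
#' @return fraction in [0, 1]: |A intersect B| / |A|.
#' @export
hyl_overlap <- function(hyl_a, hyl_b) {
  ga <- if (inherits(hyl_a, "hyl_selection")) hyl_a$genotypes else hyl_a
  gb <- if (inherits(hyl_b, "hyl_selection")) hyl_b$genotypes else hyl_b
  if (length(ga) == 0) return(NA_real_)
  length(intersect(ga, gb)) / length(ga)
}
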