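#!/usr/bin/env Rscript

# Stage 5: genetic-gain regressions. Per environment: the across-site
# BLUP means of the five highest-yielding lines of each year are
# regressed on year (gain per se, GYP), and their gap to the predicted
# local-check mean gives the check-relative gain (GYLC) in both % per
# year and kg/ha/yr. Yearly all-line yield distributions summarize the
# whole nursery.

library(metgain)

blups <- utils::read.csv("results/blup_genotype_means.csv")

gains_rows <- list()
hyl_by_env <- list()
for (env in unique(blups$environment)) {
  b <- blups[blups$environment == env, ]
  yearly <- do.call(rbind, lapply(sort(unique(b$year)), function(y) {
    by_ <- b[b$year == y, ]
    sel <- select_top_lines(by_, n = 5)
    data.frame(year = y, hyl_mean = mean(sel$means),
               lc_mean = by_$lc_group_mean[1],
               hyl = I(list(sel$genotypes)))
  }))
  hyl_by_env[[env]] <- unique(unlist(yearly$hyl))
  gyp <- estimate_gyp_gain(data.frame(year = yearly$year,
                                      value = yearly$hyl_mean))
  gylc <- estimate_gylc_gain(yearly[, c("year", "hyl_mean", "lc_mean")])
  gains_rows[[env]] <- data.frame(
    environment = env,
    mode = c("GYP", "GYLC"),
    slope_kg_ha_yr = c(gyp$slope_kg_per_ha_yr, gylc$slope_kg_per_ha_yr),
    percent_rate = c(gyp$percent_rate, gylc$percent_rate),
    r_squared = c(gyp$r_squared, gylc$r_squared),
    p_value = c(gyp$p_value, gylc$p_value))
  message(sprintf(
    "%s: GYP %.0f kg/ha/yr (%.2f %%/yr, p = %.2g); GYLC %.1f kg/ha/yr (%.2f points/yr, p = %.2g)",
    env, gyp$slope_kg_per_ha_yr, gyp$percent_rate, gyp$p_value,
    gylc$slope_kg_per_ha_yr, gylc$percent_rate, gylc$p_value))

  dist <- yearly_yield_distribution(
    data.frame(year = b$year[!b$is_local_check],
               value = b$across_site_mean[!b$is_local_check]))
  write_table(dist, sprintf("results/yield_distribution_%s.csv", env))
}
write_table(do.call(rbind, gains_rows), "results/gains.csv")

if (length(hyl_by_env) == 2) {
  ov <- hyl_overlap(hyl_by_env[["high_rainfall"]], hyl_by_env[["low_rainfall"]])
  message(sprintf("%.0f%% of high-rainfall top lines also rank among the low-rainfall top lines.",
                  100 * ov))
}
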