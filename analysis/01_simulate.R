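#!/usr/bin/env Rscript

# Stage 1: generate the synthetic ten-year international nursery program
# used by every downstream stage. The configuration is the package
# default: 50 fresh elite entries per year plus one local check per
# site, 8 sites per year in two climate groups, alpha-lattice with 2
# replicates x 5 incomplete blocks, elite genetic trend 0.16 t/ha/yr,
# widening local-check gap 0.0651 t/ha/yr, rank-1 factor-analytic
# site-wise genetic covariance.

library(metgain)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260924L)
sim <- simulate_program(cfg)

write_table(sim$plots, file.path(out_dir, "plots.csv"))
write_table(sim$climate, file.path(out_dir, "climate.csv"))
write_table(sim$truth$genotypes, file.path(out_dir, "truth_genotypes.csv"))
yaml::write_yaml(list(
  true_gain_t_ha_yr = sim$truth$true_gain,
  true_lc_gap_trend_t_ha_yr = sim$truth$true_lc_gap_trend,
  trait_trends = as.list(sim$truth$trait_trends),
  variance_components = as.list(sim$truth$variance_components),
  fa_loadings = sim$truth$fa_loadings,
  fa_specific_vars = sim$truth$fa_specific_vars
), file.path(out_dir, "truth.yaml"))

message(sprintf("Simulated %d plots over %d years at %d sites/year (%d genotypes).",
                nrow(sim$plots), cfg$n_years, cfg$n_sites_per_year,
                length(unique(sim$plots$genotype_name))))
message("Wrote plots.csv, climate.csv and the generating truth under ", out_dir)
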