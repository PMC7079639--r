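#!/usr/bin/env Rscript

# Stage 3: assign retained sites to high- and low-rainfall environments
# by k-means (k = 2, 25 restarts) on standardized coolest-quarter
# precipitation, mean minimum temperature and altitude; the wetter
# cluster is labeled high_rainfall and each site is checked against the
# 150 mm rule.

library(metgain)

climate <- read_climate_table("results/data/climate.csv")
flt <- utils::read.csv("results/site_filter.csv")
retained <- flt$site_id[flt$retained]

cl <- climate[climate$site_id %in% retained, ]
assignment <- label_clusters(classify_sites(cl, k = 2, restarts = 25,
                                            seed = 20260924L), cl)
write_table(assignment$assignments, "results/env_assignment.csv")

a <- assignment$assignments
message(sprintf("Classified %d retained sites: %d high-rainfall, %d low-rainfall.",
                nrow(a), sum(a$label == "high_rainfall"),
                sum(a$label == "low_rainfall")))
if ("true_env" %in% names(cl)) {
  acc <- mean(a$label == cl$true_env[match(a$site_id, cl$site_id)])
  message(sprintf("Agreement with generating labels: %.1f%%.", 100 * acc))
}
message(sprintf("Cluster centres (precip mm): %s.",
                paste(round(sort(assignment$centers[, 1])), collapse = " / ")))
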