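test_that("top-line selection excludes checks, breaks ties by name and flags shortfalls", {
  gm <- data.frame(genotype = sprintf("L%02d", 1:10),
                   is_local_check = FALSE,
                   across_site_mean = seq(4.0, 4.9, by = 0.1))
  sel <- select_top_lines(gm, n = 5)
  expect_equal(sel$genotypes, sprintf("L%02d", 10:6))

  ## the top entry being a local check promotes the next line
  gm$is_local_check[10] <- TRUE
  sel2 <- select_top_lines(gm, n = 5)
  expect_false("L10" %in% sel2$genotypes)
  expect_equal(sel2$genotypes[1], "L09")

  ## ties at the cut are resolved lexicographically and deterministically
  gm3 <- data.frame(genotype = c("B", "A", "C", "D", "E", "F"),
                    is_local_check = FALSE,
                    across_site_mean = c(5, 5, 5, 5, 4.5, 4.5))
  s3a <- select_top_lines(gm3, n = 5)
  s3b <- select_top_lines(gm3, n = 5)
  expect_identical(s3a$genotypes, s3b$genotypes)
  expect_equal(s3a$genotypes[5], "E")  # E < F at the tied rank

  gm4 <- gm3[1:3, ]
  expect_warning(s4 <- select_top_lines(gm4, n = 5), "candidate")
  expect_true(s4$flagged)
  expect_length(s4$genotypes, 3)
})

test_that("gain per se recovers an exact linear series and its percentage rate", {
  yearly <- data.frame(year = 1:10, value = seq(4.0, 4.9, by = 0.1))
  g <- estimate_gyp_gain(yearly)
  expect_equal(g$slope, 0.1, tolerance = 1e-12)
  expect_equal(g$slope_kg_per_ha_yr, 100, tolerance = 1e-10)
  expect_equal(g$percent_rate, 0.1 / 4.45 * 100, tolerance = 1e-10)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)

  const <- data.frame(year = 1:6, value = rep(4.2, 6))
  g0 <- estimate_gyp_gain(const)
  expect_equal(g0$slope, 0)
  expect_equal(g0$percent_rate, 0)
  expect_equal(g0$r_squared, 0)

  expect_error(estimate_gyp_gain(data.frame(year = 1, value = 4)), "2 years")
})

test_that("percentage rate per se is invariant to a global unit change", {
  yearly <- data.frame(year = 1:8, value = 4 + 0.13 * (1:8) + c(0.02, -0.01, 0, 0.03, -0.02, 0.01, 0, -0.03))
  a <- estimate_gyp_gain(yearly)
  yearly_kg <- transform(yearly, value = value * 1000)
  b <- estimate_gyp_gain(yearly_kg)
  expect_equal(a$percent_rate, b$percent_rate, tolerance = 1e-10)
})

test_that("relative-to-check yield follows its formula and scale invariance", {
  expect_equal(compute_gylc(5, 4), 25)
  expect_equal(compute_gylc(4, 4), 0)
  expect_equal(compute_gylc(5, 4), compute_gylc(5 * 3.7, 4 * 3.7),
               tolerance = 1e-12)
  expect_error(compute_gylc(5, 0), "positive")
})

test_that("check-relative gain regression reports both slope conventions", {
  ## constant gap: both slopes zero
  yearly <- data.frame(year = 1:7, hyl_mean = 4.5 + 0.1 * (1:7),
                       lc_mean = 4.0 + 0.1 * (1:7))
  g <- estimate_gylc_gain(yearly)
  expect_lt(abs(g$slope_kg_per_ha_yr), 1e-9)

  ## a gap growing by exactly 0.0651 t/ha/yr gives 65.1 kg/ha/yr
  yearly2 <- data.frame(year = 1:10, lc_mean = rep(4, 10))
  yearly2$hyl_mean <- yearly2$lc_mean + 0.3 + 0.0651 * (1:10)
  g2 <- estimate_gylc_gain(yearly2)
  expect_equal(g2$slope_kg_per_ha_yr, 65.1, tolerance = 1e-9)
  expect_gt(g2$percent_rate, 0)
})

test_that("trend statistics agree with the closed-form OLS oracle", {
  set.seed(14)
  for (i in 1:5) {
    year <- 1:9
    value <- 4 + 0.1 * year + rnorm(9, 0, 0.2)
    g <- estimate_gyp_gain(data.frame(year = year, value = value))
    orc <- ols_oracle(year - mean(year), value)
    expect_equal(g$slope, orc$slope, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(g$p_value, orc$p_value, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(g$r_squared, orc$r_squared, tolerance = 1e-10)
  }
})

test_that("yearly yield distributions are normalized, equivariant and flag degeneracy", {
  set.seed(15)
  b <- data.frame(year = rep(1:3, each = 40),
                  value = rnorm(120, rep(c(4, 4.3, 4.6), each = 40), 0.4))
  d1 <- yearly_yield_distribution(b)
  dens <- attr(d1, "densities")
  for (dn in dens) {
    area <- sum(diff(dn$x) * (head(dn$y, -1) + tail(dn$y, -1)) / 2)
    expect_lt(abs(area - 1), 1e-3)
  }
  b2 <- transform(b, value = value + 1)
  d2 <- yearly_yield_distribution(b2)
  expect_equal(d2$mean, d1$mean + 1, tolerance = 1e-12)

  b3 <- data.frame(year = 1, value = rep(4, 8))
  d3 <- yearly_yield_distribution(b3)
  expect_true(d3$degenerate)
  expect_equal(d3$sd, 0)
})

test_that("top-line overlap between environments is a fraction in [0, 1]", {
  expect_equal(hyl_overlap(c("A", "B", "C", "D"), c("C", "D", "E")), 0.5)
  expect_equal(hyl_overlap(c("A"), c("B")), 0)
  expect_equal(hyl_overlap(c("A", "B"), c("A", "B")), 1)
})
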