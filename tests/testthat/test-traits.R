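test_that("derived traits follow their unit identities and missing-data contract", {
  d <- data.frame(dh = c(60, 65, NA), dm = c(100, 60, 110),
                  gy_g_m2 = c(450, 500, 300), gw_mg = c(45, -1, 30))
  out <- derive_traits(d)
  expect_equal(out$dhm_days[1], 40)
  expect_true(out$dhm_invalid[2])        # dm <= dh
  expect_true(is.na(out$dhm_days[2]))
  expect_true(is.na(out$dhm_days[3]))    # missing component
  expect_equal(out$gn_per_m2[1], 10000)  # 450 g m-2 at 45 mg per grain
  expect_true(out$gn_invalid[2])         # non-positive grain weight
  expect_equal(out$gy_t_ha[1], 4.5)
  ## row 3 keeps its derivable traits despite missing dh
  expect_equal(out$gn_per_m2[3], 10000)
})

test_that("trait trends recover constructed slopes and degenerate inputs", {
  gw <- data.frame(year = 1:7, value = 30 + 1.08 * (1:7))
  tr <- trait_trend(gw, "gw_mg")
  expect_equal(tr$slope, 1.08, tolerance = 1e-12)
  expect_lt(tr$p_value, 1e-10)

  ph <- data.frame(year = 1:6, value = rep(88, 6))
  tr2 <- trait_trend(ph, "ph_cm")
  expect_equal(tr2$slope, 0)

  two <- data.frame(year = 1:2, value = c(1, 2))
  tr3 <- trait_trend(two, "x")
  expect_true(tr3$flagged)
  expect_true(is.na(tr3$p_value))
})

test_that("sequential partial R2 telescopes and matches a prefix-refit oracle", {
  set.seed(31)
  for (i in 1:6) {
    n <- 40
    X <- as.data.frame(matrix(rnorm(n * 4), n,
                              dimnames = list(NULL, c("a", "b", "c", "d"))))
    y <- 1 + X$a + 0.5 * X$b - 0.3 * X$c + rnorm(n, 0, 0.5)
    ord <- sample(names(X))
    sr <- sequential_r2(y, X, order = ord)
    ## telescoping identity
    expect_equal(sum(sr$table$partial_r2), sr$total_r2, tolerance = 1e-10)
    expect_equal(sum(sr$table$contribution_pct), 100, tolerance = 1e-8)
    ## brute-force prefix-refit oracle
    for (t in seq_along(ord)) {
      r2t <- summary(lm(y ~ ., data = X[, ord[1:t], drop = FALSE]))$r.squared
      r2p <- if (t == 1) 0 else
        summary(lm(y ~ ., data = X[, ord[1:(t - 1)], drop = FALSE]))$r.squared
      expect_equal(sr$table$partial_r2[t], r2t - r2p, tolerance = 1e-10)
    }
  }
})

test_that("a single predictor takes the full R2 and orthogonal predictors are order-free", {
  set.seed(32)
  x <- rnorm(30)
  y <- 2 + x + rnorm(30, 0, 0.3)
  sr <- sequential_r2(y, data.frame(x = x), order = "x")
  expect_equal(sr$table$partial_r2[1], sr$total_r2, tolerance = 1e-12)
  expect_equal(sr$table$contribution_pct[1], 100, tolerance = 1e-8)

  ## exactly orthogonal, mean-zero columns (orthogonal to the intercept
  ## too): partial R2 equals marginal R2, any order
  n <- 32
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  X <- as.data.frame(Q)
  names(X) <- c("p", "q", "r")
  y2 <- Q %*% c(1, 0.5, -0.2) + rnorm(n, 0, 0.2)
  marg <- sapply(names(X), function(v)
    summary(lm(y2 ~ X[[v]]))$r.squared)
  for (ord in list(c("p", "q", "r"), c("r", "p", "q"))) {
    sr2 <- sequential_r2(as.numeric(y2), X, order = ord)
    expect_equal(sr2$table$partial_r2,
                 unname(marg[sr2$table$trait]), tolerance = 1e-10)
  }
})

test_that("forward selection is invariant to column order and finds the dominant trait", {
  set.seed(33)
  n <- 60
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  y <- 3 * a + 1 * b + 0.2 * c_ + rnorm(n, 0, 0.5)
  X1 <- data.frame(a = a, b = b, c = c_)
  X2 <- X1[, c("c", "a", "b")]
  s1 <- sequential_r2(y, X1, order = "auto")
  s2 <- sequential_r2(y, X2, order = "auto")
  expect_equal(s1$order, s2$order)
  expect_equal(s1$order[1], "a")
})

test_that("exact collinearity is detected and pivoted with a warning", {
  set.seed(34)
  n <- 30
  dh <- rnorm(n, 65, 3)
  dm <- rnorm(n, 110, 4)
  dhm <- dm - dh
  y <- 0.05 * dm + 0.04 * dhm + rnorm(n, 0, 0.3)
  expect_warning(
    sr <- sequential_r2(y, data.frame(dh = dh, dm = dm, dhm = dhm),
                        order = c("dm", "dhm", "dh")),
    "collinear")
  expect_equal(sum(sr$table$partial_r2), sr$total_r2, tolerance = 1e-10)
})

test_that("biplot decomposition satisfies its SVD identities", {
  set.seed(35)
  ## rank-2 data: first two dimensions explain everything
  n <- 20
  u <- rnorm(n); v <- rnorm(n)
  M <- cbind(t1 = u, t2 = v, t3 = u + v, t4 = u - 2 * v)
  bp <- biplot_decomposition(M)
  expect_equal(bp$cumulative[2], 1, tolerance = 1e-10)
  expect_equal(sum(bp$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(bp$variance_explained) <= 1e-12))

  ## duplicated trait columns coincide after standardization
  M2 <- cbind(x = u, y = v, x2 = 2 * u + 5)
  bp2 <- biplot_decomposition(M2)
  expect_equal(bp2$loadings["x", ], bp2$loadings["x2", ], tolerance = 1e-8)

  ## rank-2 reconstruction reproduces pairwise correlations
  set.seed(36)
  z1 <- rnorm(100); z2 <- rnorm(100)
  M3 <- cbind(a = z1, b = 0.8 * z1 + 0.6 * z2, c = z2,
              d = 0.5 * z1 - 0.5 * z2 + 0.1 * rnorm(100))
  bp3 <- biplot_decomposition(M3)
  rec <- tcrossprod(bp3$loadings)  # V2 D2 V2' ~ Z'Z up to rank-2 truncation
  emp <- cor(M3) * (nrow(M3) - 1)
  expect_gt(cor(rec[upper.tri(rec)], emp[upper.tri(emp)]), 0.95)
})
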