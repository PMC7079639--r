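#' Derive secondary physiological traits
#'
#' Grain-filling duration dhm_days = dm - dh; grain number per square
#' meter gn_per_m2 = yield in g m-2 divided by single-grain weight in
#' grams (gw_mg / 1000); gy_t_ha = gy_g_m2 * 0.01. Rows with missing or
#' invalid components keep the derivable traits and flag the rest.
#'
#' @param records data.frame with (any of) dh, dm, gy_g_m2, gw_mg columns.
#' @return the data.frame with dhm_days, gn_per_m2, gy_t_ha added and
#'   logical flag columns dhm_invalid (dm <= dh), gn_invalid (gw <= 0).
#' @export
derive_traits <- function(records) {
  d <- records
  if (all(c("dh", "dm") %in% names(d))) {
    d$dhm_days <- d$dm - d$dh
    d$dhm_invalid <- !is.na(d$dhm_days) & d$dhm_days <= 0
    d$dhm_days[d$dhm_invalid] <- NA_real_
  }
  if (all(c("gy_g_m2", "gw_mg") %in% names(d))) {
    d$gn_invalid <- !is.na(d$gw_mg) & d$gw_mg <= 0
    d$gn_per_m2 <- ifelse(d$gn_invalid, NA_real_,
                          d$gy_g_m2 / (d$gw_mg / 1000))
  }
  if ("gy_g_m2" %in% names(d) && !"gy_t_ha" %in% names(d))
    d$gy_t_ha <- d$gy_g_m2 * 0.01
  d
}

#' Annual trend of a physiological trait
#'
#' OLS of the yearly top-line trait mean on the centered nursery year;
#' slope in trait units per year. With only two years the slope is
#' returned without a p-value and flagged.
#'
#' @param yearly data.frame with columns year and value.
#' @param trait trait name carried through to the output.
#' @return list: trait, slope, p_value, r_squared, n_years, flagged.
#' @export
trait_trend <- function(yearly, trait = "trait") {
  stopifnot(all(c("year", "value") %in% names(yearly)))
  tr <- ols_trend(yearly$year, yearly$value)
  list(trait = trait, slope = tr$slope, p_value = tr$p_value,
       r_squared = tr$r_squared, n_years = tr$n_years,
       flagged = tr$n_years < 3)
}

## R^2 of the regression of y on the given predictor columns (empty set
## gives 0); NA rows removed pairwise upstream.
prefix_r2 <- function(y, X, cols) {
  if (length(cols) == 0) return(0)
  fit <- stats::lm(y ~ ., data = as.data.frame(X[, cols, drop = FALSE]))
  summary(fit)$r.squared
}

#' Sequential partial R-squared decomposition of trait contributions
#'
#' Multiple linear regression of yield on the trait matrix; the partial
#' R-squared of the t-th trait in the order is R^2 of the first t traits
#' minus R^2 of the first t-1 (equivalently its sequential sum of squares
#' over the total). `order = "auto"` uses greedy forward selection by
#' incremental R-squared, ties broken by trait name. Contributions are
#' normalized by the total R-squared.
#'
#' @param response numeric yield vector.
#' @param predictors data.frame or matrix of traits.
#' @param order character vector of trait names, or "auto".
#' @return list of class `trait_contribution`: table (trait,
#'   cumulative_r2, partial_r2, contribution_pct, p_value of the
#'   sequential F test), total_r2, coefficients (full model), order,
#'   collinear (traits adding no rank, if any).
#' @export
sequential_r2 <- function(response, predictors, order = "auto") {
  X <- as.data.frame(predictors)
  stopifnot(ncol(X) >= 1, length(response) == nrow(X))
  keep <- stats::complete.cases(X) & !is.na(response)
  X <- X[keep, , drop = FALSE]
  y <- response[keep]
  if (length(y) < ncol(X) + 2)
    stop("need at least 2 more observations than predictors")
  csd <- vapply(X, stats::sd, 0)
  if (any(csd == 0))
    stop("constant predictor(s): ", paste(names(X)[csd == 0], collapse = ", "))

  nm <- sort(names(X))
  if (identical(order, "auto")) {
    chosen <- character(0)
    remaining <- nm
    while (length(remaining)) {
      base_r2 <- prefix_r2(y, X, chosen)
      inc <- vapply(remaining, function(v)
        prefix_r2(y, X, c(chosen, v)) - base_r2, 0)
      best <- remaining[order(-inc, remaining)][1]
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
    }
    order <- chosen
  } else {
    stopifnot(all(order %in% names(X)), length(order) == ncol(X))
  }

  full <- stats::lm(y ~ ., data = X[, order, drop = FALSE])
  total_r2 <- summary(full)$r.squared
  collinear <- names(stats::coef(full))[is.na(stats::coef(full))]
  if (length(collinear))
    warning("collinear predictor(s) pivoted out: ",
            paste(collinear, collapse = ", "),
            "; their partial R2 is computed on the residual space")

  ## sequential (type-I) decomposition: partial R2 telescopes to total R2;
  ## rows are matched by term name so aliased (collinear) predictors,
  ## which lm pivots out, contribute zero
  an <- stats::anova(full)
  ss <- an[["Sum Sq"]]
  terms_ <- rownames(an)
  tss <- sum(ss)
  ridx <- match(make.names(order), make.names(terms_))
  partial <- stats::setNames(
    ifelse(is.na(ridx), 0, ss[ridx] / tss), order)
  pvals <- stats::setNames(
    ifelse(is.na(ridx), NA_real_, an[["Pr(>F)"]][ridx]), order)
  cumulative <- cumsum(partial)
  tab <- data.frame(trait = order,
                    cumulative_r2 = unname(cumulative),
                    partial_r2 = unname(partial),
                    contribution_pct = unname(100 * partial / total_r2),
                    p_value = unname(pvals),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, total_r2 = total_r2,
              coefficients = stats::coef(full),
              order = order, collinear = collinear,
              n = length(y))
  class(out) <- "trait_contribution"
  out
}

#' Biplot decomposition of an observations-by-traits matrix
#'
#' Correlation biplot: columns are centered and scaled to unit variance
#' (traits have incommensurate units), then a singular-value
#' decomposition gives observation scores and trait loadings with the
#' singular values split evenly between the two. Variance explained per
#' dimension is the squared singular value over their total.
#'
#' @param trait_matrix numeric matrix or data.frame, >= 3 observations
#'   and >= 2 traits.
#' @return list of class `biplot_result`: scores (obs x 2), loadings
#'   (trait x 2), variance_explained (all dimensions), cumulative,
#'   flagged (rank < 2).
#' @export
biplot_decomposition <- function(trait_matrix) {
  M <- as.matrix(trait_matrix)
  stopifnot(nrow(M) >= 3, ncol(M) >= 2)
  Z <- scale(M)
  if (any(!is.finite(Z))) {
    keep <- apply(Z, 2, function(z) all(is.finite(z)))
    warning("dropping constant trait column(s): ",
            paste(colnames(M)[!keep], collapse = ", "))
    Z <- Z[, keep, drop = FALSE]
  }
  sv <- svd(Z)
  d2 <- sv$d^2
  ve <- d2 / sum(d2)
  rank_ <- sum(sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1])
  flagged <- rank_ < 2
  k <- min(2, ncol(Z))
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sqrt(sv$d[1:k]), k)
  loadings <- sv$v[, 1:k, drop = FALSE] %*% diag(sqrt(sv$d[1:k]), k)
  rownames(loadings) <- colnames(Z)
  out <- list(scores = scores, loadings = loadings,
              variance_explained = ve,
              cumulative = cumsum(ve),
              singular_values = sv$d,
              flagged = flagged)
  class(out) <- "biplot_result"
  out
}
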