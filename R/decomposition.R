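#' Weighted linear probability model with cluster-robust errors
#'
#' Ordinary weighted least squares of a binary outcome on a covariate
#' design, the regression underlying the exact linear decomposition of the
#' concentration index. Categorical covariates enter as single ordinal
#' scores by default (one regressor per covariate, matching the one-row-
#' per-covariate decomposition layout, reference = lowest-coded level);
#' `expand_factors = TRUE` gives a full dummy expansion instead.
#'
#' @param y binary (0/1) outcome vector.
#' @param X data frame of covariates.
#' @param w optional nonnegative weights.
#' @param psu optional cluster ids for the sandwich variance.
#' @param expand_factors expand non-numeric covariates into dummies.
#' @return list with `coefficients`, `se` (cluster-robust), `fit` (the
#'   `lm` object) and `X` (the numeric design actually used).
#' @export
fit_lpm <- function(y, X, w = NULL, psu = NULL, expand_factors = FALSE) {
  X <- encode_covariates(X, expand_factors)
  n <- length(y)
  if (nrow(X) != n) stop("y and X sizes differ", call. = FALSE)
  w <- check_weights(w, n)
  design <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrX <- qr(sqrt(w) * design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat, weights = w)
  V <- if (is.null(psu)) sandwich::vcovHC(fit, type = "HC1") else
    sandwich::vcovCL(fit, cluster = psu)
  list(coefficients = stats::coef(fit), se = sqrt(diag(V)), fit = fit, X = X)
}

encode_covariates <- function(X, expand_factors = FALSE) {
  X <- as.data.frame(X)
  if (expand_factors) {
    mm <- stats::model.matrix(~ ., data = X)[, -1, drop = FALSE]
    return(as.data.frame(mm, check.names = FALSE))
  }
  enc <- lapply(X, function(x) {
    if (is.numeric(x)) x
    else if (is.logical(x)) as.numeric(x)
    else as.numeric(as.integer(factor(x)))   # ordinal code, lowest = reference
  })
  as.data.frame(enc, check.names = FALSE)
}

#' Concentration index of a covariate against wealth rank
#'
#' The unbounded-variable variant used inside the decomposition: 2
#' cov_w(x, r) / mean_w(x), with no Erreygers scaling. Undefined (NA, with
#' a warning) when the covariate's weighted mean is zero.
#'
#' @param x numeric covariate.
#' @param r fractional ranks.
#' @param w optional weights.
#' @return scalar concentration index, or `NA` when undefined.
#' @export
covariate_ci <- function(x, r, w = NULL) {
  w <- check_weights(w, length(x))
  xbar <- weighted_mean(x, w)
  if (xbar == 0) {
    warning("zero-mean covariate: concentration index undefined")
    return(NA_real_)
  }
  2 * weighted_cov(x, r, w) / xbar
}

#' Decompose an Erreygers concentration index into covariate contributions
#'
#' Wagstaff-style regression decomposition: fit the weighted linear
#' probability model y = a + sum_k beta_k x_k + e, then write
#' ENCI = sum_k 4 beta_k xbar_k CI_k + residual, where CI_k is the
#' covariate's concentration index against the same ranks and the residual
#' is four times the generalized concentration index of e. With the same
#' weights and ranks throughout, the identity ENCI = sum(contributions) +
#' residual is algebraic and holds to machine precision. Elasticity is
#' beta_k * xbar_k (the mean-of-outcome division is absorbed by the
#' Erreygers factor 4 mu).
#'
#' @param y binary outcome.
#' @param X data frame of covariates (encoded as in [fit_lpm()]).
#' @param r fractional ranks from [fractional_rank()].
#' @param w optional weights.
#' @param psu optional cluster ids.
#' @param bounds outcome bounds, default `c(0, 1)`.
#' @param expand_factors passed to [fit_lpm()].
#' @return an `enci_decomposition`: a data frame with one row per
#'   covariate (`beta`, `se_beta`, `xbar`, `elasticity`, `ci_k`,
#'   `contribution`, `pct`), with attributes `enci` (an `index_estimate`),
#'   `residual` and `residual_pct`. Percent contributions are `NA`d with a
#'   warning when the total index is numerically zero.
#' @export
decompose_enci <- function(y, X, r, w = NULL, psu = NULL, bounds = c(0, 1),
                           expand_factors = FALSE) {
  n <- length(y)
  w <- check_weights(w, n)
  lpm <- fit_lpm(y, X, w, psu, expand_factors)
  Xn <- lpm$X
  enci <- erreygers_index(y, r, w, psu, bounds = bounds)
  factor4 <- 4 / (bounds[2] - bounds[1])

  nms <- names(Xn)
  beta <- lpm$coefficients[nms]
  xbar <- vapply(Xn, weighted_mean, numeric(1), w = w)
  covs <- vapply(Xn, weighted_cov, numeric(1), y = r, w = w)
  ci_k <- ifelse(xbar != 0, 2 * covs / xbar, NA_real_)
  if (anyNA(ci_k)) {
    warning("zero-mean covariate(s): ", paste(nms[is.na(ci_k)], collapse = ", "),
            "; covariate CI undefined, contribution computed directly")
  }
  elasticity <- beta * xbar
  # contribution = factor4 * elasticity * ci_k, written via the covariance so
  # zero-mean covariates keep the adding-up identity exact
  contribution <- 2 * factor4 * beta * covs
  residual <- enci$value - sum(contribution)

  if (abs(enci$value) > 1e-12) {
    pct <- 100 * contribution / enci$value
    residual_pct <- 100 * residual / enci$value
  } else {
    warning("total ENCI is numerically zero: percent contributions undefined")
    pct <- rep(NA_real_, length(contribution))
    residual_pct <- NA_real_
  }

  tab <- data.frame(covariate = nms, beta = as.numeric(beta),
                    se_beta = as.numeric(lpm$se[nms]),
                    xbar = as.numeric(xbar),
                    elasticity = as.numeric(elasticity),
                    ci_k = as.numeric(ci_k),
                    contribution = as.numeric(contribution),
                    pct = as.numeric(pct), row.names = NULL)
  structure(tab, class = c("enci_decomposition", "data.frame"),
            enci = enci, residual = residual, residual_pct = residual_pct,
            sign_convention = "positive = concentrated among the rich (pro-rich)")
}

#' Erreygers contribution from a printed elasticity and covariate CI
#'
#' The cell-level identity of the decomposition table: absolute
#' contribution = 4 x elasticity x covariate concentration index. Useful
#' for auditing published decomposition tables.
#'
#' @param elasticity beta_k * xbar_k.
#' @param ci covariate concentration index CI_k.
#' @return 4 * elasticity * ci, vectorized.
#' @export
enci_contribution <- function(elasticity, ci) 4 * elasticity * ci

#' Adding-up identity check of a decomposition
#'
#' @param decomp an `enci_decomposition`.
#' @return absolute gap | ENCI - sum(contributions) - residual |.
#' @export
decomposition_gap <- function(decomp) {
  abs(attr(decomp, "enci")$value - sum(decomp$contribution) -
        attr(decomp, "residual"))
}

#' @export
print.enci_decomposition <- function(x, digits = 4, ...) {
  enci <- attr(x, "enci")
  cat(sprintf("Decomposition of %s = %.*f (SE %.*f)\n", enci$estimator,
              digits, enci$value, digits, enci$std_error))
  cat(attr(x, "sign_convention"), "\n\n")
  tab <- data.frame(Covariate = x$covariate,
                    Elasticity = round(x$elasticity, digits),
                    `Concentration Index` = round(x$ci_k, digits),
                    Contribution = round(x$contribution, digits),
                    `Contribution (%)` = round(x$pct, 2),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("\nResiduals: %.2f%%\n", attr(x, "residual_pct")))
  invisible(x)
}
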