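#' Concentration index of a health variable against wealth rank
#'
#' CI = 2 cov_w(h, r) / mu, with cov_w the population-form weighted
#' covariance, r the weighted fractional rank and mu the weighted mean of
#' h — twice the area between the concentration curve and the line of
#' equality. The equivalent "convenient regression" route (weighted least
#' squares of a transformed outcome on the rank) is available via `method`
#' and is always used for the standard error, with a cluster-robust
#' sandwich variance grouped by PSU when cluster ids are supplied.
#'
#' @param h numeric health variable.
#' @param r fractional ranks from [fractional_rank()].
#' @param w optional nonnegative weights.
#' @param psu optional cluster (primary sampling unit) identifiers for the
#'   robust variance; with `psu = NULL` a heteroskedasticity-robust (HC1)
#'   variance is used.
#' @param method `"covariance"` (direct formula, default) or
#'   `"regression"` (convenient-regression slope); both agree to numerical
#'   precision.
#' @return an object of class `index_estimate` with fields `value`,
#'   `std_error`, `ci95`, `estimator`, `mu`, `n`, `cluster_count`.
#' @export
concentration_index <- function(h, r, w = NULL, psu = NULL,
                                method = c("covariance", "regression")) {
  method <- match.arg(method)
  est_index(h, r, w, psu, method, estimator = "CI", bounds = NULL)
}

#' Erreygers-normalized concentration index
#'
#' For a health variable bounded on \[a, b\], ENCI = 4 mu / (b - a) * CI;
#' for a binary variable this is 4 mu CI, spans \[-1, 1\], and obeys the
#' mirror property ENCI(1 - h) = -ENCI(h). Positive values indicate
#' concentration among the rich (pro-rich), negative among the poor.
#'
#' @inheritParams concentration_index
#' @param bounds `c(a, b)` range of the health variable, default `c(0, 1)`.
#' @return an `index_estimate` with `estimator = "ENCI"`.
#' @export
erreygers_index <- function(h, r, w = NULL, psu = NULL, bounds = c(0, 1),
                            method = c("covariance", "regression")) {
  method <- match.arg(method)
  if (length(bounds) != 2 || !(bounds[2] > bounds[1])) {
    stop("bounds must be c(a, b) with b > a", call. = FALSE)
  }
  if (any(h < bounds[1] | h > bounds[2], na.rm = TRUE)) {
    stop("health variable outside its stated bounds", call. = FALSE)
  }
  est_index(h, r, w, psu, method, estimator = "ENCI", bounds = bounds)
}

# shared estimator: point value by either route + convenient-regression SE
est_index <- function(h, r, w, psu, method, estimator, bounds) {
  n <- length(h)
  if (length(r) != n) stop("h and r lengths differ", call. = FALSE)
  if (anyNA(h) || anyNA(r)) stop("h and r must be non-missing", call. = FALSE)
  if (n < 2) stop("need at least 2 records", call. = FALSE)
  w <- check_weights(w, n)
  mu <- weighted_mean(h, w)
  if (mu == 0) stop("mean outcome is zero: index undefined", call. = FALSE)
  scale <- if (estimator == "ENCI") 4 * mu / (bounds[2] - bounds[1]) else 1
  vr <- weighted_var(r, w)

  value <- if (method == "regression" && vr > 0) {
    b <- weighted_cov(h, r, w) / vr           # WLS slope of h on r
    scale * 2 * vr * b / mu
  } else {
    scale * 2 * weighted_cov(h, r, w) / mu
  }

  cluster_count <- if (!is.null(psu)) length(unique(psu)) else NA_integer_
  if (!is.null(psu) && cluster_count < 2) {
    stop("only one PSU: pass psu = NULL for the unclustered robust variance",
         call. = FALSE)
  }
  se <- index_se(h, r, w, psu, mu, vr, scale)
  new_index_estimate(value, se, estimator, mu, bounds, n, cluster_count)
}

# convenient-regression SE: regress (scale * 2 var_w(r) / mu) * h on r; the
# slope is the index, and the sandwich variance of the slope is its SE.
index_se <- function(h, r, w, psu, mu, vr, scale) {
  if (vr == 0 || weighted_var(h, w) == 0) return(0)   # no sampling variation
  ytrans <- scale * 2 * vr * h / mu
  fit <- stats::lm(ytrans ~ r, weights = w)
  V <- if (is.null(psu)) sandwich::vcovHC(fit, type = "HC1") else
    sandwich::vcovCL(fit, cluster = psu)
  sqrt(V["r", "r"])
}

new_index_estimate <- function(value, se, estimator, mu, bounds, n,
                               cluster_count) {
  structure(list(value = value, std_error = se,
                 ci95 = c(value - 1.96 * se, value + 1.96 * se),
                 estimator = estimator, mu = mu, bounds = bounds,
                 n = n, cluster_count = cluster_count),
            class = "index_estimate")
}

#' @export
print.index_estimate <- function(x, digits = 4, ...) {
  p <- if (x$std_error > 0) {
    2 * stats::pnorm(-abs(x$value / x$std_error))
  } else if (x$value == 0) 1 else 0
  cat(sprintf("%s = %.*f (SE %.*f) %s  [95%% CI %.*f, %.*f]\n",
              x$estimator, digits, x$value, digits, x$std_error,
              signif_stars(p), digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("n = %d%s, mean outcome = %.*f\n", x$n,
              if (!is.na(x$cluster_count))
                sprintf(", SE adjusted for %d PSU clusters", x$cluster_count)
              else "", digits, x$mu))
  invisible(x)
}
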