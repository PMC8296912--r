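# Internal weighted-moment helpers. All use the population form (divide by
# total weight), which is the convention the index formulas assume.

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# population-form weighted covariance: sum w (x - xbar)(y - ybar) / sum w
weighted_cov <- function(x, y, w) {
  W <- sum(w)
  mx <- sum(w * x) / W
  my <- sum(w * y) / W
  sum(w * (x - mx) * (y - my)) / W
}

weighted_var <- function(x, w) weighted_cov(x, x, w)

check_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("weights must have length ", n, call. = FALSE)
  if (anyNA(w) || any(w < 0)) {
    stop("weights must be nonnegative and non-missing", call. = FALSE)
  }
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  w
}

signif_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("p", "L", "outcome"))
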