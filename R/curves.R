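#' Concentration-curve ordinates with standard errors
#'
#' L(p): the cumulative weighted share of the health variable held by the
#' poorest fraction p of children, evaluated on a quantile grid (default 19
#' interior points 0.05..0.95). A record is inside the poorest p when its
#' cumulative weight share (sorted by rank) does not exceed p. Ordinate
#' standard errors use the influence-function asymptotic variance of a
#' cumulative share, including the quantile-estimation term (the
#' conditional mean outcome at the cutoff is estimated by a rank-window
#' mean); a cluster bootstrap over PSUs is available instead.
#'
#' @param h numeric health variable (mean must be positive).
#' @param r fractional ranks from [fractional_rank()].
#' @param w optional nonnegative weights.
#' @param grid quantile points in (0, 1).
#' @param se_method `"asymptotic"` (default) or `"cluster_bootstrap"`.
#' @param psu cluster ids, required for the bootstrap.
#' @param boot_reps bootstrap replicates.
#' @param bandwidth half-width of the rank window used to estimate the
#'   conditional mean at each cutoff.
#' @return object of class `concentration_curve`: data frame with columns
#'   `p`, `L`, `se`; endpoints L(0)=0 and L(1)=1 are implicit.
#' @export
curve_ordinates <- function(h, r, w = NULL, grid = seq(0.05, 0.95, by = 0.05),
                            se_method = c("asymptotic", "cluster_bootstrap"),
                            psu = NULL, boot_reps = 500, bandwidth = 0.05) {
  se_method <- match.arg(se_method)
  n <- length(h)
  w <- check_weights(w, n)
  if (anyNA(h) || anyNA(r)) stop("h and r must be non-missing", call. = FALSE)
  if (any(grid <= 0 | grid >= 1)) stop("grid points must lie in (0,1)", call. = FALSE)
  mu <- weighted_mean(h, w)
  if (mu <= 0) stop("mean outcome must be positive for curve ordinates",
                    call. = FALSE)
  L <- curve_L(h, r, w, grid)
  se <- if (se_method == "asymptotic") {
    curve_se_if(h, r, w, grid, L, mu, bandwidth)
  } else {
    if (is.null(psu)) stop("cluster bootstrap requires psu ids", call. = FALSE)
    curve_se_boot(h, r, w, psu, grid, boot_reps)
  }
  structure(data.frame(p = grid, L = L, se = se),
            class = c("concentration_curve", "data.frame"),
            mu = mu, n = n, se_method = se_method)
}

# point estimates: cumulative weighted outcome share among the poorest p
curve_L <- function(h, r, w, grid) {
  ord <- order(r)
  F_i <- cumsum(w[ord]) / sum(w)
  cum_h <- cumsum((w * h)[ord]) / sum(w * h)
  vapply(grid, function(p) {
    k <- sum(F_i <= p + 1e-12)
    if (k == 0) 0 else cum_h[k]
  }, numeric(1))
}

# influence-function variance of L(p) = gamma_p / mu with estimated cutoff:
# IF_i = [ (h_i d_i - gamma) + m_p (p - d_i) - L (h_i - mu) ] / mu
curve_se_if <- function(h, r, w, grid, L, mu, bandwidth) {
  W <- sum(w)
  wt <- w / W
  ord <- order(r)
  F_all <- numeric(length(h))
  F_all[ord] <- cumsum(w[ord]) / W
  vapply(seq_along(grid), function(j) {
    p <- grid[j]
    d <- as.numeric(F_all <= p + 1e-12)
    gam <- sum(wt * h * d)
    bw <- bandwidth
    win <- abs(r - p) <= bw
    while (!any(win) && bw < 1) { bw <- bw * 2; win <- abs(r - p) <= bw }
    m_p <- weighted_mean(h[win], w[win])
    IF <- ((h * d - gam) + m_p * (p - d) - L[j] * (h - mu)) / mu
    sqrt(sum(wt^2 * IF^2))
  }, numeric(1))
}

curve_se_boot <- function(h, r, w, psu, grid, reps) {
  ids <- unique(psu)
  idx <- split(seq_along(psu), psu)
  sims <- vapply(seq_len(reps), function(b) {
    take <- unlist(idx[sample(as.character(ids), length(ids), replace = TRUE)],
                   use.names = FALSE)
    hb <- h[take]; wb <- w[take]
    rb <- fractional_rank(r[take], wb)   # re-rank within the resample
    curve_L(hb, rb, wb, grid)
  }, numeric(length(grid)))
  apply(sims, 1, stats::sd)
}

#' Dominance test of a concentration curve against the 45-degree line
#'
#' Multiple-comparison approach ("mca"): at each grid point compute
#' z = (L(p) - p) / se(p) and compare with a critical value adjusted for
#' the number of points (Sidak by default). The curve dominates the line of
#' equality when at least one difference is significantly positive and none
#' is significantly negative; the line dominates in the symmetric case;
#' significant differences of both signs indicate crossing; otherwise
#' non-dominance.
#'
#' @param curve a `concentration_curve` from [curve_ordinates()].
#' @param alpha familywise significance level (default 0.05).
#' @param adjust multiplicity adjustment of the per-point level: `"sidak"`
#'   (default), `"bonferroni"`, or `"none"`.
#' @return object of class `dominance_result` with the verdict, per-point
#'   z statistics and the critical value.
#' @export
dominance_test <- function(curve, alpha = 0.05,
                           adjust = c("sidak", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  k <- nrow(curve)
  diff <- curve$L - curve$p
  if (any(curve$se == 0 & abs(diff) > 1e-12)) {
    stop("zero ordinate standard error with nonzero difference: ",
         "degenerate variance", call. = FALSE)
  }
  z <- ifelse(curve$se > 0, diff / curve$se, 0)
  a_pp <- switch(adjust,
                 sidak = 1 - (1 - alpha)^(1 / k),
                 bonferroni = alpha / k,
                 none = alpha)
  crit <- stats::qnorm(a_pp / 2, lower.tail = FALSE)
  pos <- z > crit
  neg <- z < -crit
  verdict <- if (any(pos) && any(neg)) "crossing"
  else if (any(pos)) "curve_dominates"
  else if (any(neg)) "line_dominates"
  else "non_dominance"
  structure(list(verdict = verdict, z = z, critical_value = crit,
                 alpha = alpha, adjust = adjust, n_points = k,
                 rule = "mca"),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("Dominance vs 45-degree line: %s\n", x$verdict))
  cat(sprintf("rule = %s, %d points, familywise alpha = %g (%s), |z| crit = %.3f\n",
              x$rule, x$n_points, x$alpha, x$adjust, x$critical_value))
  invisible(x)
}

#' Plot concentration curves against the line of equality
#'
#' @param curves a single `concentration_curve` or a named list of them
#'   (one per outcome).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_concentration_curve <- function(curves, title = "Concentration curve") {
  if (inherits(curves, "concentration_curve")) curves <- list(outcome = curves)
  dat <- do.call(rbind, lapply(names(curves), function(nm) {
    cc <- curves[[nm]]
    data.frame(outcome = nm,
               p = c(0, cc$p, 1), L = c(0, cc$L, 1))
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = p, y = L, colour = outcome)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "cumulative share of children (poorest to richest)",
                  y = "cumulative share of outcome", title = title) +
    ggplot2::theme_minimal()
}
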