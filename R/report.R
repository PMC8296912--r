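#' Per-outcome analysis subset with ranks (listwise deletion)
#'
#' Each outcome analysis uses the rows complete for that outcome and the
#' wealth variable; fractional ranks are recomputed within the subset, so
#' different outcomes may have different analysis samples (as when outcome
#' ingredients are collected for different age ranges).
#'
#' @param data `childineq_data` with derived outcome columns.
#' @param outcome outcome column name.
#' @return list with `h`, `r`, `w`, `psu`, `n`.
#' @export
analysis_subset <- function(data, outcome) {
  h <- data[[outcome]]
  if (is.null(h)) stop("outcome column '", outcome, "' not found; ",
                       "run derive_outcomes() first", call. = FALSE)
  wealth <- data$wealth_score %||% data$wealth_quintile
  keep <- !is.na(h) & !is.na(wealth)
  w <- data$weight %||% rep(1, nrow(data))
  list(h = h[keep], r = fractional_rank(wealth[keep], w[keep]),
       w = w[keep], psu = data$psu[keep], n = sum(keep))
}

#' Erreygers index report across outcomes
#'
#' One row per outcome: ENCI, cluster-adjusted SE, p-value and
#' significance stars (p < 0.01 / 0.05 / 0.1), analysis n and PSU count.
#'
#' @param data `childineq_data` with derived outcomes.
#' @param outcomes outcome column names.
#' @return data frame.
#' @export
report_indices <- function(data, outcomes = c("immunized", "food_insecure",
                                              "malnourished")) {
  rows <- lapply(outcomes, function(oc) {
    s <- analysis_subset(data, oc)
    est <- erreygers_index(s$h, s$r, s$w, psu = s$psu)
    p <- if (est$std_error > 0) 2 * stats::pnorm(-abs(est$value / est$std_error))
    else as.numeric(est$value != 0)
    data.frame(outcome = oc, enci = est$value, se = est$std_error,
               p_value = p, stars = signif_stars(p), n = s$n,
               clusters = est$cluster_count)
  })
  do.call(rbind, rows)
}

#' Dominance-test report across outcomes
#'
#' @param data `childineq_data` with derived outcomes.
#' @param outcomes outcome column names.
#' @param alpha familywise level.
#' @param grid quantile grid.
#' @param adjust multiplicity adjustment, see [dominance_test()].
#' @return data frame: outcome, significance level, number of points,
#'   rule ("mca"), verdict.
#' @export
report_dominance <- function(data, outcomes = c("immunized", "food_insecure",
                                                "malnourished"),
                             alpha = 0.05, grid = seq(0.05, 0.95, by = 0.05),
                             adjust = "sidak") {
  rows <- lapply(outcomes, function(oc) {
    s <- analysis_subset(data, oc)
    cc <- curve_ordinates(s$h, s$r, s$w, grid = grid)
    dt <- dominance_test(cc, alpha = alpha, adjust = adjust)
    data.frame(outcome = oc, significance_level = alpha,
               n_points = dt$n_points, rule = dt$rule, verdict = dt$verdict)
  })
  do.call(rbind, rows)
}

#' Decomposition report for one outcome
#'
#' @param data `childineq_data` with derived outcomes.
#' @param outcome outcome column name.
#' @param covariates covariate column names entering the linear probability
#'   model.
#' @param expand_factors passed to [decompose_enci()].
#' @return an `enci_decomposition`.
#' @export
report_decomposition <- function(data, outcome, covariates,
                                 expand_factors = FALSE) {
  h <- data[[outcome]]
  wealth <- data$wealth_score %||% data$wealth_quintile
  X <- data[covariates]
  keep <- !is.na(h) & !is.na(wealth) & stats::complete.cases(X)
  w <- (data$weight %||% rep(1, nrow(data)))[keep]
  r <- fractional_rank(wealth[keep], w)
  decompose_enci(h[keep], X[keep, , drop = FALSE], r, w,
                 psu = data$psu[keep], expand_factors = expand_factors)
}

#' Write a run manifest sufficient to replay an analysis
#'
#' Records the configuration, an MD5 digest of the input file, and package
#' and R versions, as JSON.
#'
#' @param path output JSON path.
#' @param config a serializable list (the run configuration).
#' @param input_path optional input data file to digest.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, input_path = NULL) {
  manifest <- list(
    config = config,
    input_md5 = if (!is.null(input_path) && file.exists(input_path))
      unname(tools::md5sum(input_path)) else NULL,
    package_version = as.character(utils::packageVersion("childineq")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}
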