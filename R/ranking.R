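#' Weighted fractional socioeconomic ranks
#'
#' Midpoint-form fractional ranks in (0, 1): after sorting by wealth score
#' ascending, record i receives (cumulative weight before i + w_i/2) /
#' total weight. Tied scores share their group's weighted midpoint rank, so
#' the weighted mean rank is exactly 0.5 — the normalization the
#' concentration-index formula presumes. Ranks depend on the score only
#' through its ordering, so any strictly increasing transform of the score
#' leaves them unchanged.
#'
#' @param wealth_score numeric vector (continuous score or ordered group
#'   codes such as wealth quintiles).
#' @param w optional nonnegative weights (default equal).
#' @return numeric vector of fractional ranks in (0, 1).
#' @export
fractional_rank <- function(wealth_score, w = NULL) {
  n <- length(wealth_score)
  if (n == 0L) stop("empty wealth score vector", call. = FALSE)
  if (anyNA(wealth_score)) stop("wealth scores must be non-missing", call. = FALSE)
  w <- check_weights(w, n)
  ord <- order(wealth_score)
  s <- wealth_score[ord]
  ws <- w[ord]
  W <- sum(ws)
  grp <- cumsum(c(1L, as.integer(s[-1] != s[-n])))
  wg <- tapply(ws, grp, sum)
  before <- cumsum(wg) - wg
  rank_g <- (before + wg / 2) / W
  r <- numeric(n)
  r[ord] <- rank_g[grp]
  r
}

#' Wealth quintile assignment from weighted ranks
#'
#' Cuts the weighted rank distribution at 0.2, 0.4, 0.6, 0.8 so each
#' quintile holds 20% of the weighted population up to one record's weight.
#' Tied scores carry identical ranks, so a tie block always falls entirely
#' in the quintile containing its midpoint rank. When the input already
#' carries survey-provided quintiles, pass them through unchanged with
#' `use_provided`.
#'
#' @param wealth_score numeric vector of wealth scores.
#' @param w optional nonnegative weights.
#' @param use_provided optional integer vector of provided quintile labels
#'   (1..5); returned unchanged when supplied.
#' @return integer vector of quintile labels 1..5.
#' @export
assign_quintiles <- function(wealth_score, w = NULL, use_provided = NULL) {
  if (!is.null(use_provided)) {
    q <- as.integer(use_provided)
    if (any(!q %in% 1:5, na.rm = TRUE)) {
      stop("provided quintiles must lie in 1..5", call. = FALSE)
    }
    return(q)
  }
  r <- fractional_rank(wealth_score, w)
  1L + (r > 0.2) + (r > 0.4) + (r > 0.6) + (r > 0.8)
}
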