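#' Default column map for child-level microdata
#'
#' Maps the canonical column roles the pipeline needs onto the column names
#' found in an input file. DHS-flavoured defaults: the raw design weight is
#' `v005` (to be divided by 1,000,000), the cluster identifier is `psu`.
#' Vaccine-dose status columns and food-group flag columns are located by
#' prefix (`dose_`, `food_`).
#'
#' @param child_id,weight,psu,wealth_score,wealth_quintile,waz,age_months
#'   column names in the input file; `wealth_quintile`, `waz`, `age_months`
#'   and `child_id` may be `NULL` when absent.
#' @param dose_prefix,food_prefix prefixes locating vaccine-dose status and
#'   food-group flag columns.
#' @return a named list usable as `column_map` in [load_microdata()].
#' @export
default_column_map <- function(child_id = "child_id", weight = "v005",
                               psu = "psu", wealth_score = "wealth_score",
                               wealth_quintile = "wealth_quintile",
                               waz = "waz", age_months = NULL,
                               dose_prefix = "dose_", food_prefix = "food_") {
  list(child_id = child_id, weight = weight, psu = psu,
       wealth_score = wealth_score, wealth_quintile = wealth_quintile,
       waz = waz, age_months = age_months,
       dose_prefix = dose_prefix, food_prefix = food_prefix)
}

#' Rescale raw DHS-convention design weights
#'
#' DHS files store the child/woman design weight (`v005`) multiplied by
#' 1,000,000; analysis weights are recovered by dividing by that constant.
#'
#' @param raw_weight nonnegative numeric vector of raw weights.
#' @return `raw_weight / 1e6`.
#' @examples
#' normalize_weights(c(1e6, 0, 250000))
#' @export
normalize_weights <- function(raw_weight) {
  if (anyNA(raw_weight) || any(raw_weight < 0)) {
    stop("raw weights must be nonnegative and non-missing", call. = FALSE)
  }
  raw_weight / 1e6
}

#' Load and validate child-level survey microdata
#'
#' Reads a delimited text file of one row per child, renames columns to the
#' canonical roles given by `column_map`, applies row-level validation
#' (nonnegative numeric weight, non-missing cluster id, a usable wealth
#' score or quintile, optional age window) and normalizes the design
#' weights. Rows failing validation are dropped and tallied in the load
#' report (see [load_report()]).
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named list from [default_column_map()].
#' @param delim field delimiter (default comma).
#' @param encoding file encoding (default UTF-8).
#' @param weights_prenormalized if `TRUE` the weight column is already on
#'   the analysis scale and the division by 1,000,000 is skipped.
#' @param age_window optional `c(min, max)` in months; applied only when the
#'   map names an age column.
#' @return a `childineq_data` data frame with canonical columns
#'   `child_id`, `raw_weight`, `weight`, `psu`, `wealth_score`,
#'   `wealth_quintile`, `waz` plus all other input columns, and attributes
#'   `load_report` and `psu_count`.
#' @export
load_microdata <- function(path, column_map = default_column_map(),
                           delim = ",", encoding = "UTF-8",
                           weights_prenormalized = FALSE,
                           age_window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           fileEncoding = encoding, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (role in c("weight", "psu")) {
    cn <- column_map[[role]]
    if (is.null(cn) || !cn %in% names(raw)) {
      stop("required column for '", role, "' (", cn %||% "<unset>",
           ") missing from ", path, call. = FALSE)
    }
  }
  has_score <- !is.null(column_map$wealth_score) &&
    column_map$wealth_score %in% names(raw)
  has_quint <- !is.null(column_map$wealth_quintile) &&
    column_map$wealth_quintile %in% names(raw)
  if (!has_score && !has_quint) {
    stop("required column for 'wealth_score' or 'wealth_quintile' missing",
         call. = FALSE)
  }

  rename <- function(role, new) {
    cn <- column_map[[role]]
    if (!is.null(cn) && cn %in% names(raw)) names(raw)[names(raw) == cn] <<- new
  }
  rename("child_id", "child_id")
  rename("weight", "raw_weight")
  rename("psu", "psu")
  rename("wealth_score", "wealth_score")
  rename("wealth_quintile", "wealth_quintile")
  rename("waz", "waz")
  rename("age_months", "age_months")

  n_read <- nrow(raw)
  rej <- c(bad_weight = 0L, missing_psu = 0L, missing_wealth = 0L,
           bad_quintile = 0L, outside_age_window = 0L)

  wnum <- suppressWarnings(as.numeric(raw$raw_weight))
  ok <- !is.na(wnum) & wnum >= 0
  rej["bad_weight"] <- sum(!ok)
  keep <- ok
  raw$raw_weight <- wnum

  ok <- !is.na(raw$psu)
  rej["missing_psu"] <- sum(keep & !ok)
  keep <- keep & ok

  score_ok <- if (has_score) {
    raw$wealth_score <- suppressWarnings(as.numeric(raw$wealth_score))
    !is.na(raw$wealth_score)
  } else rep(FALSE, n_read)
  quint_ok <- if (has_quint) {
    raw$wealth_quintile <- suppressWarnings(as.integer(raw$wealth_quintile))
    !is.na(raw$wealth_quintile)
  } else rep(FALSE, n_read)
  ok <- score_ok | quint_ok
  rej["missing_wealth"] <- sum(keep & !ok)
  keep <- keep & ok

  if (has_quint) {
    bad_q <- quint_ok & !(raw$wealth_quintile %in% 1:5)
    rej["bad_quintile"] <- sum(keep & bad_q)
    keep <- keep & !bad_q
  }

  if (!is.null(age_window) && "age_months" %in% names(raw)) {
    age <- suppressWarnings(as.numeric(raw$age_months))
    ok <- !is.na(age) & age >= age_window[1] & age <= age_window[2]
    rej["outside_age_window"] <- sum(keep & !ok)
    keep <- keep & ok
  }

  dat <- raw[keep, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no usable rows in ", path, call. = FALSE)
  rownames(dat) <- NULL
  dat$weight <- if (weights_prenormalized) dat$raw_weight else
    normalize_weights(dat$raw_weight)

  as_childineq_data(dat,
    load_report = list(n_read = n_read, n_kept = nrow(dat),
                       n_dropped = n_read - nrow(dat),
                       rejections = as.list(rej)))
}

as_childineq_data <- function(dat, load_report = NULL) {
  attr(dat, "load_report") <- load_report %||%
    list(n_read = nrow(dat), n_kept = nrow(dat), n_dropped = 0L,
         rejections = list())
  attr(dat, "psu_count") <- length(unique(dat$psu))
  class(dat) <- c("childineq_data", "data.frame")
  dat
}

#' Machine-readable load report of a microdata file
#'
#' @param data a `childineq_data` object from [load_microdata()].
#' @return list with counts read/kept/dropped and per-rule rejection tallies.
#' @export
load_report <- function(data) attr(data, "load_report")

#' Write microdata in the delimited-text format [load_microdata()] reads
#'
#' @param data a `childineq_data` object (or compatible data frame).
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(data, path, delim = ",") {
  out <- as.data.frame(data)
  out$weight <- NULL          # recomputed on load
  if ("raw_weight" %in% names(out)) {
    names(out)[names(out) == "raw_weight"] <- "v005"
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weighted percentage distribution of outcome-positive children
#'
#' Column percentages in the survey-report convention: among children with
#' the outcome present, the weighted share falling in each category of a
#' grouping variable. Shares sum to 100 across categories.
#'
#' @param data `childineq_data` (or data frame with a `weight` column).
#' @param outcome name of a binary (0/1) column.
#' @param by name of a categorical column.
#' @return data frame with columns `category` and `pct`.
#' @export
weighted_prevalence <- function(data, outcome, by) {
  h <- data[[outcome]]
  g <- data[[by]]
  if (is.null(h)) stop("outcome column '", outcome, "' not found", call. = FALSE)
  if (is.null(g)) stop("grouping column '", by, "' not found", call. = FALSE)
  w <- data$weight %||% rep(1, nrow(data))
  keep <- !is.na(h) & !is.na(g)
  if (!any(keep)) stop("grouping column '", by, "' is all-missing", call. = FALSE)
  h <- h[keep]; g <- g[keep]; w <- w[keep]
  if (!all(h %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  wpos <- w * h
  tot <- sum(wpos)
  if (tot <= 0) stop("no outcome-positive weight", call. = FALSE)
  shares <- tapply(wpos, g, sum) / tot * 100
  data.frame(category = names(shares), pct = as.numeric(shares),
             row.names = NULL)
}
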