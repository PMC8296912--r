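#' Default childhood immunization schedule
#'
#' The full-immunization definition used throughout: 1 dose of BCG, 4 of
#' oral polio vaccine, 3 of pentavalent, 3 of pneumococcal conjugate, 2 of
#' rotavirus and 1 each of measles and yellow fever — 7 vaccines, 15 doses.
#' A child is fully immunized only if every scheduled dose is card-dated.
#'
#' @return data frame with columns `vaccine`, `dose` and `column` (the
#'   microdata column holding that dose's status).
#' @export
default_schedule <- function() {
  v <- c("bcg", rep("opv", 4), rep("penta", 3), rep("pcv", 3),
         rep("rota", 2), "measles", "yellow_fever")
  d <- c(1, 1:4, 1:3, 1:3, 1:2, 1, 1)
  data.frame(vaccine = v, dose = d,
             column = paste0("dose_", v, d), stringsAsFactors = FALSE)
}

#' Read an immunization schedule from a plain-text file
#'
#' Two delimited columns, `vaccine` and `dose`, one scheduled dose per row;
#' national schedules other than the default can be supplied this way.
#'
#' @param path path to a delimited text file with header `vaccine,dose`.
#' @param delim field delimiter.
#' @return schedule data frame as in [default_schedule()].
#' @export
read_schedule <- function(path, delim = ",") {
  s <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE)
  if (!all(c("vaccine", "dose") %in% names(s))) {
    stop("schedule file must have columns 'vaccine' and 'dose'", call. = FALSE)
  }
  s$dose <- as.integer(s$dose)
  s$column <- paste0("dose_", s$vaccine, s$dose)
  s
}

#' Full-immunization indicator
#'
#' 1 if and only if every dose in the schedule has status `"card_dated"`.
#' Mother's verbal report without written card confirmation
#' (`"verbal_only"`) does not count, to avoid recall bias; a missing status
#' or missing dose column counts as not received.
#'
#' @param data data frame holding one status column per scheduled dose, with
#'   values in `c("card_dated", "verbal_only", "none")`.
#' @param schedule schedule data frame ([default_schedule()]).
#' @return integer 0/1 vector, one element per row of `data`.
#' @export
full_immunization <- function(data, schedule = default_schedule()) {
  out <- rep(TRUE, nrow(data))
  for (cn in schedule$column) {
    if (!cn %in% names(data)) return(integer(nrow(data)))   # missing = none
    st <- data[[cn]]
    out <- out & !is.na(st) & st == "card_dated"
  }
  as.integer(out)
}

#' Dietary diversity score over 13 food groups
#'
#' @param food_flags data frame or matrix with exactly 13 logical/0-1
#'   columns, one per food group.
#' @return integer vector of counts in 0..13.
#' @export
dietary_diversity_score <- function(food_flags) {
  food_flags <- as.data.frame(food_flags)
  if (ncol(food_flags) != 13L) {
    stop("exactly 13 food-group flags required, got ", ncol(food_flags),
         call. = FALSE)
  }
  m <- vapply(food_flags, function(x) as.numeric(as.logical(x)),
              numeric(nrow(food_flags)))
  as.integer(rowSums(matrix(m, nrow = nrow(food_flags))))
}

#' Food-insecurity indicator from a dietary diversity score
#'
#' Follows the IYCF minimum-dietary-diversity reading: a child consuming
#' fewer than `threshold` (default 4) of the 13 food groups is food
#' insecure.
#'
#' @param score integer dietary diversity scores in 0..13.
#' @param threshold minimum number of food groups for food security;
#'   children with `score < threshold` are insecure.
#' @return integer 0/1 vector (1 = insecure).
#' @export
food_insecure <- function(score, threshold = 4) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 1 || threshold > 13) {
    stop("dd_threshold must be a single value in 1..13", call. = FALSE)
  }
  if (any(score < 0 | score > 13, na.rm = TRUE)) {
    stop("dietary diversity scores must lie in 0..13", call. = FALSE)
  }
  ifelse(is.na(score), NA_integer_, as.integer(score < threshold))
}

#' Malnutrition indicator from weight-for-age z-scores
#'
#' 1 if the weight-for-age z-score lies strictly below −2 SD of the
#' reference median. Missing z-scores propagate as `NA` and are excluded
#' from nutrition analyses by listwise deletion.
#'
#' @param waz numeric weight-for-age z-scores.
#' @return integer 0/1 vector (1 = malnourished), `NA` where `waz` missing.
#' @export
malnourished <- function(waz) {
  ifelse(is.na(waz), NA_integer_, as.integer(waz < -2))
}

#' Derive the three binary child-health outcomes
#'
#' Adds `immunized`, `food_insecure` and `malnourished` columns to a
#' microdata set, from the dose-status columns, the 13 food-group flag
#' columns (located by prefix) and the `waz` column respectively.
#'
#' @param data `childineq_data` from [load_microdata()] or
#'   [generate_dataset()].
#' @param schedule immunization schedule ([default_schedule()]).
#' @param dd_threshold food-security threshold passed to [food_insecure()].
#' @param food_prefix prefix locating the food-group flag columns.
#' @return `data` with the three outcome columns appended.
#' @export
derive_outcomes <- function(data, schedule = default_schedule(),
                            dd_threshold = 4, food_prefix = "food_") {
  data$immunized <- full_immunization(data, schedule)
  food_cols <- grep(paste0("^", food_prefix), names(data), value = TRUE)
  if (length(food_cols) == 13L) {
    score <- dietary_diversity_score(data[food_cols])
    data$food_insecure <- food_insecure(score, dd_threshold)
  }
  if ("waz" %in% names(data)) data$malnourished <- malnourished(data$waz)
  data
}
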