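#' Configuration of the DHS-like synthetic data generator
#'
#' Defines a clustered child-survey population with known-truth inequality:
#' a latent log-normal household wealth score with a PSU-level random
#' intercept (share `rho` of the latent variance), wealth-correlated
#' covariates, v005-scale design weights (gamma, mean 1,000,000, CV 0.3),
#' and binary outcomes drawn from linear probability models with stated
#' coefficient vectors (probabilities clipped into `clip`). Outcome
#' ingredients (dose statuses, food-group flags, weight-for-age z-scores)
#' are constructed to reproduce the drawn labels exactly under
#' [derive_outcomes()].
#'
#' Coefficients are expressed on the covariate scales produced by the
#' generator: `wealth_quintile` 1..5, `rural` 0/1, `mother_edu` 0..3,
#' `mother_age` in years (truncated 15..49), `household_size` >= 1,
#' `birth_order` >= 1, and 0/1 flags `anc4`, `facility_delivery`,
#' `media_exposure`, `pnc`, `head_female`, `child_female`.
#'
#' @param n_children number of child records.
#' @param n_psu number of primary sampling units.
#' @param rho share of latent wealth variance at the PSU level, in \[0, 1).
#' @param weight_mean,weight_cv mean and coefficient of variation of the
#'   raw (v005-scale) design weights.
#' @param outcome_coefs named list of named coefficient vectors (one per
#'   outcome; names `immunized`, `food_insecure`, `malnourished`), each
#'   with an `(Intercept)` entry and entries named after covariates.
#' @param clip `c(lo, hi)` clipping range for outcome probabilities.
#' @param psu_outcome_sd optional SD of an additional PSU-level shock added
#'   to the outcome probabilities (default 0: cluster effects enter wealth
#'   only). Used to exercise cluster-robust variance estimators.
#' @param dd_threshold food-security threshold the ingredients encode.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_children = 20000, n_psu = 650, rho = 0.3,
                             weight_mean = 1e6, weight_cv = 0.3,
                             outcome_coefs = default_outcome_coefs(),
                             clip = c(0.01, 0.99), psu_outcome_sd = 0,
                             dd_threshold = 4) {
  if (n_children < 2 || n_psu < 1) stop("need n_children >= 2, n_psu >= 1",
                                        call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (clip[1] <= 0 || clip[2] >= 1 || clip[1] >= clip[2]) {
    stop("clip must satisfy 0 < lo < hi < 1", call. = FALSE)
  }
  for (nm in names(outcome_coefs)) {
    if (!"(Intercept)" %in% names(outcome_coefs[[nm]])) {
      stop("outcome '", nm, "' lacks an (Intercept) coefficient", call. = FALSE)
    }
  }
  structure(list(n_children = n_children, n_psu = n_psu, rho = rho,
                 weight_mean = weight_mean, weight_cv = weight_cv,
                 outcome_coefs = outcome_coefs, clip = clip,
                 psu_outcome_sd = psu_outcome_sd,
                 dd_threshold = dd_threshold),
            class = "generator_config")
}

#' Default outcome coefficient vectors of the synthetic generator
#'
#' The generator's own truth: a pro-rich gradient in full immunization and
#' pro-poor gradients in food insecurity and malnutrition, with covariate
#' effects of realistic sign and modest size so that clipping of the
#' linear-probability draws is negligible.
#'
#' @return named list of named numeric vectors.
#' @export
default_outcome_coefs <- function() {
  list(
    immunized = c(`(Intercept)` = 0.30, wealth_quintile = 0.040,
                  rural = -0.030, mother_edu = 0.030, mother_age = 0.002,
                  anc4 = 0.060, facility_delivery = 0.050,
                  media_exposure = 0.020, birth_order = -0.020),
    food_insecure = c(`(Intercept)` = 0.45, wealth_quintile = -0.050,
                      rural = 0.040, mother_edu = -0.040,
                      household_size = 0.005, head_female = -0.020),
    malnourished = c(`(Intercept)` = 0.45, wealth_quintile = -0.060,
                     rural = 0.030, mother_edu = -0.030,
                     mother_age = -0.001, household_size = 0.004)
  )
}

# covariate draws given the latent wealth z-score
draw_covariates <- function(n, z) {
  edu_latent <- z + stats::rnorm(n)
  age <- stats::rnorm(n, 28, 6)
  age <- pmin(pmax(age, 15), 49)
  data.frame(
    rural = stats::rbinom(n, 1, stats::plogis(0.5 - 1.0 * z)),
    mother_edu = findInterval(edu_latent, c(-0.8, 0.2, 1.2)),
    mother_age = age,
    head_female = stats::rbinom(n, 1, 0.15),
    child_female = stats::rbinom(n, 1, 0.487),
    household_size = 1L + stats::rpois(n, 4),
    birth_order = 1L + stats::rpois(n, 1.2),
    anc4 = stats::rbinom(n, 1, stats::plogis(-0.2 + 0.8 * z)),
    facility_delivery = stats::rbinom(n, 1, stats::plogis(0.8 + 0.9 * z)),
    media_exposure = stats::rbinom(n, 1, stats::plogis(1.1 * z)),
    pnc = stats::rbinom(n, 1, stats::plogis(-0.3 + 0.5 * z))
  )
}

lpm_probability <- function(covs, coefs, clip) {
  p <- rep(coefs[["(Intercept)"]], nrow(covs))
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    if (!nm %in% names(covs)) stop("unknown covariate in coefficients: ", nm,
                                   call. = FALSE)
    p <- p + coefs[[nm]] * covs[[nm]]
  }
  pmin(pmax(p, clip[1]), clip[2])
}

#' Generate a clustered DHS-like synthetic dataset
#'
#' Reproducible for a fixed seed. Returns both the microdata (with raw
#' outcome ingredients, so [derive_outcomes()] recovers the drawn labels
#' exactly) and the truth record: the coefficient vectors and drawn labels.
#'
#' @param config a [generator_config()].
#' @param seed integer random seed.
#' @return list with elements `data` (a `childineq_data`) and `truth`
#'   (list: `config`, `outcome_coefs`, `labels` — a data frame of the
#'   drawn outcome labels).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n_children
  psu <- sample.int(config$n_psu, n, replace = TRUE)
  u <- stats::rnorm(config$n_psu, 0, sqrt(config$rho))
  z <- u[psu] + stats::rnorm(n, 0, sqrt(1 - config$rho))
  wealth_score <- exp(z)

  shape <- 1 / config$weight_cv^2
  v005 <- round(stats::rgamma(n, shape = shape,
                              scale = config$weight_mean / shape))

  covs <- draw_covariates(n, z)
  covs$wealth_quintile <- assign_quintiles(wealth_score, v005 / 1e6)

  shock <- if (config$psu_outcome_sd > 0) {
    stats::rnorm(config$n_psu, 0, config$psu_outcome_sd)[psu]
  } else 0

  labels <- list()
  for (nm in names(config$outcome_coefs)) {
    p <- lpm_probability(covs, config$outcome_coefs[[nm]], config$clip)
    p <- pmin(pmax(p + shock, config$clip[1]), config$clip[2])
    labels[[nm]] <- stats::rbinom(n, 1, p)
  }
  labels <- as.data.frame(labels)

  dat <- data.frame(child_id = seq_len(n), raw_weight = v005,
                    weight = v005 / 1e6, psu = psu,
                    wealth_score = wealth_score, covs,
                    check.names = FALSE)
  ing <- make_ingredients(labels, config$dd_threshold)
  if (ncol(ing) > 0) dat <- cbind(dat, ing)
  dat <- as_childineq_data(dat)
  list(data = dat, truth = list(config = config,
                                outcome_coefs = config$outcome_coefs,
                                labels = labels))
}

# raw outcome ingredients consistent with the drawn labels
make_ingredients <- function(labels, dd_threshold) {
  n <- nrow(labels)
  out <- list()
  if (!is.null(labels$immunized)) {
    sched <- default_schedule()
    status <- matrix("card_dated", n, nrow(sched),
                     dimnames = list(NULL, sched$column))
    miss <- which(labels$immunized == 0)
    if (length(miss)) {
      spoiled <- sample(nrow(sched), length(miss), replace = TRUE)
      status[cbind(miss, spoiled)] <-
        sample(c("verbal_only", "none"), length(miss), replace = TRUE)
    }
    out <- c(out, as.data.frame(status, stringsAsFactors = FALSE))
  }
  if (!is.null(labels$food_insecure)) {
    score <- ifelse(labels$food_insecure == 1,
                    sample(0:(dd_threshold - 1), n, replace = TRUE),
                    sample(dd_threshold:13, n, replace = TRUE))
    flags <- matrix(0L, n, 13, dimnames = list(NULL, paste0("food_", 1:13)))
    pick <- sample.int(13, 13)   # fixed random group order per dataset
    flags[cbind(rep(seq_len(n), score), pick[sequence(score)])] <- 1L
    out <- c(out, as.data.frame(flags))
  }
  if (!is.null(labels$malnourished)) {
    out$waz <- ifelse(labels$malnourished == 1,
                      -2 - abs(stats::rnorm(n, 0, 0.9)) - 0.001,
                      -2 + abs(stats::rnorm(n, 0, 1.1)))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Population truth of a generator configuration by brute-force Monte Carlo
#'
#' Evaluates the generator's own population Erreygers index and the
#' decomposition contributions 4 beta_k xbar_k CI_k (using the true
#' coefficients) on a single large draw of `oracle_n` children. The
#' reported `enci_se` is the sampling SE of the oracle ENCI itself and
#' quantifies the Monte-Carlo error of the truth values.
#'
#' @param config a [generator_config()].
#' @param oracle_n Monte-Carlo population size (default 200,000).
#' @param seed oracle seed (kept separate from analysis seeds).
#' @return named list, one entry per outcome, each with `enci`, `enci_se`,
#'   `contributions` (named) and `n`.
#' @export
population_truth <- function(config = generator_config(), oracle_n = 200000,
                             seed = 10007) {
  big <- config
  big$n_children <- oracle_n
  big$n_psu <- max(2L, round(config$n_psu * oracle_n / config$n_children))
  gen <- generate_dataset(big, seed = seed)
  dat <- gen$data
  r <- fractional_rank(dat$wealth_score, dat$weight)
  out <- list()
  for (nm in names(config$outcome_coefs)) {
    y <- gen$truth$labels[[nm]]
    est <- erreygers_index(y, r, dat$weight, psu = dat$psu)
    coefs <- config$outcome_coefs[[nm]]
    ks <- setdiff(names(coefs), "(Intercept)")
    contrib <- vapply(ks, function(k) {
      2 * 4 * coefs[[k]] * weighted_cov(dat[[k]], r, dat$weight)
    }, numeric(1))
    out[[nm]] <- list(enci = est$value, enci_se = est$std_error,
                      contributions = contrib, n = oracle_n)
  }
  out
}
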