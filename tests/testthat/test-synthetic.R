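test_that("generation is deterministic for a fixed seed", {
  cfg <- generator_config(n_children = 500, n_psu = 25)
  g1 <- generate_dataset(cfg, seed = 123)
  g2 <- generate_dataset(cfg, seed = 123)
  expect_identical(g1$data, g2$data)
  expect_identical(g1$truth$labels, g2$truth$labels)
  g3 <- generate_dataset(cfg, seed = 124)
  expect_false(identical(g1$truth$labels, g3$truth$labels))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(rho = 1), "rho")
  expect_error(generator_config(clip = c(0, 0.5)), "clip")
  expect_error(generator_config(outcome_coefs = list(y = c(x = 1))),
               "Intercept")
  bad <- generator_config(outcome_coefs = list(
    immunized = c(`(Intercept)` = 0.5, not_a_covariate = 1)))
  expect_error(generate_dataset(bad, seed = 1), "unknown covariate")
})

test_that("generated quintiles have near-equal weighted shares", {
  gen <- generate_dataset(generator_config(n_children = 10000, n_psu = 300),
                          seed = 5)
  d <- gen$data
  shares <- tapply(d$weight, d$wealth_quintile, sum) / sum(d$weight)
  expect_true(all(abs(shares - 0.2) < 0.01))
})

test_that("a flat outcome model yields an index near zero", {
  cfg <- generator_config(
    n_children = 10000, n_psu = 300,
    outcome_coefs = list(flat = c(`(Intercept)` = 0.5)))
  gen <- generate_dataset(cfg, seed = 77)
  d <- gen$data
  r <- fractional_rank(d$wealth_score, d$weight)
  est <- erreygers_index(gen$truth$labels$flat, r, d$weight, psu = d$psu)
  expect_lt(abs(est$value), 3 * est$std_error)
})

test_that("a strong wealth gradient always surfaces with the right sign", {
  cfg <- generator_config(
    n_children = 5000, n_psu = 200,
    outcome_coefs = list(prorich = c(`(Intercept)` = 0.2,
                                     wealth_quintile = 0.1)))
  values <- sapply(1:20, function(s) {
    gen <- generate_dataset(cfg, seed = s)
    d <- gen$data
    r <- fractional_rank(d$wealth_score, d$weight)
    erreygers_index(gen$truth$labels$prorich, r, d$weight)$value
  })
  expect_true(all(values > 0))
})

test_that("population truth behaves like a Monte-Carlo oracle", {
  null_cfg <- generator_config(
    n_children = 2000, n_psu = 100,
    outcome_coefs = list(flat = c(`(Intercept)` = 0.5)))
  tr <- population_truth(null_cfg, oracle_n = 40000, seed = 901)
  expect_lt(abs(tr$flat$enci), 3 * tr$flat$enci_se)
  expect_length(tr$flat$contributions, 0)

  one_cfg <- generator_config(
    n_children = 2000, n_psu = 100,
    outcome_coefs = list(y = c(`(Intercept)` = 0.3, wealth_quintile = 0.08)))
  tr1 <- population_truth(one_cfg, oracle_n = 40000, seed = 902)
  # single covariate: its contribution carries essentially the whole index
  expect_lt(abs(tr1$y$enci - tr1$y$contributions[["wealth_quintile"]]),
            4 * tr1$y$enci_se)

  # doubling the oracle population shrinks the oracle SE by about root two
  tr_small <- population_truth(one_cfg, oracle_n = 20000, seed = 903)
  tr_big <- population_truth(one_cfg, oracle_n = 80000, seed = 903)
  ratio <- tr_small$y$enci_se / tr_big$y$enci_se
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("estimates from generated samples converge to population truth", {
  cfg <- generator_config(n_children = 2000, n_psu = 100)
  tr <- population_truth(cfg, oracle_n = 100000, seed = 904)$immunized
  est_at <- function(n, seed) {
    cfg_n <- generator_config(n_children = n, n_psu = max(50, n %/% 30))
    gen <- generate_dataset(cfg_n, seed = seed)
    d <- gen$data
    r <- fractional_rank(d$wealth_score, d$weight)
    erreygers_index(gen$truth$labels$immunized, r, d$weight, psu = d$psu)
  }
  e_small <- est_at(2000, 31)
  e_big <- est_at(20000, 31)
  expect_lt(abs(e_small$value - tr$enci), 4 * e_small$std_error)
  expect_lt(abs(e_big$value - tr$enci), 4 * e_big$std_error)
  expect_lt(e_big$std_error, e_small$std_error)
})
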