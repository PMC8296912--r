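test_that("closed-form limits of the concentration index are recovered", {
  # constant outcome: no covariance with rank
  r <- fractional_rank(rnorm(100))
  est <- concentration_index(rep(1, 100), r)
  expect_true(est$value == 0)

  # h = r (perfect gradient): CI -> 2 * (1/12) / (1/2) = 1/3
  n <- 10000
  r <- (seq_len(n) - 0.5) / n
  expect_lt(abs(concentration_index(r, r)$value - 1/3), 1e-3)

  # outcome held by the richest half only: CI -> 0.5, ENCI -> 1
  h <- as.numeric(r > 0.5)
  expect_lt(abs(concentration_index(h, r)$value - 0.5), 1e-3)
  expect_lt(abs(erreygers_index(h, r)$value - 1), 0.01)
})

test_that("mirror property and wealth-reversal antisymmetry hold exactly", {
  for (seed in 1:5) {
    x <- random_hrw(200, seed)
    e1 <- erreygers_index(x$h, x$r, x$w)$value
    e2 <- erreygers_index(1 - x$h, x$r, x$w)$value
    expect_equal(e1, -e2, tolerance = 1e-12)
    # reversing the wealth ordering flips the sign
    rr <- fractional_rank(-x$wealth, x$w)
    expect_equal(erreygers_index(x$h, rr, x$w)$value, -e1, tolerance = 1e-12)
  }
})

test_that("the convenient-regression route equals the covariance route", {
  for (seed in 1:20) {
    x <- random_hrw(sample(50:400, 1), seed)
    a <- concentration_index(x$h, x$r, x$w, method = "covariance")$value
    b <- concentration_index(x$h, x$r, x$w, method = "regression")$value
    expect_lt(abs(a - b), 1e-10)
    ea <- erreygers_index(x$h, x$r, x$w, method = "covariance")$value
    eb <- erreygers_index(x$h, x$r, x$w, method = "regression")$value
    expect_lt(abs(ea - eb), 1e-10)
  }
})

test_that("with one record per PSU the clustered SE matches the
           heteroskedasticity-robust SE", {
  x <- random_hrw(250, seed = 6)
  psu1 <- seq_along(x$h)
  a <- erreygers_index(x$h, x$r, x$w, psu = psu1)$std_error
  b <- erreygers_index(x$h, x$r, x$w, psu = NULL)$std_error
  expect_equal(a, b, tolerance = 0.02)   # HC1 vs CR1 small-sample factors
})

test_that("the cluster-adjusted SE agrees with a cluster bootstrap", {
  cfg <- generator_config(n_children = 4000, n_psu = 100,
                          psu_outcome_sd = 0.08)
  gen <- generate_dataset(cfg, seed = 31)
  d <- gen$data
  y <- gen$truth$labels$immunized
  r <- fractional_rank(d$wealth_score, d$weight)
  analytic <- erreygers_index(y, r, d$weight, psu = d$psu)$std_error

  set.seed(99)
  idx <- split(seq_len(nrow(d)), d$psu)
  boots <- replicate(1000, {
    take <- unlist(idx[sample(names(idx), length(idx), replace = TRUE)],
                   use.names = FALSE)
    rb <- fractional_rank(d$wealth_score[take], d$weight[take])
    erreygers_index(y[take], rb, d$weight[take])$value
  })
  expect_lt(abs(analytic - sd(boots)) / sd(boots), 0.15)
})

test_that("doubling the clusters shrinks the SE by about root two", {
  x <- random_hrw(600, seed = 13)
  se1 <- erreygers_index(x$h, x$r, x$w, psu = x$psu)$std_error
  h2 <- rep(x$h, 2); w2 <- rep(x$w, 2)
  wl2 <- rep(x$wealth, 2)
  psu2 <- c(x$psu, x$psu + max(x$psu))
  r2 <- fractional_rank(wl2, w2)
  se2 <- erreygers_index(h2, r2, w2, psu = psu2)$std_error
  expect_gt(se1 / se2, 1.3)
  expect_lt(se1 / se2, 1.5)
})

test_that("degenerate inputs raise informative errors", {
  r <- fractional_rank(1:10)
  expect_error(concentration_index(rep(0, 10), r), "undefined")
  expect_error(erreygers_index(rbinom(10, 1, 0.5), r, psu = rep(1, 10)),
               "one PSU")
  expect_error(erreygers_index(c(rep(0.5, 9), 2), r), "bounds")
  expect_error(erreygers_index(rep(1, 10), r, bounds = c(1, 1)), "b > a")
})

test_that("the 95% interval is value plus-minus 1.96 SE", {
  x <- random_hrw(300, seed = 17)
  est <- erreygers_index(x$h, x$r, x$w, psu = x$psu)
  expect_equal(est$ci95,
               c(est$value - 1.96 * est$std_error,
                 est$value + 1.96 * est$std_error))
})
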