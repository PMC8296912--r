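test_that("linear probability model recovers closed-form coefficients", {
  set.seed(3)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  w <- runif(n, 0.5, 2)
  y <- rbinom(n, 1, 0.3 + 0.4 * x)
  fit <- fit_lpm(y, data.frame(x = x), w)
  diff_means <- weighted.mean(y[x == 1], w[x == 1]) -
    weighted.mean(y[x == 0], w[x == 0])
  expect_equal(unname(fit$coefficients["x"]), diff_means, tolerance = 1e-10)

  # y identical to a covariate
  fit2 <- fit_lpm(y, data.frame(a = y, b = x), w)
  expect_equal(unname(fit2$coefficients["a"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit2$coefficients["b"]), 0, tolerance = 1e-10)
})

test_that("coefficients match a brute-force normal-equations solve", {
  set.seed(14)
  n <- 300
  X <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5), c = rpois(n, 2))
  w <- runif(n, 0.2, 3)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_lpm(y, X, w)
  D <- cbind(1, as.matrix(X))
  beta <- solve(t(D) %*% (w * D), t(D) %*% (w * y))
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(15)
  X <- data.frame(a = rnorm(50))
  X$dup <- 2 * X$a
  expect_error(fit_lpm(rbinom(50, 1, 0.5), X), "dup")
})

test_that("covariate concentration indices follow their closed forms", {
  n <- 10000
  r <- (seq_len(n) - 0.5) / n
  expect_lt(abs(covariate_ci(r, r) - 1/3), 1e-3)    # rank against itself
  expect_equal(covariate_ci(rep(2, n), r), 0)       # constant covariate
  rich <- as.numeric(r > 0.8)                       # held only by the richest
  expect_gt(covariate_ci(rich, r), 0)
  expect_warning(ci0 <- covariate_ci(c(-1, 1), c(0.25, 0.75)), "zero-mean")
  expect_true(is.na(ci0))
})

test_that("the adding-up identity is exact on arbitrary inputs", {
  set.seed(26)
  for (i in 1:20) {
    n <- sample(100:500, 1)
    k <- sample(2:5, 1)
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    wealth <- rnorm(n)
    w <- runif(n, 0.2, 2)
    r <- fractional_rank(wealth, w)
    y <- rbinom(n, 1, plogis(0.3 * wealth + rowSums(X) / (2 * k)))
    dec <- decompose_enci(y, X, r, w)
    expect_lt(decomposition_gap(dec), 1e-10)
    expect_lt(abs(sum(dec$pct) + attr(dec, "residual_pct") - 100), 1e-8)
  }
})

test_that("an outcome independent of the covariates attributes the index
           to the residual", {
  set.seed(41)
  n <- 20000
  wealth <- rnorm(n)
  r <- fractional_rank(wealth)
  y <- rbinom(n, 1, plogis(0.8 * wealth))
  X <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))  # pure noise
  dec <- decompose_enci(y, X, r)
  enci <- attr(dec, "enci")$value
  expect_true(all(abs(dec$contribution) < 0.02))
  expect_lt(abs(attr(dec, "residual") - enci) / abs(enci), 0.1)
})

test_that("published-style cell identities: contribution = 4 x elasticity
           x covariate CI", {
  expect_equal(round(enci_contribution(0.0439, 0.2870), 4), 0.0504)
  expect_equal(round(enci_contribution(-0.0616, 0.2405), 4), -0.0593)
  expect_equal(round(enci_contribution(-0.0226, -0.1719), 4), 0.0155)
})

test_that("a numerically zero index suppresses percent contributions", {
  set.seed(50)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  r <- fractional_rank(rep(1:(n / 2), each = 2))   # engineered zero cov
  X <- data.frame(a = rnorm(n))
  # force exact zero: constant outcome within each rank tie
  expect_warning(dec <- decompose_enci(y, X, rep(0.5, n)), "zero")
  expect_true(all(is.na(dec$pct)))
  expect_true(is.na(attr(dec, "residual_pct")))
})

test_that("ordinal and dummy encodings both run; categorical levels are
           coded against the lowest level", {
  set.seed(52)
  n <- 300
  X <- data.frame(edu = sample(c("none", "primary", "secondary"), n, TRUE),
                  rural = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  r <- fractional_rank(rnorm(n))
  dec1 <- decompose_enci(y, X, r)
  expect_equal(nrow(dec1), 2)            # one row per covariate
  dec2 <- decompose_enci(y, X, r, expand_factors = TRUE)
  expect_gt(nrow(dec2), 2)               # one row per non-reference level
  expect_lt(decomposition_gap(dec2), 1e-10)
})
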