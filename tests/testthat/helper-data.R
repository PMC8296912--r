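# Shared fixture builders and independent oracles. Oracles are written as
# plain loops so they stay independent of the vectorized implementation.

random_hrw <- function(n, seed, gradient = 0.5) {
  set.seed(seed)
  wealth <- rnorm(n)
  w <- runif(n, 0.2, 2)
  psu <- sample(seq_len(max(2L, n %/% 10)), n, replace = TRUE)
  h <- rbinom(n, 1, plogis(gradient * wealth))
  list(h = h, wealth = wealth, r = fractional_rank(wealth, w), w = w,
       psu = psu)
}

# brute-force concentration-curve ordinates: explicit per-point accumulation
brute_curve <- function(h, r, w, grid) {
  ord <- order(r)
  h <- h[ord]; w <- w[ord]
  tot_w <- sum(w)
  tot_h <- sum(w * h)
  sapply(grid, function(p) {
    acc <- 0; cw <- 0
    for (i in seq_along(h)) {
      cw <- cw + w[i]
      if (cw / tot_w <= p + 1e-12) acc <- acc + w[i] * h[i] else break
    }
    acc / tot_h
  })
}

# brute-force weighted group shares among outcome-positive records
brute_prevalence <- function(h, g, w) {
  cats <- sort(unique(g))
  num <- sapply(cats, function(cc) {
    s <- 0
    for (i in seq_along(h)) if (g[i] == cc && h[i] == 1) s <- s + w[i]
    s
  })
  100 * num / sum(num)
}

# small microdata file on disk for load tests
write_fixture_csv <- function(path, weights = c(1e6, 5e5, 2e6, 1e6),
                              psu = c(1, 1, 2, 2)) {
  df <- data.frame(child_id = seq_along(weights), v005 = weights, psu = psu,
                   wealth_score = seq_along(weights) / 2,
                   wealth_quintile = rep_len(1:2, length(weights)),
                   waz = c(-2.5, 0, -1, -3)[seq_along(weights)])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
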