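test_that("Shannon entropy matches textbook values", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_error(shannon_entropy(c(0.7, 0.6)), "sum to 1")
})

test_that("empirical joint distribution uses plug-in frequencies", {
  d <- empirical_joint(x = c(0L, 0L, 1L, 1L), y = c(0L, 1L, 0L, 1L))
  expect_equal(sum(d$probability), 1)
  expect_equal(nrow(d), 4L)
  expect_true(all(d$probability == 0.25))
})

test_that("conditional TE is exactly zero for a deterministic target", {
  # x alternates, so its next value is a function of its present value:
  # both conditional entropies vanish and TE is exactly zero
  x <- rep(c(0L, 1L), 60)
  set.seed(2)
  y <- rbinom(120, 1, 0.5)
  z <- rbinom(120, 1, 0.5)
  expect_identical(conditional_te(x, y, z)$te_bits, 0)
})

test_that("independent series give near-zero TE at large samples", {
  set.seed(41)
  n <- 10000
  r <- conditional_te(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                      rbinom(n, 1, 0.5))
  expect_lt(r$te_bits, 0.02)
  expect_gte(r$te_bits, 0)
})

test_that("a copy process transfers the source entropy", {
  set.seed(6)
  n <- 1000
  y <- rbinom(n, 1, 0.5)
  x <- c(0L, y[-n])                 # x_{t+1} = y_t exactly
  r <- conditional_te(x, y, rep(0L, n))
  expect_gt(r$te_bits, 0.9)
  expect_lte(r$te_bits, 1 + 1e-12)
})

test_that("plug-in TE equals the brute-force entropy-difference oracle", {
  set.seed(29)
  for (rep in 1:50) {
    n <- sample(30:200, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    z <- rbinom(n, 1, runif(1, 0.2, 0.8))
    lag <- sample(0:3, 1)
    expect_equal(conditional_te(x, y, z, lag = lag)$te_bits,
                 te_oracle(x, y, z, lag = lag), tolerance = 1e-12)
  }
})

test_that("a constant conditioner reduces conditional TE to pairwise TE", {
  set.seed(301)
  for (rep in 1:10) {
    n <- 150
    y <- rbinom(n, 1, 0.5)
    x <- rbinom(n, 1, 0.5)
    take <- runif(n - 1) < 0.4
    x[-1][take] <- y[-n][take]
    cte <- conditional_te(x, y, rep(1L, n))$te_bits
    # pairwise TE from explicit tables (no conditioning variable at all)
    H <- function(...) {
      tab <- table(...)
      p <- as.vector(tab) / sum(tab)
      p <- p[p > 0]
      -sum(p * log2(p))
    }
    a <- x[-1]; b <- x[-n]; yy <- y[-n]
    pairwise <- (H(a, b) - H(b)) - (H(a, b, yy) - H(b, yy))
    expect_equal(cte, pairwise, tolerance = 1e-12)
  }
})

test_that("TE estimates are nonnegative across random inputs", {
  set.seed(83)
  for (rep in 1:30) {
    n <- sample(25:80, 1)
    r <- conditional_te(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                        rbinom(n, 1, 0.3))
    expect_gte(r$te_bits, -1e-12)
  }
})

test_that("conditioning exposes a chain as an indirect link", {
  tr <- generate_coupled_triad("chain", length = 5000, strength = 0.9,
                               seed = 44)
  uncond <- conditional_te(tr$x, tr$y, rep(0L, 5000))$te_bits
  cond <- conditional_te(tr$x, tr$y, tr$z)$te_bits
  expect_gt(uncond, 0.05)           # y -> z -> x leaks pairwise
  expect_lt(cond, uncond / 3)       # but mostly vanishes given z
})

test_that("local permutation shuffles only within (X_t, Z_t) strata", {
  # a source that is a deterministic function of the stratum pair is
  # invariant under within-stratum shuffling: every surrogate equals the
  # observed statistic and the p-value is exactly 1
  set.seed(12)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(x, z))
  r <- local_permutation_test(x, y, z, n_permutations = 200, seed = 3)
  expect_equal(r$p_value, 1)

  # a genuinely coupled source is detected
  tr <- generate_coupled_triad("y_to_x", length = 216, strength = 0.6,
                               seed = 21)
  r2 <- local_permutation_test(tr$x, tr$y, tr$z, n_permutations = 500,
                               seed = 5)
  expect_lt(r2$p_value, 0.05)
  expect_identical(
    local_permutation_test(tr$x, tr$y, tr$z, n_permutations = 200,
                           seed = 8)$te_bits,
    local_permutation_test(tr$x, tr$y, tr$z, n_permutations = 200,
                           seed = 8)$te_bits)
})

test_that("triad analysis fills all six directed links", {
  set.seed(77)
  series <- list(a = cumsum(rnorm(120)) + 10,
                 b = rnorm(120),
                 events = rpois(120, 0.5))
  plan <- list(a = list(rule = "change", detrend = TRUE),
               b = list(rule = "change"),
               events = list(rule = "event"))
  tab <- triad_analysis(series, plan, n_permutations = 100, seed = 2)
  expect_s3_class(tab, "te_table")
  expect_equal(nrow(tab), 6L)
  expect_equal(nrow(dplyr::distinct(tab, source, target)), 6L)
  expect_true(all(tab$source != tab$target))
  expect_true(all(tab$conditioner != tab$source &
                    tab$conditioner != tab$target))
  expect_true(all(tab$te_bits >= -1e-12))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
  expect_output(print(tab), "rows: sources")
})

test_that("lagged TE recovers a delayed coupling at the right delay", {
  set.seed(50)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 1, 0.5)
  delay <- 3L
  # x_{t+1} copies y_{t-3} most of the time
  idx <- (delay + 1):(n - 1)
  x[idx + 1] <- ifelse(runif(length(idx)) < 0.8, y[idx - delay], x[idx + 1])
  z <- rbinom(n, 1, 0.5)
  te_at <- vapply(0:5, function(l)
    conditional_te(x, y, z, lag = l)$te_bits, numeric(1))
  expect_equal(which.max(te_at) - 1L, delay)
  expect_gt(te_at[delay + 1], 10 * max(te_at[-(delay + 1)]))
})
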