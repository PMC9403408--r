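test_that("stacked design has the documented shape and masks", {
  panel <- toy_panel(n = 4, T = 3)
  d <- assemble_stack(panel, toy_Wseq(panel))
  expect_equal(length(d$Y), (3 - 1) * 4)
  expect_equal(ncol(d$Z), 11L)
  expect_equal(colnames(d$Z),
               c("Y_L", "WY_L", "X1_H", "X1_L", "X2_H", "X2_L", "WX1",
                 "WX2", "d", "i_H", "i_L"))
  isL <- rep(panel$response_class == "L", times = 2)
  expect_true(all(d$Z[isL, c("X1_H", "X2_H", "i_H")] == 0))
  expect_true(all(d$Z[!isL, c("X1_L", "X2_L", "i_L")] == 0))
  expect_true(all(abs(rowSums(do.call(rbind, d$Wblocks)) - 1) < 1e-12 |
                    rowSums(do.call(rbind, d$Wblocks)) == 0))
})

test_that("stack entries match hand assembly on a 2-unit, 2-year panel", {
  panel <- toy_panel(n = 2, T = 2)
  Wseq <- toy_Wseq(panel)
  d <- assemble_stack(panel, Wseq)
  W2 <- Wseq$matrices[[2]]
  # target year 2: response = survey October year 2; lag = survey year 1;
  # proxies = September (column 21) of year 2
  expect_equal(unname(d$Y), unname(panel$survey[, 2]))
  expect_equal(unname(d$Z[, "Y_L"]), unname(panel$survey[, 1]))
  expect_equal(unname(d$Z[, "WY_L"]),
               unname(drop(W2 %*% panel$survey[, 1])))
  sep <- panel$X1[, 21]
  expect_equal(unname(d$Z[, "X1_H"]),
               unname(sep * (panel$response_class == "H")))
  expect_equal(unname(d$Z[, "WX1"]), unname(drop(W2 %*% sep)))
  expect_equal(unname(d$Z[, "d"]), c(1, 1))
  expect_equal(unname(d$WY), unname(drop(W2 %*% panel$survey[, 2])))
})

test_that("missing anchors and short panels are rejected with names", {
  panel <- toy_panel(n = 2, T = 3)
  panel$survey[2, 2] <- NA
  expect_error(assemble_stack(panel, toy_Wseq(panel)), "U2.*2001")
})

test_that("log-likelihood at rho = 0 equals the Gaussian regression form", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:8, 1); T <- sample(3:5, 1)
    panel <- toy_panel(n = n, T = T, seed = rep)
    d <- assemble_stack(panel, toy_Wseq(panel))
    delta <- rnorm(11, sd = 0.3)
    sigma2 <- runif(1, 0.01, 0.5)
    e <- d$Y - drop(d$Z %*% delta)
    oracle <- sum(stats::dnorm(e, 0, sqrt(sigma2), log = TRUE))
    expect_equal(sdm_loglik(d, 0, delta, sigma2), oracle,
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood matches a scalar hand computation on 4 rows", {
  panel <- toy_panel(n = 2, T = 3, seed = 12)
  d <- assemble_stack(panel, toy_Wseq(panel))
  delta <- seq(0.01, 0.11, by = 0.01)
  rho <- 0.2; sigma2 <- 0.04
  e <- d$Y - rho * d$WY - drop(d$Z %*% delta)
  ld <- sum(log(abs(vapply(d$Wblocks, function(W)
    det(diag(2) - rho * W), numeric(1)))))
  by_hand <- -4 / 2 * log(2 * pi * sigma2) + ld - sum(e^2) / (2 * sigma2)
  expect_equal(sdm_loglik(d, rho, delta, sigma2), by_hand,
               tolerance = 1e-10)
})

test_that("closed-form sigma2 maximizes the profile likelihood", {
  panel <- toy_panel(n = 4, T = 4, seed = 6)
  d <- assemble_stack(panel, toy_Wseq(panel))
  delta <- rnorm(11, sd = 0.2)
  rho <- 0.1
  e <- d$Y - rho * d$WY - drop(d$Z %*% delta)
  s2_hat <- sum(e^2) / length(d$Y)
  ll_hat <- sdm_loglik(d, rho, delta, s2_hat)
  for (s2 in c(s2_hat / 3, s2_hat * 0.7, s2_hat * 1.5, s2_hat * 4))
    expect_lt(sdm_loglik(d, rho, delta, s2), ll_hat)
})

test_that("Monte-Carlo log-determinant approximates the dense value", {
  expect_equal(logdet_mc(random_W(7, seed = 1), rho = 0, n_draws = 3,
                         order = 5), 0)
  set.seed(31)
  for (rep in 1:5) {
    W <- random_W(sample(4:10, 1))
    for (rho in c(0.1, 0.3, 0.5)) {
      exact <- determinant(diag(nrow(W)) - rho * W, logarithm = TRUE)
      exact <- as.numeric(exact$modulus)
      est <- logdet_mc(W, rho, n_draws = 100, order = 50, seed = rep)
      expect_lt(abs(est - exact), max(abs(exact) * 0.01, 5e-4))
    }
  }
  # more probe vectors, less spread
  W <- random_W(8, seed = 5)
  few <- vapply(1:30, function(s) logdet_mc(W, 0.4, 5, 40, seed = s),
                numeric(1))
  many <- vapply(1:30, function(s) logdet_mc(W, 0.4, 200, 40, seed = s),
                 numeric(1))
  expect_lt(sd(many), sd(few))
})

test_that("null-W fit coincides with an independent least-squares oracle", {
  panel <- toy_panel(n = 6, T = 4, seed = 42)
  d <- assemble_stack(panel, null_W(6, 4))
  fit <- fit_sdm(d)
  keep <- colSums(abs(d$Z)) > 0            # drop the identically-zero W lags
  ols <- stats::lm.fit(d$Z[, keep], d$Y)$coefficients
  est <- fit$params
  expect_equal(est$rho, 0)
  # WY_L and the spatial proxy columns are identically zero under W = 0;
  # the remaining coefficients must match OLS exactly
  expect_equal(est$tau, unname(ols["Y_L"]), tolerance = 1e-8)
  expect_equal(est$phi1_H, unname(ols["X1_H"]), tolerance = 1e-8)
  expect_equal(est$phi2_L, unname(ols["X2_L"]), tolerance = 1e-8)
  expect_equal(est$gamma, unname(ols["d"]), tolerance = 1e-8)
  expect_equal(est$alpha_H, unname(ols["i_H"]), tolerance = 1e-8)
  res <- d$Y - drop(d$Z[, keep] %*% ols)
  expect_equal(est$sigma2, sum(res^2) / length(d$Y), tolerance = 1e-8)
})

test_that("maximum likelihood recovers generating parameters", {
  cfg <- scenario_config(n_units = 20L, n_years = 10L, n_low = 4L, seed = 19)
  sc <- generate_scenario(cfg)
  d <- assemble_stack(sc$panel, sc$Wseq)
  fit <- fit_sdm(d)
  expect_true(fit$converged)
  z <- (unlist(fit$params)[1:12] - unlist(sc$truth)[1:12]) / fit$se[1:12]
  expect_true(all(abs(z) < 4))
  # the optimum cannot lie below the truth's likelihood
  truth_delta <- unlist(sc$truth)[c("tau", "eta", "phi1_H", "phi1_L",
                                    "phi2_H", "phi2_L", "psi1", "psi2",
                                    "gamma", "alpha_H", "alpha_L")]
  ll_truth <- sdm_loglik(d, sc$truth$rho, truth_delta, sc$truth$sigma2)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("tidy and glance expose broom-style summaries", {
  panel <- toy_panel(n = 5, T = 4, seed = 2)
  fit <- fit_sdm(assemble_stack(panel, toy_Wseq(panel)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 13L)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$nobs, 15L)
})
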