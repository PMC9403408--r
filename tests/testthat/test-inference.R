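test_that("intercept-only model with matching anchors predicts a constant", {
  n <- 3; T <- 3
  cst <- 0.42
  panel <- toy_panel(n = n, T = T)
  panel$survey[] <- cst
  p <- model_params(alpha_H = cst, alpha_L = cst)
  pred <- predict_monthly(p, panel, null_W(n, T), national = FALSE)
  expect_true(all(abs(pred$monthly - cst) < 1e-12))
})

test_that("prediction matches a step-by-step hand recursion with the anchor switch", {
  n <- 2; T <- 3
  set.seed(33)
  panel <- toy_panel(n = n, T = T, seed = 33)
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  Wseq <- weight_sequence(replicate(T, W, simplify = FALSE), panel$years)
  p <- model_params(rho = 0.2, tau = 0.1, eta = 0.05, phi1_H = 10,
                    phi1_L = 20, phi2_H = 0.5, phi2_L = 0.25, psi1 = -30,
                    psi2 = 0.8, gamma = 0.01, alpha_H = -0.1,
                    alpha_L = -0.05)
  pred <- predict_monthly(p, panel, Wseq, national = FALSE)

  # independent recursion, written out month by month
  isH <- panel$response_class == "H"
  A <- solve(diag(2) - 0.2 * W)
  Yhand <- matrix(NA_real_, n, panel$M)
  for (m in seq_len(panel$M)) {
    y <- (m - 1) %/% 12 + 1
    mon <- (m - 1) %% 12 + 1
    ylag <- if (mon == 10) {
      if (y == 1) panel$survey[, 1] else panel$survey[, y - 1]
    } else if (m > 12) Yhand[, m - 12] else panel$survey[, 1]
    x1 <- panel$X1[, max(m - 1, 1)]
    x2 <- panel$X2[, max(m - 1, 1)]
    rhs <- 0.1 * ylag + 0.05 * W %*% ylag +
      ifelse(isH, 10, 20) * x1 + ifelse(isH, 0.5, 0.25) * x2 +
      (-30) * W %*% x1 + 0.8 * W %*% x2 + 0.01 * (y - 1) +
      ifelse(isH, -0.1, -0.05)
    Yhand[, m] <- A %*% rhs
  }
  expect_equal(unname(pred$monthly), Yhand, tolerance = 1e-12)
})

test_that("anchor bookkeeping records one survey anchor per year", {
  panel <- toy_panel(n = 2, T = 4)
  pred <- predict_monthly(model_params(), panel, null_W(2, 4),
                          national = FALSE)
  expect_equal(nrow(pred$anchors_used), 4L)
  expect_true(all(pred$anchors_used$source == "survey"))

  panel$survey[1, 2] <- NA
  expect_warning(
    pred2 <- predict_monthly(model_params(), panel, null_W(2, 4),
                             national = FALSE),
    "falling back to model output")
  expect_equal(pred2$anchors_used$source, c("survey", "survey", "model",
                                            "survey"))
})

test_that("noiseless prediction reproduces the model's own simulation", {
  cfg <- scenario_config(n_units = 10L, n_years = 5L, n_low = 3L,
                         seed = 55)
  cfg$true_params$sigma2 <- 0
  sc <- generate_scenario(cfg)
  sim <- simulate_panel(sc$truth, sc$Wseq, sc$panel$X1, sc$panel$X2,
                        sc$Y_init, sc$panel$response_class)
  expect_equal(unname(sc$panel$survey), unname(sim$octobers),
               tolerance = 1e-12)
  pred <- predict_monthly(sc$truth, sc$panel, sc$Wseq, national = FALSE)
  expect_lt(max(abs(pred$monthly - sim$Y)), 1e-10)
  ev <- evaluate_fit(pred, sc$panel$survey)
  expect_equal(ev$sse, 0, tolerance = 1e-18)
  expect_equal(ev$mse, 0, tolerance = 1e-18)

  full <- predict_monthly(sc$truth, sc$panel, sc$Wseq)
  expect_length(full$national, sc$panel$M)
  expect_s3_class(ggplot2::autoplot(full, panel = sc$panel), "ggplot")
  expect_equal(nrow(as_tibble(full)), sc$panel$n * sc$panel$M)
})

test_that("squared-error summaries follow their definitions", {
  Y <- matrix(0.5, 1, 240)
  survey <- matrix(0.5, 1, 20)
  ev <- evaluate_fit(Y, survey)
  expect_equal(ev$sse, 0)

  survey2 <- matrix(0.6, 1, 20)          # constant error 0.1 over 20 years
  ev2 <- evaluate_fit(Y, survey2)
  expect_equal(ev2$sse, 0.2, tolerance = 1e-12)
  expect_equal(ev2$mse, 0.01, tolerance = 1e-12)
  expect_equal(ev2$mse, ev2$sse / 20)
  expect_equal(ev2$n_compared, 20L)
})

test_that("national aggregation pools counts, not state outputs", {
  # hand arithmetic on a 2-unit toy: national rate = (c1+c2)/(p1+p2)
  panel <- toy_panel(n = 2, T = 2, seed = 71)
  pops <- panel$populations
  m <- 5
  y <- 1
  c1 <- panel$X1[1, m] * pops[1, y]
  c2 <- panel$X1[2, m] * pops[2, y]
  expected_rate <- (c1 + c2) / (pops[1, y] + pops[2, y])

  p <- model_params(phi1_H = 1, alpha_H = 0)
  nat <- national_aggregate(panel, p)
  # the month-6 national value is phi1 * national rate of month 5
  expect_equal(nat[m + 1], unname(expected_rate), tolerance = 1e-12)

  # single-unit panel: national series equals the unit's own prediction
  single <- state_panel(units = "U1", years = panel$years,
                        X1 = panel$X1[1, , drop = FALSE],
                        X2 = panel$X2[1, , drop = FALSE],
                        survey = panel$survey[1, , drop = FALSE],
                        populations = pops[1, , drop = FALSE],
                        centroids = panel$centroids[1, ],
                        response_class = "H")
  p2 <- model_params(tau = 0.2, phi1_H = 8, phi2_H = 0.4, gamma = 0.01,
                     alpha_H = -0.2)
  pred <- predict_monthly(p2, single, null_W(1, 2))
  expect_equal(unname(drop(pred$monthly)), pred$national, tolerance = 1e-12)

  # two identical units with spatially trivial parameters
  twin <- state_panel(units = c("U1", "U2"), years = panel$years,
                      X1 = panel$X1[c(1, 1), ], X2 = panel$X2[c(1, 1), ],
                      survey = panel$survey[c(1, 1), ],
                      populations = pops[c(1, 1), ],
                      centroids = tibble::tibble(unit = c("U1", "U2"),
                                                 lat = c(30, 40),
                                                 lon = c(-100, -90)),
                      response_class = c("H", "H"))
  pred2 <- predict_monthly(p2, twin, null_W(2, 2))
  expect_equal(unname(pred2$monthly[1, ]), pred2$national,
               tolerance = 1e-12)
})

test_that("predictions are invariant to unit reordering", {
  panel <- toy_panel(n = 4, T = 3, seed = 13)
  Wseq <- toy_Wseq(panel)
  p <- model_params(rho = 0.15, tau = 0.05, phi1_H = 10, phi1_L = 15,
                    phi2_H = 0.4, phi2_L = 0.2, psi1 = -20, psi2 = 0.9,
                    gamma = 0.01, alpha_H = -0.1, alpha_L = -0.1)
  pred <- predict_monthly(p, panel, Wseq, national = FALSE)

  ord <- c(3, 1, 4, 2)
  panel2 <- state_panel(units = panel$units[ord], years = panel$years,
                        X1 = panel$X1[ord, ], X2 = panel$X2[ord, ],
                        survey = panel$survey[ord, ],
                        populations = panel$populations[ord, ],
                        centroids = panel$centroids[ord, ],
                        response_class = panel$response_class[ord])
  pred2 <- predict_monthly(p, panel2, toy_Wseq(panel2), national = FALSE)
  expect_equal(unname(pred2$monthly[order(ord), ]),
               unname(pred$monthly), tolerance = 1e-10)
})
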