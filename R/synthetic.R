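#' Configuration for a synthetic study scenario
#'
#' Defines the conditions a generated dataset emulates: the panel scale
#' (48 units over 20 years by default, matching the real study window), the
#' generating model parameters (defaulting to the calibrated operating
#' point: `rho = 0.163`, `sigma2 = 0.031`, proxy coefficients of realistic
#' magnitude), strong period-12 seasonality in background checks per
#' capita, a slow trend in the suicide fraction, a designated subset of
#' low-response units with single-digit respondent counts, sporadic monthly
#' event counts, and log-normal media output optionally coupled to events.
#'
#' @param n_units Number of spatial units (>= 2).
#' @param n_years Number of whole years (>= 3).
#' @param true_params Generating [model_params].
#' @param x1_mean Mean background checks per capita (checks/person/month).
#' @param x1_season_amp Relative seasonal amplitude of X1 (peak in winter).
#' @param x1_noise_cv Coefficient of variation of multiplicative X1 noise.
#' @param x2_level Mean fraction of suicides with firearms.
#' @param x2_trend_per_year Linear drift of X2 per year.
#' @param x2_noise_sd Additive X2 noise standard deviation.
#' @param n_low Number of low-response units.
#' @param respondents_H,respondents_L Integer ranges (length-2) for annual
#'   respondent counts in high/low-response units.
#' @param survey_sampling `"exact"` (anchors equal simulated ownership) or
#'   `"binomial"` (anchors are binomial survey fractions given the
#'   respondent counts).
#' @param event_rate Mean mass-shooting events per month (Poisson).
#' @param media_noise_scale Log-scale sd of the media-output series.
#' @param media_event_coupling Multiplicative lift of media output in the
#'   month after an event (0 = uncoupled).
#' @param seed Integer root seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_units = 48L, n_years = 20L,
                            true_params = model_params(
                              rho = 0.1630, tau = 0.0034, eta = -0.0493,
                              phi1_H = 18.1596, phi1_L = 36.5954,
                              phi2_H = 0.5285, phi2_L = 0.2741,
                              psi1 = -70.2457, psi2 = 1.5989,
                              gamma = 0.0104, alpha_H = -0.6225,
                              alpha_L = -0.5080, sigma2 = 0.0310),
                            x1_mean = 0.004, x1_season_amp = 0.35,
                            x1_noise_cv = 0.10,
                            x2_level = 0.58, x2_trend_per_year = -0.002,
                            x2_noise_sd = 0.02,
                            n_low = 8L,
                            respondents_H = c(15L, 60L),
                            respondents_L = c(1L, 12L),
                            survey_sampling = c("exact", "binomial"),
                            event_rate = 0.6, media_noise_scale = 0.5,
                            media_event_coupling = 0.5, seed = 1L) {
  if (n_units < 2L) stop("need at least 2 units", call. = FALSE)
  if (n_years < 3L) stop("need at least 3 years", call. = FALSE)
  if (n_low < 1L || n_low >= n_units)
    stop("n_low must leave at least one high-response unit", call. = FALSE)
  stopifnot(inherits(true_params, "model_params"))
  structure(list(
    n_units = as.integer(n_units), n_years = as.integer(n_years),
    true_params = true_params, x1_mean = x1_mean,
    x1_season_amp = x1_season_amp, x1_noise_cv = x1_noise_cv,
    x2_level = x2_level, x2_trend_per_year = x2_trend_per_year,
    x2_noise_sd = x2_noise_sd, n_low = as.integer(n_low),
    respondents_H = respondents_H, respondents_L = respondents_L,
    survey_sampling = match.arg(survey_sampling),
    event_rate = event_rate, media_noise_scale = media_noise_scale,
    media_event_coupling = media_event_coupling, seed = as.integer(seed)),
    class = "scenario_config")
}

# burn-in consistent with October anchoring: fixed point of the first
# October map, so a noiseless simulation reproduces its own anchors
fixed_point_Y_init <- function(params, Wseq, X1, X2, response_class,
                               iters = 200L, tol = 1e-13) {
  n <- nrow(X1)
  W1 <- W_for_year(Wseq, 1L)
  y <- rep(0.3, n)
  for (i in seq_len(iters)) {
    rhs <- monthly_rhs(params, W1, y, X1[, 9L], X2[, 9L], 0L,
                       response_class, W_x = W1)
    y_new <- solve_contemporaneous(params, W1, rhs)
    if (max(abs(y_new - y)) < tol) {
      y <- y_new
      break
    }
    y <- y_new
  }
  matrix(y, n, 12L)
}

#' Generate a complete synthetic study dataset
#'
#' Draws unit centroids (jittered grid), yearly populations, proxy series
#' with the configured seasonality/trend/noise, simulates ownership through
#' the forward model ([simulate_panel()]), converts October columns into
#' survey anchors (exact, or with binomial sampling noise from the
#' respondent counts), and generates monthly mass-shooting counts (Poisson)
#' and a media-output series (log-normal, optionally lifted after events).
#' Fully reproducible from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return List with `panel` (a validated [state_panel]), `Wseq`, `truth`
#'   (the generating [model_params]), `ownership` (the `n x M` simulated
#'   path), `Y_init`, and `series` (tibble with `shootings` counts and
#'   `media` output per month).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_units
  T_years <- config$n_years
  M <- 12L * T_years
  years <- seq.int(2000L, length.out = T_years)
  set.seed(config$seed)

  units <- sprintf("S%02d", seq_len(n))
  # jittered grid over a continental-scale footprint
  ncol_g <- ceiling(sqrt(n))
  gx <- (seq_len(n) - 1L) %% ncol_g
  gy <- (seq_len(n) - 1L) %/% ncol_g
  centroids <- tibble::tibble(
    unit = units,
    lat = 30 + 15 * gy / max(gy, 1) + stats::runif(n, -0.5, 0.5),
    lon = -120 + 45 * gx / max(gx, 1) + stats::runif(n, -0.5, 0.5))

  pop0 <- stats::rlnorm(n, meanlog = log(3e6), sdlog = 0.9)
  growth <- 1 + stats::runif(n, 0, 0.015)
  populations <- sapply(seq_len(T_years) - 1L, function(t) pop0 * growth^t)

  # X1: strong winter-peaking seasonality, multiplicative noise
  base1 <- config$x1_mean * exp(stats::rnorm(n, 0, 0.15))
  month_of <- rep(1:12, T_years)
  seas <- 1 + config$x1_season_amp * cos(2 * pi * (month_of - 12) / 12)
  X1 <- outer(base1, seas) *
    matrix(exp(stats::rnorm(n * M, 0, config$x1_noise_cv)), n, M)

  # X2: unit level + slow linear drift + noise, kept inside [0, 1]
  lev2 <- config$x2_level + stats::rnorm(n, 0, 0.04)
  yr_frac <- (seq_len(M) - 1) / 12
  X2 <- outer(lev2, rep(1, M)) +
    config$x2_trend_per_year * matrix(rep(yr_frac, each = n), n, M) +
    matrix(stats::rnorm(n * M, 0, config$x2_noise_sd), n, M)
  X2 <- pmin(pmax(X2, 0), 1)

  low_units <- sample.int(n, config$n_low)
  response_class <- rep("H", n)
  response_class[low_units] <- "L"
  respondents <- matrix(0L, n, T_years)
  respondents[response_class == "H", ] <-
    sample(config$respondents_H[1]:config$respondents_H[2],
           sum(response_class == "H") * T_years, replace = TRUE)
  respondents[response_class == "L", ] <-
    sample(config$respondents_L[1]:config$respondents_L[2],
           sum(response_class == "L") * T_years, replace = TRUE)
  # guarantee every L unit has a sub-threshold year so the derived
  # classification matches the one used to simulate
  respondents[low_units, 1L] <- pmin(respondents[low_units, 1L], 9L)

  Wseq <- build_population_distance_W(populations,
                                      pairwise_distance(centroids), years)
  Y_init <- fixed_point_Y_init(config$true_params, Wseq, X1, X2,
                               response_class)
  sim_seed <- config$seed + 1000003L
  sim <- simulate_panel(config$true_params, Wseq, X1, X2, Y_init,
                        response_class, seed = sim_seed)

  truth_oct <- pmin(pmax(sim$octobers, 0), 1)
  if (config$survey_sampling == "binomial") {
    set.seed(config$seed + 2000003L)
    survey <- matrix(stats::rbinom(n * T_years, as.vector(respondents),
                                   as.vector(truth_oct)) /
                       as.vector(respondents), n, T_years)
  } else {
    survey <- truth_oct
  }

  set.seed(config$seed + 3000017L)
  shootings <- stats::rpois(M, config$event_rate)
  media <- exp(stats::rnorm(M, 0, config$media_noise_scale)) *
    (1 + config$media_event_coupling *
       c(0, as.numeric(shootings[-M] >= 1)))

  panel <- state_panel(units = units, years = years, X1 = X1, X2 = X2,
                       survey = survey, populations = populations,
                       centroids = centroids, respondents = respondents)
  list(panel = panel, Wseq = Wseq, truth = config$true_params,
       ownership = sim$Y, Y_init = Y_init,
       series = tibble::tibble(year = rep(years, each = 12L),
                               month = month_of,
                               shootings = shootings, media = media))
}

#' Generate a triad of series with a known directed coupling
#'
#' Test harness for the transfer-entropy pipeline: three binary series of a
#' given length with an optional lag-1 coupling of known strength.
#' `"none"` gives mutually independent fair-coin series; `"y_to_x"` copies
#' `y_t` into `x_{t+1}` with probability `strength` (a pure copy process at
#' `strength = 1`, with analytic TE equal to the source entropy);
#' `"x_to_y"` is the reverse; `"chain"` couples `y -> z -> x`, so the
#' unconditional TE from y to x is positive but vanishes once conditioned
#' on z (a confounding demonstration).
#'
#' @param coupling One of `"none"`, `"y_to_x"`, `"x_to_y"`, `"chain"`.
#' @param length Series length (>= 50).
#' @param strength Coupling probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named list of integer 0/1 vectors `x`, `y`, `z`.
#' @export
generate_coupled_triad <- function(coupling = c("none", "y_to_x", "x_to_y",
                                                "chain"),
                                   length = 216L, strength = 0.5,
                                   seed = 1L) {
  coupling <- match.arg(coupling)
  if (length < 50L) stop("length must be >= 50", call. = FALSE)
  if (strength < 0 || strength > 1)
    stop("strength must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  coin <- function() stats::rbinom(length, 1L, 0.5)
  drive <- function(src) {
    out <- coin()
    take <- stats::runif(length - 1L) < strength
    out[-1L][take] <- src[-length][take]
    out
  }
  x <- coin(); y <- coin(); z <- coin()
  if (coupling == "y_to_x") x <- drive(y)
  if (coupling == "x_to_y") y <- drive(x)
  if (coupling == "chain") {
    # a persistent source makes the two-step path y -> z -> x visible at
    # unit lag, the classic spurious pairwise link removed by conditioning
    flips <- stats::rbinom(length - 1L, 1L, 0.2)
    y <- as.integer(cumsum(c(y[1L], flips)) %% 2L)
    z <- drive(y)
    x <- drive(z)
  }
  list(x = as.integer(x), y = as.integer(y), z = as.integer(z))
}
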