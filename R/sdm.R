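#' Parameters of the extended spatial Durbin ownership model
#'
#' The model predicts the fraction of firearm owners `Y_m` in each unit and
#' month from: a contemporaneous spatial lag `rho * W_m Y_m`, twelve-month
#' memory `tau * Y_{m-12}` and spatial memory `eta * W_m Y_{m-12}`,
#' previous-month proxies split by survey-response class
#' (`phi1_H/phi1_L` for background checks per capita, `phi2_H/phi2_L` for the
#' fraction of suicides with firearms), spatially lagged proxies
#' (`psi1`, `psi2`, unsplit), a linear year trend `gamma * d`, class
#' intercepts `alpha_H/alpha_L`, and Gaussian noise with variance `sigma2`.
#'
#' @param rho Contemporaneous spatial autoregression (dimensionless; must lie
#'   inside the spectral bounds of the weight matrix in use).
#' @param tau,eta Twelve-month own and spatial memory coefficients.
#' @param phi1_H,phi1_L Background-checks-per-capita coefficients
#'   (per check/person/month) for high/low-response units.
#' @param phi2_H,phi2_L Suicide-fraction coefficients (dimensionless).
#' @param psi1,psi2 Spatial-lag proxy coefficients (unsplit).
#' @param gamma Linear trend per year index (year 1 coded 0).
#' @param alpha_H,alpha_L Class intercepts.
#' @param sigma2 Noise variance (>= 0).
#' @return An object of class `model_params` (named list of 13 scalars).
#' @export
model_params <- function(rho = 0, tau = 0, eta = 0,
                         phi1_H = 0, phi1_L = 0, phi2_H = 0, phi2_L = 0,
                         psi1 = 0, psi2 = 0, gamma = 0,
                         alpha_H = 0, alpha_L = 0, sigma2 = 0) {
  p <- list(rho = rho, tau = tau, eta = eta, phi1_H = phi1_H,
            phi1_L = phi1_L, phi2_H = phi2_H, phi2_L = phi2_L,
            psi1 = psi1, psi2 = psi2, gamma = gamma,
            alpha_H = alpha_H, alpha_L = alpha_L, sigma2 = sigma2)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                            is.finite(v), logical(1))]
  if (length(bad))
    stop("non-finite scalar parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  v <- unlist(x)
  cat("<model_params>\n")
  print(round(v, 4))
  invisible(x)
}

# eigenvalues (possibly complex) of every per-year weight matrix, pooled
weight_eigenvalues <- function(Wseq) {
  unlist(lapply(Wseq$matrices, function(W)
    eigen(W, only.values = TRUE)$values))
}

#' Admissible interval for the spatial autoregressive parameter
#'
#' `rho` must keep `I - rho * W` nonsingular along the real-eigenvalue axis:
#' the open interval `(1/min(omega), 1/max(omega))` over the real eigenvalues
#' `omega` of the weight matrices (for a row-stochastic W the upper bound
#' is 1). The null sequence `W = 0` places no constraint.
#'
#' @param Wseq A [weight_sequence].
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
rho_bounds <- function(Wseq) {
  if (Wseq$null_flag) return(c(-Inf, Inf))
  ev <- weight_eigenvalues(Wseq)
  re <- Re(ev[abs(Im(ev)) < 1e-8])
  lo <- if (any(re < 0)) 1 / min(re) else -Inf
  hi <- if (any(re > 0)) 1 / max(re) else Inf
  c(lo, hi)
}

check_rho <- function(rho, Wseq) {
  b <- rho_bounds(Wseq)
  if (!(rho > b[1] && rho < b[2]))
    stop(sprintf("rho = %.4f outside spectral bounds (%.4f, %.4f)",
                 rho, b[1], b[2]), call. = FALSE)
  invisible(b)
}

#' Right-hand side of the monthly ownership recursion
#'
#' Evaluates every term of the model except the contemporaneous spatial lag
#' `rho * W Y_m` and the noise: own and spatial 12-month memory, split
#' previous-month proxy terms (H/L coefficients applied only to units of the
#' matching class), unsplit spatial proxy lags, year trend, and class
#' intercepts.
#'
#' @param params A [model_params].
#' @param W `n x n` weight matrix for the current month.
#' @param Y_lag12 Ownership vector 12 months prior.
#' @param X1_lag1,X2_lag1 Previous-month proxy vectors.
#' @param year_dummy Integer year index (first modeled year = 0).
#' @param response_class Length-`n` labels in `{"H","L"}`.
#' @param W_x Weight matrix paired with the lagged proxies (defaults to `W`;
#'   differs only across January boundaries since W is constant within a
#'   year).
#' @return Length-`n` numeric vector.
#' @export
monthly_rhs <- function(params, W, Y_lag12, X1_lag1, X2_lag1, year_dummy,
                        response_class, W_x = W) {
  n <- length(Y_lag12)
  if (!all(dim(W) == c(n, n)) || length(X1_lag1) != n ||
      length(X2_lag1) != n || length(response_class) != n)
    stop("dimension mismatch in monthly_rhs", call. = FALSE)
  isH <- as.numeric(response_class == "H")
  isL <- 1 - isH
  drop(params$tau * Y_lag12 + params$eta * (W %*% Y_lag12) +
    (params$phi1_H * isH + params$phi1_L * isL) * X1_lag1 +
    (params$phi2_H * isH + params$phi2_L * isL) * X2_lag1 +
    params$psi1 * (W_x %*% X1_lag1) + params$psi2 * (W_x %*% X2_lag1) +
    params$gamma * year_dummy + params$alpha_H * isH + params$alpha_L * isL)
}

#' Solve the contemporaneous spatial system
#'
#' Returns `(I - rho W)^{-1} rhs`, the reduced form of the implicit
#' `rho W Y_m` term.
#'
#' @param params A [model_params] (only `rho` is used).
#' @param W `n x n` weight matrix.
#' @param rhs Length-`n` right-hand side.
#' @return Length-`n` numeric vector.
#' @export
solve_contemporaneous <- function(params, W, rhs) {
  n <- length(rhs)
  A <- diag(n) - params$rho * W
  out <- tryCatch(solve(A, rhs), error = function(e) {
    ev <- eigen(W, only.values = TRUE)$values
    re <- Re(ev[abs(Im(ev)) < 1e-8])
    stop(sprintf(
      "singular system: rho = %.4f with spectral bounds (%.4f, %.4f)",
      params$rho, if (any(re < 0)) 1 / min(re) else -Inf,
      if (any(re > 0)) 1 / max(re) else Inf), call. = FALSE)
  })
  drop(out)
}

#' Simulate an ownership panel from the model (forward generator)
#'
#' Iterates the monthly recursion over `M = 12 T` months: each month's
#' right-hand side ([monthly_rhs()]) plus Gaussian noise is pushed through
#' the contemporaneous solve. The first modeled year's 12-month lags come
#' from `Y_init` (the burn-in year, conventionally a copy of the first
#' survey year's values). October columns are extracted as synthetic survey
#' anchors.
#'
#' @param params A [model_params].
#' @param Wseq A [weight_sequence] covering the modeled years.
#' @param X1,X2 `n x M` proxy matrices for the modeled months.
#' @param Y_init `n x 12` burn-in ownership (months of the year preceding the
#'   first modeled year).
#' @param response_class Length-`n` labels in `{"H","L"}`.
#' @param seed Integer seed for the noise (ignored when `sigma2 = 0`).
#' @param X1_0,X2_0 Proxy vectors for the December preceding month 1
#'   (default: carry back the first modeled month).
#' @return List with `Y` (`n x M` simulated ownership), `octobers`
#'   (`n x T` October extract), and `months` (calendar tibble).
#' @export
simulate_panel <- function(params, Wseq, X1, X2, Y_init, response_class,
                           seed = 1L, X1_0 = X1[, 1], X2_0 = X2[, 1]) {
  n <- nrow(X1)
  M <- ncol(X1)
  if (M %% 12L != 0L) stop("X series must cover whole years", call. = FALSE)
  T_years <- M %/% 12L
  if (length(Wseq$matrices) < T_years)
    stop("weight sequence shorter than the simulated span", call. = FALSE)
  if (!all(dim(Y_init) == c(n, 12L)))
    stop("Y_init must be n x 12", call. = FALSE)
  check_rho(params$rho, Wseq)

  noise <- matrix(0, n, M)
  if (params$sigma2 > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(n * M, sd = sqrt(params$sigma2)), n, M)
  }
  Y <- matrix(NA_real_, n, M, dimnames = list(rownames(X1), NULL))
  for (m in seq_len(M)) {
    y <- (m - 1L) %/% 12L + 1L
    W <- W_for_year(Wseq, y)
    W_x <- W_for_year(Wseq, (m - 2L) %/% 12L + 1L)  # W of month m-1
    Y_lag <- if (m > 12L) Y[, m - 12L] else Y_init[, m]
    x1 <- if (m > 1L) X1[, m - 1L] else X1_0
    x2 <- if (m > 1L) X2[, m - 1L] else X2_0
    rhs <- monthly_rhs(params, W, Y_lag, x1, x2, y - 1L, response_class,
                       W_x = W_x)
    Y[, m] <- solve_contemporaneous(params, W, rhs + noise[, m])
  }
  oct <- Y[, october_col(seq_len(T_years)), drop = FALSE]
  list(Y = Y, octobers = oct,
       months = tibble::tibble(year_index = rep(seq_len(T_years), each = 12L),
                               month = rep(1:12, T_years)))
}
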