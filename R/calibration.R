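#' Stack October observations into the estimation form
#'
#' Calibration is limited by the survey's resolution: ownership is observed
#' only each October. The monthly model evaluated at those months stacks into
#' `Y = rho W Y + Z delta + eps` with one block per target year (years
#' 2..T; the lag block is the previous October's survey values). The 11
#' columns of `Z` are, in order: `Y_L`, `WY_L`, `X1_H`, `X1_L`, `X2_H`,
#' `X2_L`, `WX1`, `WX2`, `d`, `i_H`, `i_L`, where the proxy columns take
#' September values of the target year, split by response class for the
#' direct terms and unsplit for the spatial lags.
#'
#' @param panel A [state_panel] with at least 2 survey years and no missing
#'   anchors.
#' @param Wseq A [weight_sequence] with one matrix per panel year.
#' @return An object of class `sdm_stack` with fields `Y`, `Z`, `WY`,
#'   `Wblocks`, `omega` (pooled block eigenvalues), `n`, `T`, `null_flag`.
#' @export
assemble_stack <- function(panel, Wseq) {
  n <- panel$n
  T_years <- panel$T
  if (T_years < 2L) stop("need at least 2 survey years", call. = FALSE)
  if (length(Wseq$matrices) != T_years)
    stop("weight sequence must have one matrix per panel year", call. = FALSE)
  na <- which(is.na(panel$survey), arr.ind = TRUE)
  if (nrow(na))
    stop(sprintf("missing survey anchor for unit %s, year %d",
                 panel$units[na[1, 1]], panel$years[na[1, 2]]), call. = FALSE)
  isH <- as.numeric(panel$response_class == "H")
  isL <- 1 - isH

  blocks <- vector("list", T_years - 1L)
  rows <- vector("list", T_years - 1L)
  Yv <- WYv <- vector("list", T_years - 1L)
  for (k in seq_len(T_years - 1L)) {
    y <- k + 1L                      # target year index
    W <- Wseq$matrices[[y]]
    m_oct <- october_col(y)
    y_t <- panel$survey[, y]
    y_lag <- panel$survey[, y - 1L]
    x1 <- panel$X1[, m_oct - 1L]     # September of the target year
    x2 <- panel$X2[, m_oct - 1L]
    Z_k <- cbind(Y_L = y_lag,
                 WY_L = drop(W %*% y_lag),
                 X1_H = x1 * isH, X1_L = x1 * isL,
                 X2_H = x2 * isH, X2_L = x2 * isL,
                 WX1 = drop(W %*% x1), WX2 = drop(W %*% x2),
                 d = rep(y - 1L, n), i_H = isH, i_L = isL)
    blocks[[k]] <- W
    rows[[k]] <- Z_k
    Yv[[k]] <- y_t
    WYv[[k]] <- drop(W %*% y_t)
  }
  structure(
    list(Y = unlist(Yv), Z = do.call(rbind, rows), WY = unlist(WYv),
         Wblocks = blocks,
         omega = unlist(lapply(blocks, function(W)
           eigen(W, only.values = TRUE)$values)),
         n = n, T = T_years, null_flag = Wseq$null_flag,
         units = panel$units, target_years = panel$years[-1L]),
    class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d rows ((T-1) x n = %d x %d), 11 regressors%s\n",
              length(x$Y), x$T - 1L, x$n,
              if (x$null_flag) ", null W" else ""))
  invisible(x)
}

stack_rho_bounds <- function(design) {
  if (design$null_flag) return(c(-Inf, Inf))
  re <- Re(design$omega[abs(Im(design$omega)) < 1e-8])
  c(if (any(re < 0)) 1 / min(re) else -Inf,
    if (any(re > 0)) 1 / max(re) else Inf)
}

# exact ln|I - rho W| from the pooled block eigenvalues
logdet_eigen <- function(omega, rho) {
  if (!length(omega)) return(0)
  sum(Re(log(1 - rho * omega)))
}

#' Log-likelihood of the stacked spatial model
#'
#' For residuals `e = Y - rho W Y - Z delta` over `N = (T-1) n` stacked
#' observations the Gaussian log-likelihood is
#' `-(N/2) ln(2 pi sigma2) + ln|I - rho W| - e'e / (2 sigma2)`.
#' The log-determinant (the Jacobian of the spatial transformation) is
#' computed exactly from the block eigenvalues, or by the Monte-Carlo trace
#' estimator ([logdet_mc()]).
#'
#' @param design An [assemble_stack()] result.
#' @param rho Spatial autoregressive parameter, strictly inside the spectral
#'   bounds.
#' @param delta Length-11 coefficient vector (column order of `design$Z`).
#' @param sigma2 Noise variance (> 0).
#' @param logdet_method `"exact"` or `"mc"`.
#' @param n_draws,order,seed Monte-Carlo settings when `logdet_method="mc"`.
#' @return Scalar log-likelihood.
#' @export
sdm_loglik <- function(design, rho, delta, sigma2,
                       logdet_method = c("exact", "mc"),
                       n_draws = 100L, order = 50L, seed = 1L) {
  logdet_method <- match.arg(logdet_method)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  b <- stack_rho_bounds(design)
  if (!(rho > b[1] && rho < b[2]))
    stop(sprintf("rho = %.4f at or beyond spectral bounds (%.4f, %.4f)",
                 rho, b[1], b[2]), call. = FALSE)
  N <- length(design$Y)
  e <- design$Y - rho * design$WY - drop(design$Z %*% delta)
  ld <- if (design$null_flag) 0
        else if (logdet_method == "exact") logdet_eigen(design$omega, rho)
        else sum(vapply(design$Wblocks, logdet_mc, numeric(1), rho = rho,
                        n_draws = n_draws, order = order, seed = seed))
  -N / 2 * log(2 * pi * sigma2) + ld - sum(e^2) / (2 * sigma2)
}

#' Monte-Carlo estimate of the spatial log-determinant
#'
#' Barry-Pace style estimator of `ln|I - rho W|` from the truncated trace
#' series `-sum_k rho^k tr(W^k) / k`, with each trace estimated by random
#' Gaussian probe vectors. The trace is split as
#' `tr(W^k) = tr(W^k P) + 1'W^k 1 / n` with `P` the projector off the
#' constant vector: the second piece is computed exactly by power
#' iteration, and only the complement is probed. For a row-stochastic `W`
#' the constant vector is the Perron direction, so this deflation removes
#' almost all of the estimator variance. Useful when `n` is too large for a
#' dense eigendecomposition.
#'
#' @param Wblock `n x n` weight matrix.
#' @param rho Spatial parameter inside the spectral bounds.
#' @param n_draws Number of random probe vectors (>= 1).
#' @param order Truncation order of the power series (>= 1).
#' @param seed Integer seed (reproducible).
#' @return Scalar estimate of `ln|I - rho W|`.
#' @export
logdet_mc <- function(Wblock, rho, n_draws = 100L, order = 50L, seed = 1L) {
  stopifnot(n_draws >= 1L, order >= 1L)
  n <- nrow(Wblock)
  set.seed(seed)
  # exact component along the constant direction: 1'W^k 1 / n
  exact_const <- numeric(order)
  u <- rep(1, n)
  for (k in seq_len(order)) {
    u <- drop(Wblock %*% u)
    exact_const[k] <- mean(u)
  }
  acc <- numeric(order)
  for (d in seq_len(n_draws)) {
    x <- stats::rnorm(n)
    x <- x - mean(x)                 # probe the complement of constants
    xx <- sum(x * x)
    v <- x
    for (k in seq_len(order)) {
      v <- drop(Wblock %*% v)
      acc[k] <- acc[k] + (n - 1) * sum(x * v) / xx
    }
  }
  traces <- exact_const + acc / n_draws
  # the first two traces are cheap to compute exactly at O(n^2)
  traces[1] <- sum(diag(Wblock))
  if (order >= 2L) traces[2] <- sum(Wblock * t(Wblock))
  -sum(rho^seq_len(order) * traces / seq_len(order))
}

#' Maximum-likelihood calibration of the ownership model
#'
#' Concentrated-likelihood scheme in the LeSage-Pace tradition: for a
#' candidate `rho`, the coefficient vector `delta(rho)` is the least-squares
#' fit of `Y - rho W Y` on `Z` and `sigma2(rho) = e'e/N` in closed form;
#' the scalar concentrated likelihood is then maximized over 99.9% of the
#' open spectral interval by [stats::optimize()]. Standard errors come from
#' the inverse observed information (numerical Hessian of the full
#' log-likelihood at the optimum). With the null weight sequence the fit
#' reduces to ordinary least squares and `rho` is fixed at 0.
#'
#' @param design An [assemble_stack()] result.
#' @param logdet_method `"exact"` (default) or `"mc"`.
#' @param n_draws,order,seed Monte-Carlo log-determinant settings.
#' @param tol Optimizer tolerance (default 1e-8).
#' @return An object of class `sdm_fit`: `params` ([model_params]), `tstats`,
#'   `se`, `loglik`, `n_obs`, `converged`, `rho_bounds`, `vcov`.
#' @export
fit_sdm <- function(design, logdet_method = c("exact", "mc"),
                    n_draws = 100L, order = 50L, seed = 1L, tol = 1e-8) {
  logdet_method <- match.arg(logdet_method)
  N <- length(design$Y)
  if (N < 13L) stop("need at least 13 stacked observations", call. = FALSE)
  # columns that are identically zero (e.g. every W-lag column under the
  # null weight sequence) carry no information; their coefficients are
  # pinned at 0 and excluded from the information matrix
  zero_cols <- colSums(abs(design$Z)) == 0
  qrZ <- qr(design$Z)
  if (qrZ$rank < ncol(design$Z) - sum(zero_cols))
    return(failed_fit(design, "rank-deficient design matrix"))
  coefs <- function(y) {
    b <- qr.coef(qrZ, y)
    b[is.na(b)] <- 0
    b
  }

  if (design$null_flag) {
    delta <- coefs(design$Y)
    e <- design$Y - drop(design$Z %*% delta)
    sigma2 <- sum(e^2) / N
    rho_hat <- 0
    bounds <- c(-Inf, Inf)
    ll <- sdm_loglik(design, 0, delta, sigma2)
  } else {
    delta0 <- coefs(design$Y)
    deltad <- coefs(design$WY)
    e0 <- design$Y - drop(design$Z %*% delta0)
    ed <- design$WY - drop(design$Z %*% deltad)
    conc <- function(rho) {
      e <- e0 - rho * ed
      s2 <- sum(e^2) / N
      -N / 2 * (log(2 * pi) + 1) - N / 2 * log(s2) +
        if (logdet_method == "exact") logdet_eigen(design$omega, rho)
        else sum(vapply(design$Wblocks, logdet_mc, numeric(1), rho = rho,
                        n_draws = n_draws, order = order, seed = seed))
    }
    bounds <- stack_rho_bounds(design)
    lo <- if (is.finite(bounds[1])) 0.9995 * bounds[1] else -5
    hi <- if (is.finite(bounds[2])) 0.9995 * bounds[2] else 5
    opt <- stats::optimize(conc, c(lo, hi), maximum = TRUE, tol = tol)
    rho_hat <- opt$maximum
    delta <- delta0 - rho_hat * deltad
    e <- e0 - rho_hat * ed
    sigma2 <- sum(e^2) / N
    ll <- sdm_loglik(design, rho_hat, delta, sigma2,
                     logdet_method = logdet_method, n_draws = n_draws,
                     order = order, seed = seed)
  }

  # observed information at the optimum (full likelihood in all 13 scalars;
  # exact log-determinant keeps the Hessian smooth even under logdet_method
  # = "mc", whose draws are frozen by the seed)
  par <- c(rho = rho_hat, delta, sigma2 = sigma2)
  negll <- function(p) {
    if (p[13] <= 0) return(1e10)
    if (!design$null_flag &&
        !(p[1] > stack_rho_bounds(design)[1] &&
          p[1] < stack_rho_bounds(design)[2])) return(1e10)
    -(-N / 2 * log(2 * pi * p[13]) +
        (if (design$null_flag) 0 else logdet_eigen(design$omega, p[1])) -
        sum((design$Y - p[1] * design$WY -
               drop(design$Z %*% p[2:12]))^2) / (2 * p[13]))
  }
  active <- c(if (!design$null_flag) 1L, 1L + which(!zero_cols), 13L)
  negll_active <- function(pa) {
    full <- par
    full[active] <- pa
    negll(full)
  }
  H <- tryCatch(stats::optimHess(par[active], negll_active),
                error = function(e) NULL)
  vc_a <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
          else NULL
  se <- rep(NA_real_, 13)
  vc <- NULL
  if (!is.null(vc_a)) {
    dg <- diag(vc_a)
    se[active[dg > 0]] <- sqrt(dg[dg > 0])
    vc <- matrix(NA_real_, 13, 13, dimnames = list(names(par), names(par)))
    vc[active, active] <- vc_a
  }
  names(se) <- names(par)
  tstats <- unname(par) / se
  tstats[13] <- NA_real_                      # variance has no zero-null test
  if (design$null_flag) tstats[1] <- NA_real_ # rho not identified under W=0

  params <- model_params(
    rho = rho_hat, tau = delta[["Y_L"]], eta = delta[["WY_L"]],
    phi1_H = delta[["X1_H"]], phi1_L = delta[["X1_L"]],
    phi2_H = delta[["X2_H"]], phi2_L = delta[["X2_L"]],
    psi1 = delta[["WX1"]], psi2 = delta[["WX2"]], gamma = delta[["d"]],
    alpha_H = delta[["i_H"]], alpha_L = delta[["i_L"]], sigma2 = sigma2)
  converged <- !is.null(vc) && all(is.finite(se[active[active != 13L]])) &&
    (design$null_flag ||
       (rho_hat > bounds[1] + 1e-6 && rho_hat < bounds[2] - 1e-6))
  structure(
    list(params = params, tstats = stats::setNames(tstats, names(par)),
         se = se, vcov = vc, loglik = ll, n_obs = N, converged = converged,
         rho_bounds = bounds, logdet_method = logdet_method,
         z_columns = colnames(design$Z)),
    class = "sdm_fit")
}

failed_fit <- function(design, reason) {
  structure(
    list(params = model_params(), tstats = rep(NA_real_, 13),
         se = rep(NA_real_, 13), vcov = NULL, loglik = NA_real_,
         n_obs = length(design$Y), converged = FALSE,
         rho_bounds = stack_rho_bounds(design), diagnostics = reason),
    class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> N = %d, logLik = %.3f, converged = %s\n",
              x$n_obs, x$loglik, x$converged))
  print(tidy(x), n = 13)
  invisible(x)
}

param_order <- c("rho", "Y_L", "WY_L", "X1_H", "X1_L", "X2_H", "X2_L",
                 "WX1", "WX2", "d", "i_H", "i_L", "sigma2")
param_terms <- c("rho", "tau", "eta", "phi1_H", "phi1_L", "phi2_H", "phi2_L",
                 "psi1", "psi2", "gamma", "alpha_H", "alpha_L", "sigma2")

#' Tidy the calibrated model into a coefficient table
#'
#' @param x An `sdm_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.sdm_fit <- function(x, ...) {
  est <- unlist(x$params)[param_terms]
  tibble::tibble(
    term = param_terms,
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(x$tstats),
    p.value = 2 * stats::pnorm(-abs(unname(x$tstats))))
}

#' One-row summary of the calibrated model
#'
#' @param x An `sdm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `sigma2`, `rho`, `nobs`, `converged`.
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma2 = x$params$sigma2,
                 rho = x$params$rho, nobs = x$n_obs,
                 converged = x$converged)
}
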