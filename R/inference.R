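#' Iterative monthly prediction with October survey anchoring
#'
#' Runs the calibrated model forward month by month with the noise set to
#' zero, so the output is the mean ownership path. The burn-in year (the 12
#' months preceding the first modeled year) is seeded with the first survey
#' year's values. To prevent drift over a 20-year horizon, each October's
#' 12-month lag is taken from the previous October's *survey* values; every
#' other month lags the model's own output. A missing survey anchor falls
#' back to the model value with a warning.
#'
#' A population-weighted national series is produced alongside by
#' [national_aggregate()].
#'
#' @param params A calibrated [model_params] (its `sigma2` is ignored here).
#' @param panel A [state_panel].
#' @param Wseq A [weight_sequence] with one matrix per panel year.
#' @param national Compute the national series too (default `TRUE`).
#' @return An object of class `ownership_prediction`: `monthly` (`n x M`),
#'   `national` (length `M`, or `NULL`), `anchors_used` (tibble of
#'   `(year, source)`).
#' @export
predict_monthly <- function(params, panel, Wseq, national = TRUE) {
  check_rho(params$rho, Wseq)
  if (anyNA(panel$survey[, 1L]))
    stop("first survey year must be fully observed to seed the burn-in",
         call. = FALSE)
  eng <- anchored_recursion(params, panel, Wseq)
  structure(
    list(monthly = eng$Y,
         national = if (national) national_aggregate(panel, params) else NULL,
         anchors_used = tibble::tibble(year = panel$years,
                                       source = eng$anchors),
         units = panel$units, years = panel$years),
    class = "ownership_prediction")
}

# the anchored monthly recursion shared by state-level and national paths
anchored_recursion <- function(params, panel, Wseq) {
  n <- panel$n
  M <- panel$M
  Y_init <- matrix(panel$survey[, 1L], n, 12L)
  anchors <- character(panel$T)
  Y <- matrix(NA_real_, n, M, dimnames = list(panel$units, NULL))
  for (m in seq_len(M)) {
    y <- (m - 1L) %/% 12L + 1L
    mon <- (m - 1L) %% 12L + 1L
    W <- W_for_year(Wseq, y)
    W_x <- W_for_year(Wseq, (m - 2L) %/% 12L + 1L)
    if (mon == 10L) {
      # October: anchor on the previous October's survey (year y-1; the
      # first modeled year anchors on the burn-in copy of survey year 1)
      if (y == 1L) {
        Y_lag <- Y_init[, 10L]
        anchors[y] <- "survey"
      } else {
        sv <- panel$survey[, y - 1L]
        if (anyNA(sv)) {
          warning(sprintf(
            "missing survey anchor for year %d; falling back to model output",
            panel$years[y - 1L]), call. = FALSE)
          miss <- is.na(sv)
          sv[miss] <- Y[miss, m - 12L]
          anchors[y] <- "model"
        } else anchors[y] <- "survey"
        Y_lag <- sv
      }
    } else {
      Y_lag <- if (m > 12L) Y[, m - 12L] else Y_init[, m]
    }
    x1 <- if (m > 1L) panel$X1[, m - 1L] else panel$X1[, 1L]
    x2 <- if (m > 1L) panel$X2[, m - 1L] else panel$X2[, 1L]
    rhs <- monthly_rhs(params, W, Y_lag, x1, x2, y - 1L,
                       panel$response_class, W_x = W_x)
    Y[, m] <- solve_contemporaneous(params, W, rhs)
  }
  list(Y = Y, anchors = anchors)
}

#' @export
print.ownership_prediction <- function(x, ...) {
  cat(sprintf("<ownership_prediction> %d units x %d months, %d survey anchors\n",
              nrow(x$monthly), ncol(x$monthly),
              sum(x$anchors_used$source == "survey")))
  invisible(x)
}

#' @export
as_tibble.ownership_prediction <- function(x, ...) {
  M <- ncol(x$monthly)
  tibble::tibble(
    unit = rep(x$units, times = M),
    year = rep(rep(x$years, each = 12L), each = nrow(x$monthly)),
    month = rep(rep(1:12, length(x$years)), each = nrow(x$monthly)),
    ownership = as.vector(x$monthly))
}

#' National ownership series from aggregated proxies
#'
#' Reconstructs national proxies by aggregating counts across units --
#' background checks as rate times population summed over units divided by
#' total population; the suicide fraction analogously (the panel stores
#' fractions, so counts are reconstructed as rate times population, a
#' documented approximation) -- and iterates the calibrated model on the
#' single national series (`n = 1`, no spatial terms, treated as
#' high-response). The national series is *not* the mean of state outputs.
#'
#' @param panel A [state_panel].
#' @param params A calibrated [model_params].
#' @return Length-`M` national ownership vector.
#' @export
national_aggregate <- function(panel, params) {
  popm <- panel$populations[, rep(seq_len(panel$T), each = 12L), drop = FALSE]
  tot_pop <- colSums(popm)
  x1_nat <- colSums(panel$X1 * popm) / tot_pop
  x2_nat <- colSums(panel$X2 * popm) / tot_pop
  sv_nat <- colSums(panel$survey * panel$populations) /
    colSums(panel$populations)
  if (anyNA(sv_nat))
    stop("national aggregation needs complete survey anchors", call. = FALSE)

  nat_panel <- state_panel(
    units = "national", years = panel$years,
    X1 = matrix(x1_nat, 1L), X2 = matrix(pmin(pmax(x2_nat, 0), 1), 1L),
    survey = matrix(pmin(pmax(sv_nat, 0), 1), 1L),
    populations = matrix(tot_pop[seq(1L, panel$M, by = 12L)], 1L),
    centroids = tibble::tibble(unit = "national", lat = 0, lon = 0),
    response_class = "H")
  nat_params <- params
  nat_params$rho <- 0                       # single unit: no spatial terms
  nat_params$eta <- 0
  nat_params$psi1 <- 0
  nat_params$psi2 <- 0
  drop(anchored_recursion(nat_params, nat_panel,
                          null_W(1L, panel$T, panel$years))$Y)
}

#' Squared-error agreement between predictions and survey anchors
#'
#' For every observed October the predicted ownership is subtracted from the
#' survey fraction and squared; SSE is the sum and MSE the mean over the
#' compared Octobers.
#'
#' @param pred An [predict_monthly()] result, or an `n x M` prediction
#'   matrix.
#' @param survey_Y `n x T` survey matrix (`NA` = not compared).
#' @return List with `sse`, `mse`, `n_compared`, and `per_unit` (tibble of
#'   unit-level SSE/MSE).
#' @export
evaluate_fit <- function(pred, survey_Y) {
  Y <- if (inherits(pred, "ownership_prediction")) pred$monthly else pred
  survey_Y <- as.matrix(survey_Y)
  T_years <- ncol(survey_Y)
  if (ncol(Y) < october_col(T_years))
    stop("prediction does not cover all survey Octobers", call. = FALSE)
  oct <- Y[, october_col(seq_len(T_years)), drop = FALSE]
  d2 <- (oct - survey_Y)^2
  if (all(is.na(d2))) stop("no overlapping Octobers", call. = FALSE)
  units <- rownames(Y)
  if (is.null(units)) units <- as.character(seq_len(nrow(Y)))
  per_unit <- tibble::tibble(
    unit = units,
    sse = rowSums(d2, na.rm = TRUE),
    n_compared = rowSums(!is.na(d2)))
  per_unit$mse <- per_unit$sse / per_unit$n_compared
  list(sse = sum(d2, na.rm = TRUE),
       mse = sum(d2, na.rm = TRUE) / sum(!is.na(d2)),
       n_compared = sum(!is.na(d2)),
       per_unit = per_unit)
}

#' Plot predicted ownership trajectories
#'
#' National trajectory (line) overlaid with population-weighted survey
#' anchors (points), in the style of a model-vs-survey diagnostic.
#'
#' @param object An `ownership_prediction`.
#' @param panel Optional [state_panel] supplying survey anchors to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ownership_prediction <- function(object, panel = NULL, ...) {
  M <- ncol(object$monthly)
  nat <- object$national
  if (is.null(nat)) nat <- colMeans(object$monthly)
  df <- tibble::tibble(date = object$years[1] + (seq_len(M) - 0.5) / 12,
                       national = nat)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$national)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "year", y = "fraction of firearm owners",
                  title = "Predicted national firearm ownership") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    sv <- colSums(panel$survey * panel$populations) /
      colSums(panel$populations)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(date = panel$years + 9.5 / 12, national = sv),
      color = "firebrick")
  }
  p
}
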