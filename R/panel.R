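#' Monthly state panel of ownership proxies and survey anchors
#'
#' A `state_panel` bundles everything the spatiotemporal ownership model needs
#' for `n` spatial units observed over `T` whole calendar years: two monthly
#' proxy matrices (background checks per capita and the fraction of suicides
#' committed with a firearm), annual October survey ownership fractions,
#' annual populations, unit centroids, and the high/low survey-response
#' classification that drives the split proxy coefficients.
#'
#' @param units Character vector of `n` unit labels (e.g. state codes).
#' @param years Integer vector of `T` consecutive calendar years.
#' @param X1 `n x 12T` matrix of background checks per capita
#'   (checks/person/month, nonnegative); columns run January of `years[1]`
#'   through December of `years[T]`.
#' @param X2 `n x 12T` matrix of the fraction of suicides committed with a
#'   firearm, in `[0, 1]`.
#' @param survey `n x T` matrix of October survey ownership fractions in
#'   `[0, 1]`; `NA` marks a missing anchor.
#' @param populations `n x T` matrix of yearly populations (persons, > 0).
#' @param centroids Data frame with columns `unit`, `lat`, `lon` (degrees).
#' @param response_class Character vector of `n` labels in `{"H","L"}`, or
#'   `NULL` to derive it from `respondents` via [classify_response()].
#' @param respondents Optional `n x T` matrix of survey respondent counts.
#' @param response_threshold Respondent-count threshold used when
#'   `response_class` is derived (default 10).
#'
#' @return An object of class `state_panel`.
#' @seealso [read_panel()], [classify_response()], [generate_scenario()]
#' @export
state_panel <- function(units, years, X1, X2, survey, populations, centroids,
                        response_class = NULL, respondents = NULL,
                        response_threshold = 10L) {
  units <- as.character(units)
  years <- as.integer(years)
  n <- length(units)
  T_years <- length(years)
  M <- 12L * T_years
  if (n < 1L) stop("panel needs at least one unit", call. = FALSE)
  if (T_years < 1L) stop("panel needs at least one year", call. = FALSE)
  if (anyDuplicated(units)) stop("duplicate unit labels", call. = FALSE)
  if (T_years > 1L && any(diff(years) != 1L))
    stop("years must be consecutive", call. = FALSE)

  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  survey <- as.matrix(survey); populations <- as.matrix(populations)
  check_dim <- function(m, nr, nc, what) {
    if (!all(dim(m) == c(nr, nc)))
      stop(sprintf("%s must be %d x %d, got %d x %d",
                   what, nr, nc, nrow(m), ncol(m)), call. = FALSE)
  }
  check_dim(X1, n, M, "X1"); check_dim(X2, n, M, "X2")
  check_dim(survey, n, T_years, "survey")
  check_dim(populations, n, T_years, "populations")

  if (any(!is.finite(X1)) || any(X1 < 0))
    stop("X1 (background checks per capita) must be finite and nonnegative",
         call. = FALSE)
  if (any(!is.finite(X2)) || any(X2 < 0) || any(X2 > 1))
    stop("fraction out of [0,1] in X2", call. = FALSE)
  sv <- survey[!is.na(survey)]
  if (any(!is.finite(sv)) || any(sv < 0) || any(sv > 1))
    stop("fraction out of [0,1] in survey ownership", call. = FALSE)
  if (any(!is.finite(populations)) || any(populations <= 0))
    stop("populations must be strictly positive", call. = FALSE)

  centroids <- tibble::as_tibble(centroids)
  if (!all(c("unit", "lat", "lon") %in% names(centroids)))
    stop("centroids needs columns unit, lat, lon", call. = FALSE)
  missing_cent <- setdiff(units, centroids$unit)
  if (length(missing_cent))
    stop("missing unit in centroid table: ",
         paste(missing_cent, collapse = ", "), call. = FALSE)
  centroids <- centroids[match(units, centroids$unit), c("unit", "lat", "lon")]

  if (!is.null(respondents)) {
    respondents <- as.matrix(respondents)
    check_dim(respondents, n, T_years, "respondents")
  }
  if (is.null(response_class)) {
    if (is.null(respondents))
      stop("supply response_class or respondents", call. = FALSE)
    response_class <- classify_response(respondents, response_threshold)
  }
  response_class <- as.character(response_class)
  if (length(response_class) != n || !all(response_class %in% c("H", "L")))
    stop("response_class must be length-n labels in {H, L}", call. = FALSE)

  dimnames(X1) <- dimnames(X2) <- list(units, NULL)
  dimnames(survey) <- dimnames(populations) <- list(units, years)
  structure(
    list(units = units, years = years, n = n, T = T_years, M = M,
         X1 = X1, X2 = X2, survey = survey, populations = populations,
         respondents = respondents, centroids = centroids,
         response_class = stats::setNames(response_class, units)),
    class = "state_panel")
}

#' @export
print.state_panel <- function(x, ...) {
  cat(sprintf("<state_panel> %d units x %d months (%d-%d), %d H / %d L\n",
              x$n, x$M, x$years[1], x$years[x$T],
              sum(x$response_class == "H"), sum(x$response_class == "L")))
  cat(sprintf("  survey anchors: %d observed, %d missing\n",
              sum(!is.na(x$survey)), sum(is.na(x$survey))))
  invisible(x)
}

# calendar (year, month) pairs for the panel's M monthly columns
panel_months <- function(panel) {
  tibble::tibble(year = rep(panel$years, each = 12L),
                 month = rep(1:12, times = panel$T))
}

# column index of calendar October in modeled year y (1-based year index)
october_col <- function(year_index) 12L * (year_index - 1L) + 10L

#' @export
as_tibble.state_panel <- function(x, ...) {
  mo <- panel_months(x)
  tibble::tibble(
    unit = rep(x$units, times = x$M),
    year = rep(mo$year, each = x$n),
    month = rep(mo$month, each = x$n),
    checks_pc = as.vector(x$X1),
    suicides_frac = as.vector(x$X2))
}

#' Classify units by survey response rate
#'
#' A unit is labeled high-response (`"H"`) only if its respondent count
#' exceeds `threshold` in every year; any year at or below the threshold
#' makes the unit low-response (`"L"`). The split lets the calibration
#' estimate separate proxy coefficients and intercepts for sparsely sampled
#' units, whose annual survey fractions can be wildly off (a single
#' respondent forces the observed fraction to 0 or 1).
#'
#' @param respondent_counts `n x T` matrix of nonnegative integer counts.
#' @param threshold Integer respondent threshold (default 10); `H` requires
#'   strictly more than `threshold` respondents in every year.
#' @return Character vector of `n` labels in `{"H","L"}`.
#' @export
classify_response <- function(respondent_counts, threshold = 10L) {
  m <- as.matrix(respondent_counts)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("respondent counts must be nonnegative integers", call. = FALSE)
  if (threshold < 1L) stop("threshold must be >= 1", call. = FALSE)
  ifelse(apply(m > threshold, 1L, all), "H", "L")
}

#' Read a state panel from long-format CSV tables
#'
#' Assembles and validates a [state_panel] from four CSV files. All files are
#' UTF-8 with a header row and `.` decimal separator:
#' \describe{
#'   \item{proxy}{`unit, year, month, proxy, value` with `proxy` in
#'     `{"checks_pc", "suicides_frac"}`, one row per unit-month-proxy.}
#'   \item{survey}{`unit, year, value, respondents`; `value` may be empty
#'     (missing anchor).}
#'   \item{population}{`unit, year, population`.}
#'   \item{centroid}{`unit, lat, lon`.}
#' }
#' Rows may appear in any order; units are sorted by label and months
#' ascending. Every unit must appear in every table, proxy months must form a
#' consecutive whole-year span, and fractions must lie in `[0, 1]`.
#'
#' @param proxy_table,survey_table,population_table,centroid_table File paths.
#' @param response_threshold Passed to [classify_response()].
#' @return A validated [state_panel].
#' @export
read_panel <- function(proxy_table, survey_table, population_table,
                       centroid_table, response_threshold = 10L) {
  rd <- function(path) readr::read_csv(path, show_col_types = FALSE,
                                       progress = FALSE)
  proxies <- rd(proxy_table)
  survey <- rd(survey_table)
  pops <- rd(population_table)
  cents <- rd(centroid_table)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(proxies, c("unit", "year", "month", "proxy", "value"), "proxy")
  need(survey, c("unit", "year", "value", "respondents"), "survey")
  need(pops, c("unit", "year", "population"), "population")
  need(cents, c("unit", "lat", "lon"), "centroid")

  units <- sort(unique(proxies$unit))
  for (tb in list(list(survey, "survey"), list(pops, "population"),
                  list(cents, "centroid"))) {
    miss <- setdiff(units, tb[[1]]$unit)
    if (length(miss))
      stop(sprintf("missing unit in %s table: %s", tb[[2]],
                   paste(miss, collapse = ", ")), call. = FALSE)
  }

  mo <- sort(unique(proxies$year * 12L + (proxies$month - 1L)))
  if (length(mo) > 1L && any(diff(mo) != 1L))
    stop("non-consecutive months in proxy table", call. = FALSE)
  if (length(mo) %% 12L != 0L || mo[1] %% 12L != 0L)
    stop("proxy months must span whole January-December years", call. = FALSE)
  years <- seq.int(mo[1] %/% 12L, by = 1L, length.out = length(mo) %/% 12L)
  M <- length(mo)

  grab <- function(name) {
    sub <- proxies[proxies$proxy == name, ]
    if (nrow(sub) != length(units) * M)
      stop(sprintf("proxy '%s': expected %d rows (one per unit-month), got %d",
                   name, length(units) * M, nrow(sub)), call. = FALSE)
    i <- match(sub$unit, units)
    j <- match(sub$year * 12L + (sub$month - 1L), mo)
    m <- matrix(NA_real_, length(units), M)
    m[cbind(i, j)] <- sub$value
    if (anyNA(m)) {
      hole <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("proxy '%s' missing for unit %s, month %d/%d", name,
                   units[hole[1]], mo[hole[2]] %/% 12L,
                   mo[hole[2]] %% 12L + 1L), call. = FALSE)
    }
    m
  }
  X1 <- grab("checks_pc")
  X2 <- grab("suicides_frac")

  to_annual <- function(df, col) {
    m <- matrix(NA_real_, length(units), length(years))
    keep <- df$year %in% years
    df <- df[keep, ]
    m[cbind(match(df$unit, units), match(df$year, years))] <- df[[col]]
    m
  }
  survey_m <- to_annual(survey, "value")
  resp_m <- to_annual(survey, "respondents")
  pop_m <- to_annual(pops, "population")
  if (anyNA(pop_m)) {
    hole <- which(is.na(pop_m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing population for unit %s, year %d",
                 units[hole[1]], years[hole[2]]), call. = FALSE)
  }
  if (anyNA(resp_m)) resp_m[is.na(resp_m)] <- 0
  sv <- survey_m[!is.na(survey_m)]
  if (any(sv < 0 | sv > 1))
    stop("fraction out of [0,1] in survey table", call. = FALSE)

  state_panel(units = units, years = years, X1 = X1, X2 = X2,
              survey = survey_m, populations = pop_m, centroids = cents,
              respondents = resp_m, response_threshold = response_threshold)
}

#' Write a state panel to the long-format CSV tables read by [read_panel()]
#'
#' @param panel A [state_panel].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the four file paths.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mo <- panel_months(panel)
  long <- function(m, name) {
    tibble::tibble(unit = rep(panel$units, times = panel$M),
                   year = rep(mo$year, each = panel$n),
                   month = rep(mo$month, each = panel$n),
                   proxy = name, value = as.vector(m))
  }
  paths <- list(
    proxy = file.path(dir, "proxies.csv"),
    survey = file.path(dir, "survey.csv"),
    population = file.path(dir, "populations.csv"),
    centroid = file.path(dir, "centroids.csv"))
  readr::write_csv(dplyr::bind_rows(long(panel$X1, "checks_pc"),
                                    long(panel$X2, "suicides_frac")),
                   paths$proxy, progress = FALSE)
  resp <- panel$respondents
  if (is.null(resp))   # synthesize counts consistent with the H/L labels
    resp <- matrix(ifelse(panel$response_class == "H", 99L, 1L),
                   panel$n, panel$T)
  readr::write_csv(
    tibble::tibble(unit = rep(panel$units, times = panel$T),
                   year = rep(panel$years, each = panel$n),
                   value = as.vector(panel$survey),
                   respondents = as.vector(resp)),
    paths$survey, progress = FALSE)
  readr::write_csv(
    tibble::tibble(unit = rep(panel$units, times = panel$T),
                   year = rep(panel$years, each = panel$n),
                   population = as.vector(panel$populations)),
    paths$population, progress = FALSE)
  readr::write_csv(panel$centroids, paths$centroid, progress = FALSE)
  invisible(paths)
}
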