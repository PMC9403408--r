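#' Time-varying spatial weight matrices
#'
#' A `weight_sequence` holds one row-stochastic `n x n` interaction matrix per
#' year. The default builder makes the influence of unit `j` on unit `i`
#' proportional to `j`'s population divided by the centroid distance between
#' `i` and `j`, row-normalized — closer and more populated neighbours exert
#' greater influence. Populations are annual, so the matrix is constant
#' within a year.
#'
#' @param matrices List of `T` `n x n` matrices.
#' @param years Integer vector of `T` years.
#' @param null_flag `TRUE` for the all-zero (no spatial interaction) sequence,
#'   which waives the row-sum invariant.
#' @return An object of class `weight_sequence`.
#' @export
weight_sequence <- function(matrices, years, null_flag = FALSE) {
  stopifnot(is.list(matrices), length(matrices) == length(years))
  n <- nrow(matrices[[1]])
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("all weight matrices must be n x n", call. = FALSE)
    if (any(diag(m) != 0))
      stop("weight matrix diagonal must be zero", call. = FALSE)
    if (any(m < 0)) stop("weight matrix entries must be >= 0", call. = FALSE)
    if (!null_flag && any(abs(rowSums(m) - 1) > 1e-12))
      stop("weight matrix rows must sum to 1", call. = FALSE)
  }
  structure(list(matrices = matrices, years = as.integer(years), n = n,
                 null_flag = null_flag),
            class = "weight_sequence")
}

#' @export
print.weight_sequence <- function(x, ...) {
  cat(sprintf("<weight_sequence> %d x %d, years %d-%d%s\n", x$n, x$n,
              x$years[1], x$years[length(x$years)],
              if (x$null_flag) " (null: W = 0)" else ""))
  invisible(x)
}

#' Great-circle distances between unit centroids
#'
#' Haversine distances (Earth radius 6371 km) between all pairs of centroids.
#'
#' @param centroids Data frame with columns `unit`, `lat`, `lon` (degrees),
#'   or a two-column `lat`/`lon` matrix.
#' @return Symmetric `n x n` matrix of distances in km, zero diagonal.
#' @export
pairwise_distance <- function(centroids) {
  if (is.data.frame(centroids)) {
    units <- if ("unit" %in% names(centroids)) centroids$unit else NULL
    ll <- cbind(centroids$lon, centroids$lat)
  } else {
    units <- rownames(centroids)
    ll <- cbind(centroids[, 2], centroids[, 1])  # matrix given as (lat, lon)
  }
  n <- nrow(ll)
  if (n < 2L) stop("need at least two centroids", call. = FALSE)
  if (any(abs(ll[, 2]) > 90) || any(abs(ll[, 1]) > 180))
    stop("latitudes must be in [-90, 90], longitudes in [-180, 180]",
         call. = FALSE)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    d <- geosphere::distHaversine(ll[i, , drop = FALSE],
                                  ll[(i + 1L):n, , drop = FALSE],
                                  r = 6371)
    D[i, (i + 1L):n] <- d
    D[(i + 1L):n, i] <- d
  }
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    ij <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1, ]
    stop(sprintf("duplicate centroid for distinct units %s and %s",
                 if (is.null(units)) ij[1] else units[ij[1]],
                 if (is.null(units)) ij[2] else units[ij[2]]), call. = FALSE)
  }
  dimnames(D) <- list(units, units)
  D
}

#' Population / inverse-distance weight matrices
#'
#' Builds one matrix per year with off-diagonal entries
#' `W[i, j] = p[j] / (K[i] * D[i, j])`, where `p[j]` is the population of
#' unit `j` that year, `D` the centroid distance matrix, and `K[i]` the
#' row-normalizing sum, so every row sums to 1.
#'
#' @param populations `n x T` matrix of positive yearly populations.
#' @param distances Symmetric `n x n` positive off-diagonal distance matrix,
#'   e.g. from [pairwise_distance()].
#' @param years Optional year labels (default `1:T` or population colnames).
#' @return A [weight_sequence].
#' @export
build_population_distance_W <- function(populations, distances, years = NULL) {
  populations <- as.matrix(populations)
  if (any(populations <= 0) || any(!is.finite(populations)))
    stop("populations must be strictly positive", call. = FALSE)
  n <- nrow(populations)
  if (!all(dim(distances) == c(n, n)))
    stop("distance matrix must be n x n", call. = FALSE)
  if (any(distances[upper.tri(distances)] <= 0))
    stop("off-diagonal distances must be positive", call. = FALSE)
  if (is.null(years)) {
    years <- colnames(populations)
    if (is.null(years)) years <- seq_len(ncol(populations))
  }
  inv_d <- 1 / distances
  diag(inv_d) <- 0
  mats <- lapply(seq_len(ncol(populations)), function(t) {
    raw <- sweep(inv_d, 2L, populations[, t], `*`)  # raw[i,j] = p_j / D_ij
    W <- raw / rowSums(raw)
    dimnames(W) <- dimnames(distances)
    W
  })
  weight_sequence(mats, as.integer(years))
}

#' Generic row-normalized weight builder
#'
#' Applies a user-supplied kernel `(populations_t, distances, ...) -> raw
#' n x n weights` per year, zeroes the diagonal, and row-normalizes. Allows
#' alternative interaction schemes (GDP, area, shared borders) without
#' shipping them.
#'
#' @param populations `n x T` matrix passed column-wise to `kernel`.
#' @param distances `n x n` matrix passed to `kernel`.
#' @param kernel Function returning a nonnegative `n x n` matrix of raw
#'   weights.
#' @param years Optional year labels.
#' @param ... Extra arguments for `kernel`.
#' @return A [weight_sequence].
#' @export
build_custom_W <- function(populations, distances, kernel, years = NULL, ...) {
  populations <- as.matrix(populations)
  if (is.null(years)) years <- seq_len(ncol(populations))
  mats <- lapply(seq_len(ncol(populations)), function(t) {
    raw <- kernel(populations[, t], distances, ...)
    diag(raw) <- 0
    if (any(raw < 0)) stop("kernel produced negative weights", call. = FALSE)
    rs <- rowSums(raw)
    if (any(rs == 0)) stop("kernel produced an all-zero row", call. = FALSE)
    raw / rs
  })
  weight_sequence(mats, as.integer(years))
}

#' Null weight sequence (no spatial interaction)
#'
#' All-zero matrices: with `W = 0` the spatial Durbin model collapses to an
#' ordinary (distributed-lag) linear model.
#'
#' @param n Number of units.
#' @param T Number of years.
#' @param years Optional year labels.
#' @return A [weight_sequence] with `null_flag = TRUE`.
#' @export
null_W <- function(n, T, years = NULL) {
  stopifnot(n >= 1L, T >= 1L)
  if (is.null(years)) years <- seq_len(T)
  weight_sequence(replicate(T, matrix(0, n, n), simplify = FALSE),
                  as.integer(years), null_flag = TRUE)
}

# W matrix in force for modeled year index y (clamped to the covered range,
# so the burn-in December before year 1 reuses year 1's matrix)
W_for_year <- function(Wseq, year_index) {
  Wseq$matrices[[min(max(year_index, 1L), length(Wseq$matrices))]]
}
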