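#' Shannon entropy of a discrete distribution, in bits
#'
#' `H = -sum p log2 p`, with `0 * log 0 := 0`.
#'
#' @param probs Nonnegative probability vector summing to 1 (within 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(probs) {
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9)
    stop("probabilities must be nonnegative and sum to 1", call. = FALSE)
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

#' Empirical joint distribution of aligned symbol series
#'
#' Plug-in relative frequencies over the joint outcomes of one or more
#' aligned binary series.
#'
#' @param ... Named binary vectors or `symbolic_series` of equal length.
#' @return Tibble of joint outcomes with a `probability` column.
#' @export
empirical_joint <- function(...) {
  vars <- lapply(list(...), as_symbols)
  if (length(unique(lengths(vars))) != 1L)
    stop("series lengths differ", call. = FALSE)
  df <- tibble::as_tibble(vars)
  out <- dplyr::count(df, dplyr::across(dplyr::everything()), name = "count")
  out$probability <- out$count / sum(out$count)
  out$count <- NULL
  out
}

# cell code for the joint state (x_{t+1}, x_t, y, z): 8a + 4b + 2y + z + 1
TE_A <- (0:15) %/% 8L
TE_B <- ((0:15) %/% 4L) %% 2L
TE_Y <- ((0:15) %/% 2L) %% 2L
TE_Z <- (0:15) %% 2L
TE_MAP_BZ <- 2L * TE_B + TE_Z + 1L           # -> 4 cells (b, z)
TE_MAP_BYZ <- 4L * TE_B + 2L * TE_Y + TE_Z + 1L   # -> 8 cells (b, y, z)
TE_MAP_ABZ <- 4L * TE_A + 2L * TE_B + TE_Z + 1L   # -> 8 cells (a, b, z)

# plug-in conditional TE (bits) from the 16-cell contingency counts
te_from_counts <- function(counts) {
  N <- sum(counts)
  n_bz <- as.vector(rowsum(counts, TE_MAP_BZ))[TE_MAP_BZ]
  n_byz <- as.vector(rowsum(counts, TE_MAP_BYZ))[TE_MAP_BYZ]
  n_abz <- as.vector(rowsum(counts, TE_MAP_ABZ))[TE_MAP_ABZ]
  pos <- counts > 0
  te <- sum(counts[pos] * (log2(counts[pos]) + log2(n_bz[pos]) -
                             log2(n_byz[pos]) - log2(n_abz[pos]))) / N
  max(te, 0)   # plug-in conditional MI is nonnegative; clip rounding dust
}

# align (X_{t+1}, X_t, Y_{t-lag}, Z_{t-lag}) and encode cell codes
te_alignment <- function(target, source, conditioner, lag = 0L) {
  x <- as_symbols(target)
  y <- as_symbols(source)
  z <- as_symbols(conditioner)
  if (length(y) != length(x) || length(z) != length(x))
    stop("length mismatch after alignment", call. = FALSE)
  if (lag < 0L) stop("lag must be >= 0", call. = FALSE)
  n <- length(x)
  t_idx <- (lag + 1L):(n - 1L)
  if (length(t_idx) < 20L)
    stop("need at least 20 aligned time points", call. = FALSE)
  list(a = x[t_idx + 1L], b = x[t_idx], y = y[t_idx - lag],
       z = z[t_idx - lag])
}

#' Conditional transfer entropy between binary symbol series
#'
#' Plug-in estimate of `TE(source -> target | conditioner)
#' = H(X_{t+1} | X_t, Z_t) - H(X_{t+1} | X_t, Y_t, Z_t)` under a first-order
#' embedding with a unitary time step, from the empirical joint distribution
#' of `(X_{t+1}, X_t, Y_{t-lag}, Z_{t-lag})`. `lag = 0` is the main
#' analysis; positive lags shift the source and conditioner back for delay
#' analysis.
#'
#' @param target,source,conditioner Binary vectors or `symbolic_series`,
#'   equal length (>= 21 usable points after alignment).
#' @param lag Months of delay applied to source and conditioner (>= 0).
#' @return An object of class `te_result` with `te_bits`, `lag`,
#'   `direction`; `p_value` is `NA` until a permutation test is run.
#' @export
conditional_te <- function(target, source, conditioner, lag = 0L) {
  al <- te_alignment(target, source, conditioner, lag)
  counts <- tabulate(8L * al$a + 4L * al$b + 2L * al$y + al$z + 1L, 16L)
  te_result(te_from_counts(counts), NA_real_, 0L,
            direction_labels(target, source, conditioner), lag)
}

direction_labels <- function(target, source, conditioner) {
  lab <- function(s, fallback) {
    if (inherits(s, "symbolic_series") && nzchar(s$source_label))
      s$source_label else fallback
  }
  c(source = lab(source, "source"), target = lab(target, "target"),
    conditioner = lab(conditioner, "conditioner"))
}

te_result <- function(te_bits, p_value, n_permutations, direction, lag) {
  structure(list(te_bits = te_bits, p_value = p_value,
                 n_permutations = n_permutations, direction = direction,
                 lag = as.integer(lag)),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("<te_result> TE(%s -> %s | %s) = %.4f bits",
              x$direction[["source"]], x$direction[["target"]],
              x$direction[["conditioner"]], x$te_bits))
  if (x$lag > 0L) cat(sprintf(", lag %d", x$lag))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4f (%d permutations)", x$p_value,
                x$n_permutations))
  cat("\n")
  invisible(x)
}

#' @export
tidy.te_result <- function(x, ...) {
  tibble::tibble(source = x$direction[["source"]],
                 target = x$direction[["target"]],
                 conditioner = x$direction[["conditioner"]],
                 lag = x$lag, te_bits = x$te_bits, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' Local permutation significance test for conditional transfer entropy
#'
#' Surrogate test that preserves the conditioning structure: time points are
#' stratified by the realized pair `(X_t, Z_t)` -- the four cells (0,0),
#' (0,1), (1,0), (1,1) -- and the source symbols are shuffled only within
#' each stratum, so every surrogate keeps the per-stratum multiset of source
#' symbols. TE is recomputed for each surrogate; the p-value is the
#' right-tail fraction `(1 + #{surrogate >= observed}) / (1 + n)` (ties
#' count toward the tail; the +1 keeps p > 0). A link is called significant
#' when the observed TE exceeds the surrogate 95th percentile.
#'
#' @inheritParams conditional_te
#' @param n_permutations Number of surrogates (default 50000).
#' @param seed Integer seed; the test is reproducible.
#' @return A `te_result` with `p_value` and `surrogate_q95` filled in.
#' @export
local_permutation_test <- function(target, source, conditioner, lag = 0L,
                                   n_permutations = 50000L, seed = 1L) {
  al <- te_alignment(target, source, conditioner, lag)
  code0 <- 8L * al$a + 4L * al$b + al$z + 1L   # everything but the source
  y <- al$y
  obs <- te_from_counts(tabulate(code0 + 2L * y, 16L))
  strata <- split(seq_along(y), 2L * al$b + al$z)
  strata <- strata[lengths(strata) > 0L]
  set.seed(seed)
  surr <- numeric(n_permutations)
  yp <- y
  for (r in seq_len(n_permutations)) {
    for (idx in strata) yp[idx] <- y[idx[sample.int(length(idx))]]
    surr[r] <- te_from_counts(tabulate(code0 + 2L * yp, 16L))
  }
  p <- (1 + sum(surr >= obs)) / (1 + n_permutations)
  out <- te_result(obs, p, n_permutations,
                   direction_labels(target, source, conditioner), lag)
  out$surrogate_q95 <- unname(stats::quantile(surr, 0.95))
  out
}

#' Full causal analysis of a labeled triad
#'
#' Preprocesses three series per a per-series plan ([preprocess_series()]),
#' truncates all symbol series to their common length (change-rule series
#' are one shorter than their input, so event series lose their final
#' element), then computes conditional transfer entropy with the local
#' permutation test for all 6 ordered pairs, each conditioned on the third
#' variable.
#'
#' @param series_map Named list of three numeric series.
#' @param plan Named list (same names) of plans: each a list with elements
#'   `rule` (`"change"`/`"event"`), and optional `adjust`, `detrend`.
#'   Default: change symbolization with no adjustment for every series.
#' @param n_permutations,seed Passed to [local_permutation_test()].
#' @param lag Delay in months (default 0).
#' @return A `te_table`: tibble of 6 rows (`source`, `target`,
#'   `conditioner`, `te_bits`, `p_value`, `significant`).
#' @export
triad_analysis <- function(series_map, plan = NULL, n_permutations = 50000L,
                           seed = 1L, lag = 0L) {
  if (length(series_map) != 3L || is.null(names(series_map)))
    stop("series_map must be a named list of three series", call. = FALSE)
  labels <- names(series_map)
  if (is.null(plan))
    plan <- stats::setNames(rep(list(list(rule = "change")), 3L), labels)
  syms <- lapply(labels, function(lb) {
    pl <- plan[[lb]]
    if (is.null(pl)) pl <- list(rule = "change")
    preprocess_series(series_map[[lb]], rule = pl$rule,
                      adjust = isTRUE(pl$adjust),
                      detrend = isTRUE(pl$detrend), label = lb)
  })
  names(syms) <- labels
  len <- min(vapply(syms, function(s) length(s$symbols), integer(1)))
  syms <- lapply(syms, function(s) {
    s$symbols <- s$symbols[seq_len(len)]
    s
  })
  pairs <- expand.grid(source = labels, target = labels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  rows <- purrr::pmap(pairs, function(source, target) {
    cond <- setdiff(labels, c(source, target))
    res <- local_permutation_test(syms[[target]], syms[[source]],
                                  syms[[cond]], lag = lag,
                                  n_permutations = n_permutations,
                                  seed = seed)
    tibble::tibble(source = source, target = target, conditioner = cond,
                   te_bits = res$te_bits, p_value = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < 0.05
  class(out) <- c("te_table", class(out))
  out
}

#' @export
print.te_table <- function(x, ...) {
  cat("Conditional transfer entropy (rows: sources; columns: targets;\n")
  cat("p-values in parentheses)\n\n")
  labels <- unique(c(x$source, x$target))
  for (s in labels) {
    cells <- vapply(labels, function(t) {
      if (s == t) return(sprintf("%20s", "-"))
      r <- x[x$source == s & x$target == t, ]
      sprintf("%8.4f (%.4f)%s", r$te_bits, r$p_value,
              if (r$significant) "*" else " ")
    }, character(1))
    cat(sprintf("%-22s %s\n", s, paste(cells, collapse = " ")))
  }
  invisible(x)
}

#' Heatmap of triad transfer-entropy results
#'
#' @param object A `te_table` from [triad_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$te_bits)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f\n(p=%.3f)%s", .data$te_bits, .data$p_value,
                      ifelse(.data$significant, "*", "")))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(title = "Conditional transfer entropy (bits)",
                  x = "target", y = "source") +
    ggplot2::theme_minimal()
}
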