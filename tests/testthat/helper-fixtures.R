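# Small deterministic fixtures and independent oracles shared across tests.

# tiny hand-checkable panel: n units, T years, smooth proxies, H/L mix
toy_panel <- function(n = 2L, T = 2L, seed = 101L) {
  set.seed(seed)
  M <- 12L * T
  units <- sprintf("U%d", seq_len(n))
  X1 <- matrix(stats::runif(n * M, 0.003, 0.007), n, M)
  X2 <- matrix(stats::runif(n * M, 0.4, 0.6), n, M)
  survey <- matrix(stats::runif(n * T, 0.2, 0.6), n, T)
  pops <- matrix(stats::runif(n * T, 1e6, 9e6), n, T)
  centroids <- tibble::tibble(unit = units,
                              lat = 35 + seq_len(n),
                              lon = -100 + 2 * seq_len(n))
  rc <- rep(c("H", "L"), length.out = n)
  state_panel(units = units, years = seq(2000L, length.out = T),
              X1 = X1, X2 = X2, survey = survey, populations = pops,
              centroids = centroids, response_class = rc)
}

toy_Wseq <- function(panel) {
  build_population_distance_W(panel$populations,
                              pairwise_distance(panel$centroids),
                              panel$years)
}

# independent brute-force conditional transfer entropy: four joint entropies
# computed from explicit outcome tables (Eq.-by-Eq. route, no shared code)
te_oracle <- function(x, y, z, lag = 0L) {
  n <- length(x)
  t_idx <- (lag + 1L):(n - 1L)
  a <- x[t_idx + 1L]; b <- x[t_idx]
  yy <- y[t_idx - lag]; zz <- z[t_idx - lag]
  H <- function(...) {
    tab <- table(...)
    p <- as.vector(tab) / sum(tab)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  (H(a, b, zz) - H(b, zz)) - (H(a, b, yy, zz) - H(b, yy, zz))
}

# random row-stochastic zero-diagonal matrix
random_W <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  diag(W) <- 0
  W / rowSums(W)
}
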