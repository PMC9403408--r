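#' Write a result object to JSON
#'
#' Serializes [model_params], `te_result`, and `sdm_fit` objects to a JSON
#' file with a top-level `schema_version` and `type` field, at full double
#' precision so that [read_results()] round-trips exactly.
#'
#' @param result A `model_params`, `te_result`, or `sdm_fit`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path) {
  payload <- if (inherits(result, "model_params")) {
    list(type = "model_params", params = unclass(result))
  } else if (inherits(result, "te_result")) {
    list(type = "te_result", te_bits = result$te_bits,
         p_value = result$p_value, n_permutations = result$n_permutations,
         direction = as.list(result$direction), lag = result$lag)
  } else if (inherits(result, "sdm_fit")) {
    list(type = "sdm_fit", params = unclass(result$params),
         tstats = as.list(result$tstats), se = as.list(result$se),
         loglik = result$loglik, n_obs = result$n_obs,
         converged = result$converged,
         rho_bounds = unclass(result$rho_bounds),
         z_columns = result$z_columns)
  } else stop("unsupported result type", call. = FALSE)
  payload <- c(list(schema_version = 1L), payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a result object written by [write_results()]
#'
#' @param path JSON file path.
#' @return The reconstructed object.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("unknown results schema", call. = FALSE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  switch(x$type,
    model_params = do.call(model_params, lapply(x$params, num)),
    te_result = {
      out <- te_result(num(x$te_bits), num(x$p_value),
                       as.integer(x$n_permutations),
                       unlist(x$direction), as.integer(x$lag))
      out
    },
    sdm_fit = structure(
      list(params = do.call(model_params, lapply(x$params, num)),
           tstats = vapply(x$tstats, num, numeric(1)),
           se = vapply(x$se, num, numeric(1)),
           vcov = NULL, loglik = num(x$loglik),
           n_obs = as.integer(x$n_obs),
           converged = isTRUE(x$converged),
           rho_bounds = vapply(x$rho_bounds, num, numeric(1)),
           z_columns = unlist(x$z_columns)),
      class = "sdm_fit"),
    stop("unsupported result type: ", x$type, call. = FALSE))
}
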