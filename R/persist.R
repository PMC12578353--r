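#' Persist weight matrices and rate traces as plain text
#'
#' Weight matrices are written as CSV (one row per unit) with the
#' generative parameters in a JSON sidecar; rate traces as CSV (columns =
#' timepoints would be unwieldy, so one row per timepoint, one column per
#' unit) with sampling metadata in the sidecar. Both round-trip exactly
#' up to numeric text precision.
#'
#' @param W A `weight_matrix`.
#' @param traces A `rate_traces`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly; readers return the reconstructed object.
#' @export
write_weights <- function(W, path) {
  stopifnot(inherits(W, "weight_matrix"))
  utils::write.csv(W$weights, path, row.names = FALSE)
  meta <- unclass(W$params)
  meta$realized_sparseness <- W$realized_sparseness
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- as.matrix(utils::read.csv(path))
  dimnames(w) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"))
  params <- network_params(meta$n_units, meta$sparseness, meta$conn_mean,
                           meta$conn_sd, meta$gain, meta$tau, meta$dt,
                           seed = meta$seed)
  structure(list(weights = w, params = params,
                 realized_sparseness = meta$realized_sparseness),
            class = "weight_matrix")
}

#' @rdname write_weights
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "rate_traces"))
  utils::write.csv(t(traces$values), path, row.names = FALSE)
  meta <- list(fs = traces$fs, t_start = traces$t_start,
               input_meta = traces$input_meta,
               params = unclass(traces$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_traces <- function(path) {
  v <- t(as.matrix(utils::read.csv(path)))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"))
  p <- meta$params
  structure(list(values = v, fs = meta$fs, t_start = meta$t_start,
                 params = network_params(p$n_units, p$sparseness,
                                         p$conn_mean, p$conn_sd, p$gain,
                                         p$tau, p$dt, seed = p$seed),
                 input_meta = meta$input_meta),
            class = "rate_traces")
}
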