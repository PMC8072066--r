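# JSON model configuration: topology, rates (per day), initial state and
# label designs, round-tripping losslessly.

#' Write and read model configurations
#'
#' Serializes topology, kinetic rates (with their proliferation/death
#' split when available), initial compartment sizes and per-label initial
#' frequencies to JSON, at full double precision so that a write/read
#' cycle reproduces the object exactly.
#'
#' @param rates A [kinetic_rates] object.
#' @param n0 Initial expected counts.
#' @param f0 Optional named list of per-label initial-frequency vectors.
#' @param path File path.
#' @return `model_config_write()`: `path`, invisibly.
#'   `model_config_read()`: a list with elements `rates`, `n0`, `f0`.
#' @export
model_config_write <- function(rates, n0, f0 = NULL, path) {
  cfg <- list(
    time_unit = "day",
    compartments = rates$topology$compartments,
    alpha = rates$alpha, beta = rates$beta,
    lambda = rates$lambda, delta = rates$delta,
    n0 = as.numeric(n0), f0 = f0)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname model_config_write
#' @export
model_config_read <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- model_topology(cfg$compartments)
  rates <- if (!is.null(cfg$lambda) && !is.null(cfg$delta))
    kinetic_rates(cfg$alpha, lambda = cfg$lambda, delta = cfg$delta,
                  topology = topo)
  else kinetic_rates(cfg$alpha, beta = cfg$beta, topology = topo)
  f0 <- cfg$f0
  if (!is.null(f0)) f0 <- lapply(f0, as.numeric)
  list(rates = rates, n0 = as.numeric(cfg$n0), f0 = f0)
}
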