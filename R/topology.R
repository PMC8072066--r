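#' Compartment topology of the differentiation chain
#'
#' The model is a linear (acyclic) chain of compartments in
#' upstream-to-downstream order; compartment `i - 1` feeds compartment `i`
#' and the first compartment has no parent. The default four-compartment
#' chain splits the flow-cytometric HSC gate into two hidden
#' subcompartments, HSC-U (upstream, near-quiescent) and HSC-D
#' (downstream, active), followed by ST-HSC and MPP.
#'
#' @param compartments Character vector of unique compartment names in
#'   upstream-to-downstream order.
#' @return An object of class `hsc_topology`.
#' @examples
#' default_topology()
#' @export
model_topology <- function(compartments) {
  if (!is.character(compartments) || length(compartments) < 1L)
    stop("`compartments` must be a non-empty character vector")
  if (anyDuplicated(compartments))
    stop("compartment names must be unique")
  structure(list(compartments = compartments,
                 K = length(compartments)),
            class = "hsc_topology")
}

#' @rdname model_topology
#' @export
default_topology <- function() {
  model_topology(c("HSC-U", "HSC-D", "ST-HSC", "MPP"))
}

#' @export
print.hsc_topology <- function(x, ...) {
  cat("Linear differentiation chain:",
      paste(x$compartments, collapse = " -> "), "\n")
  invisible(x)
}

# indices of the two hidden subcompartments forming the observed HSC gate
hsc_gate_indices <- function(topology) {
  idx <- match(c("HSC-U", "HSC-D"), topology$compartments)
  if (anyNA(idx))
    stop("topology does not contain the HSC-U/HSC-D subcompartments")
  idx
}
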