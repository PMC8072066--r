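# Mapping from model-internal compartments to flow-cytometric observables.
# The HSC-U/HSC-D split is not resolvable by surface markers, so the
# observed HSC gate is always the aggregate of the two subcompartments.

#' Aggregate the hidden HSC subcompartments into the observed HSC gate
#'
#' The observed HSC count is \eqn{n_U + n_D} and the observed HSC labeled
#' frequency the count-weighted mixture
#' \eqn{(f_U n_U + f_D n_D) / (n_U + n_D)}.
#'
#' @param traj An `hsc_trajectory` whose topology contains HSC-U and HSC-D
#'   (frequencies `f` required for the frequency output).
#' @return A `data.frame` with columns `time`, `n_hsc`, and (if `f` is
#'   present) `f_hsc`.
#' @export
aggregate_hsc_observable <- function(traj) {
  idx <- hsc_gate_indices(traj$topology)
  n_hsc <- rowSums(traj$n[, idx, drop = FALSE])
  if (any(n_hsc == 0))
    stop("aggregate HSC count is zero at t = ",
         traj$times[which(n_hsc == 0)[1]])
  out <- data.frame(time = traj$times, n_hsc = n_hsc)
  if (!is.null(traj$f)) {
    l_hsc <- if (!is.null(traj$l)) rowSums(traj$l[, idx, drop = FALSE])
             else rowSums(traj$f[, idx, drop = FALSE] *
                          traj$n[, idx, drop = FALSE])
    out$f_hsc <- l_hsc / n_hsc
  }
  out
}

#' Normalize downstream labeled frequencies to the observed HSC gate
#'
#' ST-HSC and MPP labeled frequencies divided by the aggregate observed-HSC
#' labeled frequency at the same time point. Time points where the HSC
#' frequency is zero are masked (`NA`) and flagged with a warning.
#'
#' @param traj An `hsc_trajectory` with frequencies, on the default
#'   four-compartment topology.
#' @return A `data.frame` with columns `time`, `f_hsc`, `f_st_norm`,
#'   `f_mpp_norm`, with an attribute `masked` listing masked time points.
#' @export
normalize_to_hsc <- function(traj) {
  if (is.null(traj$f))
    stop("trajectory carries no labeled frequencies")
  agg <- aggregate_hsc_observable(traj)
  st <- match("ST-HSC", traj$topology$compartments)
  mpp <- match("MPP", traj$topology$compartments)
  if (is.na(st) || is.na(mpp))
    stop("topology must contain ST-HSC and MPP")
  zero <- agg$f_hsc == 0
  denom <- ifelse(zero, NA_real_, agg$f_hsc)
  if (any(zero))
    warning("HSC labeled frequency is zero at ", sum(zero),
            " time point(s); normalized values masked")
  out <- data.frame(time = traj$times, f_hsc = agg$f_hsc,
                    f_st_norm = traj$f[, st] / denom,
                    f_mpp_norm = traj$f[, mpp] / denom)
  attr(out, "masked") <- traj$times[zero]
  out
}
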