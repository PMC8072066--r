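#' Per-compartment kinetic rates
#'
#' Each compartment `i` carries a differentiation rate `alpha_i` (flux to
#' compartment `i + 1`, per day, non-negative) and a net proliferation rate
#' `beta_i` (per day, any sign). `beta_i` may alternatively be supplied as a
#' proliferation/death split `lambda_i - delta_i`. The derived inverse
#' residence time is `kappa_i = alpha_i - beta_i`: the decay rate of the
#' compartment content if its influx were switched off, so small `kappa`
#' means strong self-renewal.
#'
#' @param alpha Differentiation rates, length-K numeric, per day, `>= 0`.
#' @param beta Net proliferation rates (per day). Omit when `lambda` and
#'   `delta` are given.
#' @param lambda,delta Optional proliferation and death rates (per day,
#'   `>= 0`); when supplied, `beta = lambda - delta`.
#' @param topology An `hsc_topology`; defaults to the four-compartment chain.
#' @return An object of class `kinetic_rates` with fields `alpha`, `beta`,
#'   `kappa`, and (when available) `lambda`, `delta`.
#' @examples
#' kinetic_rates(alpha = c(0.01, 0.1), beta = c(0, 0.02),
#'               topology = model_topology(c("HSC-U", "HSC-D")))
#' @export
kinetic_rates <- function(alpha, beta = NULL, lambda = NULL, delta = NULL,
                          topology = default_topology()) {
  K <- topology$K
  alpha <- as.numeric(alpha)
  if (length(alpha) != K)
    stop("`alpha` must have one entry per compartment (K = ", K, ")")
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("`alpha` must be finite and non-negative")
  has_split <- !is.null(lambda) && !is.null(delta)
  if (has_split) {
    lambda <- as.numeric(lambda); delta <- as.numeric(delta)
    if (length(lambda) != K || length(delta) != K)
      stop("`lambda` and `delta` must have length K = ", K)
    if (any(!is.finite(lambda)) || any(lambda < 0) ||
        any(!is.finite(delta)) || any(delta < 0))
      stop("`lambda` and `delta` must be finite and non-negative")
    beta_split <- lambda - delta
    if (!is.null(beta) && max(abs(beta - beta_split)) > 1e-12 * max(1, max(abs(beta))))
      stop("`beta` inconsistent with `lambda - delta`")
    beta <- beta_split
  }
  if (is.null(beta))
    stop("supply `beta` or both `lambda` and `delta`")
  beta <- as.numeric(beta)
  if (length(beta) != K || any(!is.finite(beta)))
    stop("`beta` must be finite with length K = ", K)
  out <- list(alpha = alpha, beta = beta, kappa = alpha - beta,
              topology = topology)
  if (has_split) {
    out$lambda <- lambda
    out$delta <- delta
  }
  structure(out, class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, digits = 4, ...) {
  cat("Kinetic rates (per day; per-week values in brackets)\n")
  tab <- data.frame(
    compartment = x$topology$compartments,
    alpha = signif(x$alpha, digits),
    alpha_per_week = signif(7 * x$alpha, digits),
    beta = signif(x$beta, digits),
    kappa = signif(x$kappa, digits),
    kappa_per_week = signif(7 * x$kappa, digits))
  if (!is.null(x$lambda)) {
    tab$lambda <- signif(x$lambda, digits)
    tab$delta <- signif(x$delta, digits)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Initial model state
#'
#' Expected cell counts per compartment at the effective induction time,
#' plus the initial labeled frequency per compartment for one labeling
#' design (Cre driver).
#'
#' @param n0 Initial expected counts, length-K, `>= 0`.
#' @param f0 Initial labeled frequencies, length-K, in `[0, 1]`.
#' @param topology An `hsc_topology`.
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(n0, f0 = rep(0, length(n0)),
                          topology = default_topology()) {
  K <- topology$K
  n0 <- as.numeric(n0); f0 <- as.numeric(f0)
  if (length(n0) != K || any(!is.finite(n0)) || any(n0 < 0))
    stop("`n0` must be finite, non-negative, length K = ", K)
  if (length(f0) != K || any(!is.finite(f0)) || any(f0 < 0) || any(f0 > 1))
    stop("`f0` must lie in [0, 1], length K = ", K)
  structure(list(n0 = n0, f0 = f0, topology = topology),
            class = "initial_state")
}

#' Reference kinetics and state used by the synthetic-cohort generator
#'
#' A single fixed parameter set embodying the qualitative picture of
#' unperturbed adult mouse hematopoiesis that the package models: a small,
#' near-quiescent, slowly expanding HSC-U pool (about 1 in 50 cells
#' differentiating per week, slightly negative `kappa`), an active HSC-D
#' pool differentiating roughly weekly, self-renewing downstream
#' progenitors (small `kappa` for MPP), and compartment sizes near flux
#' balance that grow going downstream (HSC-U at least five-fold smaller
#' than HSC-D). The proliferation/death split is included so that
#' leukemogenesis scenarios (which act on `lambda`) can run on the same
#' parameter set.
#'
#' @return `default_rates()`: a `kinetic_rates`; `default_initial_counts()`:
#'   numeric length-4 vector of expected compartment sizes (cells).
#' @export
default_rates <- function() {
  alpha <- c(0.003, 0.14, 0.03, 0.25)
  kappa <- c(-0.002, 0.0005, 0.037, 0.009)
  beta <- alpha - kappa
  delta <- c(0.002, 0.010, 0.020, 0.020)
  kinetic_rates(alpha = alpha, lambda = beta + delta, delta = delta)
}

#' @rdname default_rates
#' @export
default_initial_counts <- function() {
  c(400, 2400, 9000, 30000)
}
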