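# Analytic solution of the linear cascade (sum of exponentials).
# Valid for pairwise-distinct kappa; ties are either perturbed by a tiny
# offset (default, with a warning) or rejected.

perturb_degenerate <- function(kappa, tol) {
  k <- kappa
  repeat {
    d <- abs(outer(k, k, "-"))
    diag(d) <- Inf
    if (min(d) >= tol) break
    tie <- which(d < tol, arr.ind = TRUE)[1, ]
    k[tie[1]] <- k[tie[1]] + 1e-9
  }
  k
}

cascade_core <- function(kappa, alpha, y0, times, tol = 1e-9,
                         degenerate = c("perturb", "error"), quiet = FALSE) {
  degenerate <- match.arg(degenerate)
  d <- abs(outer(kappa, kappa, "-"))
  diag(d) <- Inf
  if (min(d) < tol) {
    if (degenerate == "error")
      stop("degenerate spectrum: repeated kappa within tolerance ", tol)
    if (!quiet)
      warning("degenerate spectrum: tied kappa perturbed by 1e-9")
    kappa <- perturb_degenerate(kappa, tol)
  }
  cascade_solve_cpp(kappa, alpha, y0, times)
}

#' Closed-form solution of the linear cascade
#'
#' Analytic solution of the population equations
#' \deqn{dn_1/dt = -\kappa_1 n_1, \quad
#'       dn_i/dt = \alpha_{i-1} n_{i-1} - \kappa_i n_i}
#' as a sum of exponentials, exact when all inverse residence times
#' `kappa_i` are pairwise distinct. Serves as the analytic oracle for the
#' numerical integrator and as the fast model-evaluation path.
#'
#' @param rates A [kinetic_rates] object.
#' @param init An [initial_state] object.
#' @param times Numeric grid starting at 0 (days).
#' @param degenerate How to treat tied `kappa` within `tol`: `"perturb"`
#'   (offset by 1e-9 with a warning) or `"error"` (reject with a
#'   degenerate-spectrum error).
#' @param tol Tie tolerance for the spectrum.
#' @return An `hsc_trajectory` with expected counts `n`.
#' @examples
#' tr <- closed_form_cascade(default_rates(),
#'                           initial_state(default_initial_counts()),
#'                           times = seq(0, 280, by = 14))
#' head(as.data.frame(tr))
#' @export
closed_form_cascade <- function(rates, init, times,
                                degenerate = c("perturb", "error"),
                                tol = 1e-9) {
  times <- check_times(times)
  n <- cascade_core(rates$kappa, rates$alpha, init$n0, times,
                    tol = tol, degenerate = match.arg(degenerate))
  new_trajectory(times, n, topology = rates$topology)
}

# Fast internal path used by the fitting machinery: n(t) and l(t) from the
# analytic cascade, f = l / n. Ties in kappa are perturbed silently (the
# optimizer may transiently propose them).
model_curves <- function(kappa, alpha, n0, f0, times) {
  d <- abs(outer(kappa, kappa, "-"))
  diag(d) <- Inf
  if (min(d) < 1e-9) kappa <- perturb_degenerate(kappa, 1e-9)
  n <- cascade_solve_cpp(kappa, alpha, n0, times)
  l <- cascade_solve_cpp(kappa, alpha, f0 * n0, times)
  list(n = n, l = l, f = l / n)
}
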