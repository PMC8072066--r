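# Numerical integration of the population, labeled-count and
# label-frequency dynamics with deSolve. The stiff-capable lsoda default
# and tight tolerances (1e-9/1e-12) cover kappa values spanning orders of
# magnitude.

ode_solve <- function(y0, times, func, parms, rtol = 1e-9, atol = 1e-12,
                      method = "lsoda") {
  out <- deSolve::ode(y = y0, times = times, func = func, parms = parms,
                      method = method, rtol = rtol, atol = atol)
  if (anyNA(out) || nrow(out) < length(times)) {
    diag_txt <- attr(out, "istate")
    stop("ODE solver failed (istate = ",
         paste(diag_txt, collapse = ","), ")")
  }
  unname(out[, -1, drop = FALSE])
}

#' Solve the population dynamics numerically
#'
#' Integrates the expected-count equations of the linear chain,
#' \eqn{dn_1/dt = -(\alpha_1-\beta_1) n_1} and
#' \eqn{dn_i/dt = \alpha_{i-1} n_{i-1} - (\alpha_i-\beta_i) n_i},
#' with a stiff-capable integrator. The analytic counterpart is
#' [closed_form_cascade()].
#'
#' @inheritParams closed_form_cascade
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param method deSolve integration method.
#' @return An `hsc_trajectory` with expected counts `n`.
#' @export
solve_populations <- function(rates, init, times, rtol = 1e-9, atol = 1e-12,
                              method = "lsoda") {
  times <- check_times(times)
  check_dims(rates, init)
  K <- rates$topology$K
  parms <- list(kappa = rates$kappa, alpha = rates$alpha, K = K)
  deriv <- function(t, y, p) {
    influx <- c(0, p$alpha[-p$K] * y[-p$K])
    list(influx - p$kappa * y)
  }
  n <- ode_solve(init$n0, times, deriv, parms, rtol, atol, method)
  new_trajectory(times, n, topology = rates$topology)
}

#' Solve the labeled-count dynamics numerically
#'
#' Labeled cells follow the same kinetics as the whole population, so the
#' expected labeled counts \eqn{l_{A,i}(t)} obey the cascade equations with
#' initial condition \eqn{l(0) = f(0) \cdot n(0)}. Returns counts, labeled
#' counts and their ratio `f = l/n`.
#'
#' @inheritParams solve_populations
#' @param label Optional label/dataset identifier recorded on the result.
#' @return An `hsc_trajectory` with `n`, `l`, and `f`.
#' @export
solve_labeled_counts <- function(rates, init, times, label = NULL,
                                 rtol = 1e-9, atol = 1e-12, method = "lsoda") {
  times <- check_times(times)
  check_dims(rates, init)
  K <- rates$topology$K
  parms <- list(kappa = rates$kappa, alpha = rates$alpha, K = K)
  deriv <- function(t, y, p) {
    n <- y[seq_len(p$K)]
    l <- y[p$K + seq_len(p$K)]
    dn <- c(0, p$alpha[-p$K] * n[-p$K]) - p$kappa * n
    dl <- c(0, p$alpha[-p$K] * l[-p$K]) - p$kappa * l
    list(c(dn, dl))
  }
  y <- ode_solve(c(init$n0, init$f0 * init$n0), times, deriv, parms,
                 rtol, atol, method)
  n <- y[, seq_len(K), drop = FALSE]
  l <- y[, K + seq_len(K), drop = FALSE]
  f <- l / n
  tr <- new_trajectory(times, n, l, f, topology = rates$topology)
  tr$label <- label
  tr
}

#' Solve the label-frequency dynamics numerically
#'
#' Integrates the frequency form of the label dynamics,
#' \eqn{df_1/dt = 0} and
#' \eqn{df_i/dt = \alpha_{i-1}\,(n_{i-1}/n_i)\,(f_{i-1} - f_i)},
#' jointly with the population equations. This is the numerically stable
#' route when counts get small; `l` is reconstructed as `f * n`.
#'
#' @inheritParams solve_labeled_counts
#' @return An `hsc_trajectory` with `n`, `l`, and `f`.
#' @export
solve_label_frequencies <- function(rates, init, times, label = NULL,
                                    rtol = 1e-9, atol = 1e-12,
                                    method = "lsoda") {
  times <- check_times(times)
  check_dims(rates, init)
  K <- rates$topology$K
  if (any(init$n0 <= 0))
    stop("non-positive population in compartment '",
         rates$topology$compartments[which(init$n0 <= 0)[1]],
         "' at t = 0; frequencies undefined")
  parms <- list(kappa = rates$kappa, alpha = rates$alpha, K = K)
  deriv <- function(t, y, p) {
    n <- y[seq_len(p$K)]
    f <- y[p$K + seq_len(p$K)]
    dn <- c(0, p$alpha[-p$K] * n[-p$K]) - p$kappa * n
    df <- c(0, p$alpha[-p$K] * (n[-p$K] / n[-1]) * (f[-p$K] - f[-1]))
    list(c(dn, df))
  }
  y <- ode_solve(c(init$n0, init$f0), times, deriv, parms,
                 rtol, atol, method)
  n <- y[, seq_len(K), drop = FALSE]
  f <- y[, K + seq_len(K), drop = FALSE]
  bad <- which(n <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive population in compartment '",
         rates$topology$compartments[bad[1, 2]], "' at t = ",
         times[bad[1, 1]], " days; frequencies undefined")
  }
  tr <- new_trajectory(times, n, l = f * n, f = f, topology = rates$topology)
  tr$label <- label
  tr
}

#' Homogeneous steady-state label-propagation model
#'
#' The classical three-compartment description (HSC, ST-HSC, MPP) with
#' constant compartment sizes: under the steady-state constraint
#' \eqn{\alpha_{i-1} n_{i-1} = \kappa_i n_i} the frequency dynamics reduce
#' to the pure relaxation \eqn{df_i/dt = \kappa_i (f_{i-1} - f_i)} with the
#' HSC frequency constant. With HSCs initially labeled and downstream
#' compartments unlabeled, every downstream normalized frequency relaxes to
#' 1, which is the behavior this model cannot reconcile with a downstream
#' plateau below 1.
#'
#' @param kappa Inverse residence times, length 3; entries 2..3 must be
#'   positive (a steady state with positive influx requires `kappa > 0`).
#'   `kappa[1]` is unused by the frequency dynamics and may be `NA`.
#' @param f0 Initial labeled frequencies `(HSC, ST-HSC, MPP)`, in `[0, 1]`.
#' @param times Time grid starting at 0 (days).
#' @param rtol,atol Solver tolerances.
#' @return A `data.frame` with columns `time`, `f_hsc`, `f_st`, `f_mpp`,
#'   `f_st_norm`, `f_mpp_norm` (the latter scaled to the HSC frequency).
#' @examples
#' ss <- steady_state_model(kappa = c(NA, 0.1, 0.1), f0 = c(0.3, 0, 0),
#'                          times = seq(0, 1000, by = 10))
#' tail(ss, 1)
#' @export
steady_state_model <- function(kappa, f0, times, rtol = 1e-9, atol = 1e-12) {
  times <- check_times(times)
  if (length(kappa) != 3 || length(f0) != 3)
    stop("steady-state model has three compartments (HSC, ST-HSC, MPP)")
  if (any(!is.finite(kappa[2:3])) || any(kappa[2:3] <= 0))
    stop("steady state with positive influx requires kappa > 0 downstream")
  if (any(f0 < 0) || any(f0 > 1)) stop("`f0` must lie in [0, 1]")
  deriv <- function(t, y, p) {
    list(c(0, p[2] * (y[1] - y[2]), p[3] * (y[2] - y[3])))
  }
  y <- ode_solve(f0, times, deriv, kappa, rtol, atol)
  data.frame(time = times, f_hsc = y[, 1], f_st = y[, 2], f_mpp = y[, 3],
             f_st_norm = y[, 2] / y[, 1], f_mpp_norm = y[, 3] / y[, 1])
}

check_dims <- function(rates, init) {
  if (rates$topology$K != init$topology$K ||
      !identical(rates$topology$compartments, init$topology$compartments))
    stop("rates and initial state refer to different topologies")
  invisible(TRUE)
}
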