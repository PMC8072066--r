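# Mutant-clone expansion: a single founder cell in compartment s whose
# proliferation rate (and that of all downstream progeny) is scaled by a
# factor x >= 1. The mutant lineage follows the same linear cascade with
# modified inverse residence times kappa_i^mut = alpha_i - (x lambda_i -
# delta_i) for i >= s; its long-run fate is governed by the dominant
# eigenvalue -min_{i>=s} kappa_i^mut.

#' Mutation scenario
#'
#' @param origin Origin compartment: index or name (e.g. `"HSC-D"`).
#' @param factor Proliferation factor `x >= 1` applied to `lambda_i` for
#'   the origin and all downstream compartments.
#' @param m0 Initial mutant load in the origin (cells; default a single
#'   founder cell).
#' @param topology An `hsc_topology`.
#' @return An object of class `mutation_scenario`.
#' @export
mutation_scenario <- function(origin, factor = 1, m0 = 1,
                              topology = default_topology()) {
  s <- if (is.character(origin)) match(origin, topology$compartments)
       else as.integer(origin)
  if (is.na(s) || s < 1 || s > topology$K)
    stop("unknown origin compartment")
  if (!is.finite(factor) || factor < 1)
    stop("proliferation factor must be >= 1")
  if (!is.finite(m0) || m0 < 0) stop("`m0` must be non-negative")
  structure(list(s = s, factor = factor, m0 = m0, topology = topology),
            class = "mutation_scenario")
}

check_split <- function(rates, s) {
  if (is.null(rates$lambda) || is.null(rates$delta))
    stop("mutation scenarios need the lambda/delta split of the ",
         "proliferation rate for compartments >= the origin")
  invisible(TRUE)
}

#' Kinetic rates of the mutant lineage
#'
#' Applies the proliferation factor: for compartments at or downstream of
#' the origin, `lambda` becomes `x * lambda`, so
#' `kappa^mut = alpha - (x * lambda - delta)`; upstream compartments are
#' untouched (they never carry mutants).
#'
#' @param rates Wild-type [kinetic_rates] with `lambda`/`delta` split.
#' @param scenario A [mutation_scenario].
#' @return A `kinetic_rates` for the mutant lineage.
#' @export
apply_mutation <- function(rates, scenario) {
  check_split(rates, scenario$s)
  lam <- rates$lambda
  idx <- seq(scenario$s, rates$topology$K)
  lam[idx] <- scenario$factor * lam[idx]
  kinetic_rates(rates$alpha, lambda = lam, delta = rates$delta,
                topology = rates$topology)
}

#' Solve the mutant-clone dynamics
#'
#' The mutant subsystem starts at the origin (upstream compartments carry
#' no mutants): \eqn{dm_s/dt = -\kappa_s^{mut} m_s} and
#' \eqn{dm_i/dt = \alpha_{i-1} m_{i-1} - \kappa_i^{mut} m_i} for
#' \eqn{i > s}. At `factor = 1` this system coincides with the
#' labeled-count dynamics.
#'
#' @param rates Wild-type [kinetic_rates] with `lambda`/`delta`.
#' @param scenario A [mutation_scenario].
#' @param times Time grid starting at 0 (days).
#' @param method `"analytic"` (closed-form cascade) or `"ode"`.
#' @param rtol,atol Solver tolerances for the `"ode"` route.
#' @return Matrix of mutant counts, one column per compartment (zero
#'   upstream of the origin).
#' @export
solve_mutant <- function(rates, scenario, times,
                         method = c("analytic", "ode"),
                         rtol = 1e-9, atol = 1e-12) {
  method <- match.arg(method)
  times <- check_times(times)
  mut <- apply_mutation(rates, scenario)
  K <- rates$topology$K
  idx <- seq(scenario$s, K)
  y0 <- c(scenario$m0, rep(0, length(idx) - 1))
  m_sub <- if (method == "analytic") {
    cascade_core(mut$kappa[idx], mut$alpha[idx], y0, times, quiet = TRUE)
  } else {
    sub_topo <- model_topology(rates$topology$compartments[idx])
    sub_rates <- kinetic_rates(mut$alpha[idx], beta = mut$beta[idx],
                               topology = sub_topo)
    solve_populations(sub_rates,
                      initial_state(y0, topology = sub_topo), times,
                      rtol = rtol, atol = atol)$n
  }
  m <- matrix(0, nrow = length(times), ncol = K,
              dimnames = list(NULL, rates$topology$compartments))
  m[, idx] <- m_sub
  m
}

#' Mutant fraction of the MPP pool
#'
#' \eqn{p(t) = m_K(t) / n_K(t)}: the mutant MPP count relative to the MPP
#' pool. By default the denominator is the wild-type MPP trajectory (the
#' printed definition, where `p` may exceed 1 for expanding clones);
#' `include_mutants = TRUE` adds the mutant count to the denominator for a
#' bounded fraction.
#'
#' @param rates Wild-type [kinetic_rates] with `lambda`/`delta`.
#' @param scenario A [mutation_scenario].
#' @param n0 Wild-type initial compartment counts.
#' @param times Time grid starting at 0 (days).
#' @param include_mutants Add mutants to the denominator (default FALSE).
#' @return A `data.frame` with `time`, `m_mpp`, `n_mpp`, `p`.
#' @export
mutant_mpp_fraction <- function(rates, scenario, n0 = default_initial_counts(),
                                times, include_mutants = FALSE) {
  times <- check_times(times)
  K <- rates$topology$K
  m <- solve_mutant(rates, scenario, times)
  n <- cascade_core(rates$kappa, rates$alpha, n0, times, quiet = TRUE)
  if (any(n[, K] <= 0))
    stop("wild-type MPP pool vanishes at t = ",
         times[which(n[, K] <= 0)[1]])
  denom <- if (include_mutants) n[, K] + m[, K] else n[, K]
  data.frame(time = times, m_mpp = m[, K], n_mpp = n[, K],
             p = m[, K] / denom)
}

mutant_kappa <- function(rates, s, x) {
  kap <- rates$kappa
  idx <- seq(s, rates$topology$K)
  kap[idx] <- rates$alpha[idx] - (x * rates$lambda[idx] - rates$delta[idx])
  kap
}

#' Closed-form immortality threshold
#'
#' The mutant subsystem's eigenvalues are \eqn{-\kappa_i^{mut}} for
#' \eqn{i \ge s}, so the clone persists (neither washes out of the MPP
#' pool nor decays) exactly when \eqn{\min_{i \ge s} \kappa_i^{mut} \le 0}.
#' The minimal factor achieving this is
#' \deqn{x^* = \min_{i \ge s} (\alpha_i + \delta_i) / \lambda_i,}
#' clamped at 1 from below (compartments with `lambda_i = 0` cannot be
#' pushed and are excluded). Also reports the compartment attaining the
#' minimum.
#'
#' @param rates Wild-type [kinetic_rates] with `lambda`/`delta`.
#' @param origin Origin compartment (index or name).
#' @return A list: `x_star`, `critical_compartment`, and `at_one` (TRUE
#'   when the origin lineage is already self-sustaining at `x = 1`).
#' @export
threshold_closed_form <- function(rates, origin) {
  topo <- rates$topology
  s <- if (is.character(origin)) match(origin, topo$compartments)
       else as.integer(origin)
  if (is.na(s) || s < 1 || s > topo$K) stop("unknown origin compartment")
  check_split(rates, s)
  idx <- seq(s, topo$K)
  ratio <- ifelse(rates$lambda[idx] > 0,
                  (rates$alpha[idx] + rates$delta[idx]) / rates$lambda[idx],
                  Inf)
  if (all(is.infinite(ratio)))
    stop("no finite threshold: lambda = 0 for every compartment >= origin")
  j <- which.min(ratio)
  x_star <- ratio[j]
  at_one <- x_star <= 1
  list(x_star = max(1, x_star),
       critical_compartment = topo$compartments[idx[j]],
       at_one = at_one)
}

#' Immortality threshold by bisection
#'
#' Minimal proliferation factor `x` for which the mutant lineage neither
#' washes out nor explodes: bisection on the dominant decay rate
#' \eqn{g(x) = \min_{i \ge s} \kappa_i^{mut}(x)}, which is strictly
#' decreasing in `x` wherever `lambda > 0`, until `|g| <= tol`. Returns
#' `x = 1` immediately when the lineage is already self-sustaining
#' (`g(1) <= 0`, e.g. an expanding origin compartment).
#'
#' @param rates Wild-type [kinetic_rates] with `lambda`/`delta`.
#' @param origin Origin compartment (index or name).
#' @param tol Tolerance on the dominant decay rate (per day).
#' @param x_max Upper limit of the search range.
#' @return A list: `x_star`, `critical_compartment`, `g` (residual decay
#'   rate at the returned factor), `at_one`.
#' @export
find_immortal_threshold <- function(rates, origin, tol = 1e-6, x_max = 100) {
  topo <- rates$topology
  s <- if (is.character(origin)) match(origin, topo$compartments)
       else as.integer(origin)
  if (is.na(s) || s < 1 || s > topo$K) stop("unknown origin compartment")
  check_split(rates, s)
  idx <- seq(s, topo$K)
  g <- function(x) min(mutant_kappa(rates, s, x)[idx])
  if (g(1) <= 0) {
    kap1 <- mutant_kappa(rates, s, 1)[idx]
    return(list(x_star = 1,
                critical_compartment = topo$compartments[idx[which.min(kap1)]],
                g = g(1), at_one = TRUE))
  }
  if (g(x_max) > 0)
    stop("no finite threshold within the search range [1, ", x_max, "]")
  lo <- 1; hi <- x_max
  while (TRUE) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) <= tol || (hi - lo) < 1e-12) break
    if (gm > 0) lo <- mid else hi <- mid
  }
  kapm <- mutant_kappa(rates, s, mid)[idx]
  list(x_star = mid,
       critical_compartment = topo$compartments[idx[which.min(kapm)]],
       g = gm, at_one = FALSE)
}

#' Mutant-fraction scenario table
#'
#' Convenience driver: mutant MPP fraction trajectories for a grid of
#' origins and proliferation factors (defaults: weak 1.03, moderate 1.08,
#' strong 1.15 over a 60-week horizon).
#'
#' @param rates Wild-type [kinetic_rates] with `lambda`/`delta`.
#' @param n0 Wild-type initial counts.
#' @param origins Origin compartments (names).
#' @param factors Proliferation factors.
#' @param horizon_days Simulation horizon (days).
#' @param by_days Output step (days).
#' @param include_mutants Denominator convention, see
#'   [mutant_mpp_fraction()].
#' @return A long `data.frame`: origin, factor, time, p.
#' @export
leukemogenesis_scan <- function(rates, n0 = default_initial_counts(),
                                origins = rates$topology$compartments,
                                factors = c(1.03, 1.08, 1.15),
                                horizon_days = 420, by_days = 7,
                                include_mutants = FALSE) {
  times <- seq(0, horizon_days, by = by_days)
  out <- list()
  for (org in origins) {
    for (x in factors) {
      sc <- mutation_scenario(org, x, topology = rates$topology)
      p <- mutant_mpp_fraction(rates, sc, n0, times, include_mutants)
      out[[length(out) + 1]] <- data.frame(origin = org, factor = x,
                                           time = times, p = p$p)
    }
  }
  do.call(rbind, out)
}
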