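# Profile-likelihood machinery: per-parameter confidence intervals,
# profiles of derived quantities (penalty method), prediction profile
# bands, and labeling-specificity ratios.

PROFILE_DELTA <- function(level) stats::qchisq(level, df = 1)

reoptimize <- function(objfun, warm, lower, upper,
                       control = list(iter.max = 60, eval.max = 300,
                                      rel.tol = 1e-5)) {
  if (length(warm) == 0)
    return(list(objective = objfun(numeric(0)), par = numeric(0)))
  res <- tryCatch(
    stats::nlminb(warm, objfun, lower = lower, upper = upper,
                  control = control),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  list(objective = res$objective, par = res$par)
}

# Walk one parameter (transformed scale) away from the optimum,
# re-optimizing all others warm-started from the previous profile point,
# until the profiled objective crosses best + delta (bound found by
# linear interpolation) or the parameter's box edge is hit (side
# unbounded within the searched range).
profile_walk <- function(obj_free, theta_free_hat, ssr_hat, j, lower, upper,
                         delta, direction, step_init = 0.1, max_steps = 30) {
  pos <- theta_free_hat[j]
  prev_pos <- pos
  prev_ssr <- ssr_hat
  warm <- theta_free_hat[-j]
  warm_prev <- warm
  pos_prev_sol <- pos
  h <- step_init
  curve <- data.frame(theta = pos, ssr = ssr_hat)
  bound_edge <- if (direction > 0) upper[j] else lower[j]
  for (s in seq_len(max_steps)) {
    new_pos <- pos + direction * h
    at_edge <- (direction > 0 && new_pos >= bound_edge) ||
               (direction < 0 && new_pos <= bound_edge)
    if (at_edge) new_pos <- bound_edge
    objfun_j <- function(th_rest) {
      th <- numeric(length(theta_free_hat))
      th[j] <- new_pos
      th[-j] <- th_rest
      obj_free(th)
    }
    # warm start linearly extrapolated along the profile path
    warm_try <- if (pos != pos_prev_sol) {
      w <- warm + (warm - warm_prev) * (new_pos - pos) / (pos - pos_prev_sol)
      pmin(upper[-j], pmax(lower[-j], w))
    } else warm
    res <- reoptimize(objfun_j, warm_try, lower[-j], upper[-j])
    if (is.null(res)) {
      # re-optimization failure: record and step on with a smaller step
      h <- h / 2
      if (h < 1e-4) return(list(bound = new_pos, unbounded = TRUE,
                                curve = curve, failures = s))
      next
    }
    ssr <- res$objective
    if (ssr > ssr_hat + delta) {
      # overshoot: refine the step so the crossing is bracketed tightly
      # enough for linear interpolation to be accurate
      if (ssr - prev_ssr > 3 * delta && h > 1e-4 && !at_edge) {
        h <- h / 2
        next
      }
      # about to accept a crossing: verify with stronger re-optimization
      # (restart from the optimum, then a derivative-free pass), since a
      # stalled warm start would truncate the interval
      for (ws in list(res$par, theta_free_hat[-j])) {
        cand <- reoptimize(objfun_j, ws, lower[-j], upper[-j],
                           control = list(iter.max = 500, eval.max = 2000,
                                          rel.tol = 1e-8))
        if (!is.null(cand) && cand$objective < ssr) {
          ssr <- cand$objective
          res <- cand
        }
        if (ssr <= ssr_hat + delta) break
      }
      if (ssr > ssr_hat + delta && length(res$par) > 1) {
        lo_j <- lower[-j]; up_j <- upper[-j]
        for (nm_start in list(res$par, theta_free_hat[-j])) {
          nm <- tryCatch(
            stats::optim(nm_start,
                         function(th) objfun_j(pmin(up_j, pmax(lo_j, th))),
                         method = "Nelder-Mead",
                         control = list(maxit = 5000)),
            error = function(e) NULL)
          if (is.null(nm) || nm$value >= ssr) next
          cand <- reoptimize(objfun_j, pmin(up_j, pmax(lo_j, nm$par)),
                             lo_j, up_j,
                             control = list(iter.max = 500,
                                            eval.max = 2000,
                                            rel.tol = 1e-8))
          if (!is.null(cand) && cand$objective < nm$value) {
            ssr <- cand$objective
            res <- cand
          } else {
            ssr <- nm$value
            res <- list(objective = nm$value,
                        par = pmin(up_j, pmax(lo_j, nm$par)))
          }
          if (ssr <= ssr_hat + delta) break
        }
      }
      if (ssr > ssr_hat + delta) {
        # look one step beyond the apparent crossing: a locally stalled
        # re-optimization can masquerade as a bump in the profile
        ahead_pos <- new_pos + direction * h
        ahead_edge <- (direction > 0 && ahead_pos >= bound_edge) ||
                      (direction < 0 && ahead_pos <= bound_edge)
        if (!ahead_edge) {
          objfun_a <- function(th_rest) {
            th <- numeric(length(theta_free_hat))
            th[j] <- ahead_pos
            th[-j] <- th_rest
            obj_free(th)
          }
          ahead <- reoptimize(objfun_a, res$par, lower[-j], upper[-j],
                              control = list(iter.max = 500,
                                             eval.max = 2000,
                                             rel.tol = 1e-8))
          if (!is.null(ahead) && ahead$objective <= ssr_hat + delta) {
            curve <- rbind(curve,
                           data.frame(theta = ahead_pos,
                                      ssr = ahead$objective))
            prev_pos <- ahead_pos
            prev_ssr <- ahead$objective
            warm_prev <- warm
            pos_prev_sol <- pos
            pos <- ahead_pos
            warm <- ahead$par
            next
          }
        }
        curve <- rbind(curve, data.frame(theta = new_pos, ssr = ssr))
        # interpolate on the sqrt(delta-SSR) scale, exact for a locally
        # quadratic profile
        s0 <- sqrt(max(prev_ssr - ssr_hat, 0))
        s1 <- sqrt(ssr - ssr_hat)
        frac <- (sqrt(delta) - s0) / (s1 - s0)
        return(list(bound = prev_pos + (new_pos - prev_pos) * frac,
                    unbounded = FALSE, curve = curve, failures = 0))
      }
    }
    curve <- rbind(curve, data.frame(theta = new_pos, ssr = ssr))
    if (at_edge)
      return(list(bound = new_pos, unbounded = TRUE, curve = curve,
                  failures = 0))
    dssr <- ssr - prev_ssr
    if (dssr < 0.5) h <- min(h * 2, 3)
    else if (dssr > 1.5) h <- max(h * 0.6, 1e-3)
    prev_pos <- new_pos
    prev_ssr <- ssr
    warm_prev <- warm
    pos_prev_sol <- pos
    pos <- new_pos
    warm <- res$par
  }
  list(bound = pos, unbounded = TRUE, curve = curve, failures = 0)
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Scans the parameter on its transformed scale away from the best fit,
#' re-optimizing all other free parameters at each step, until the
#' profiled objective exceeds the optimum by the chi-square 1-df quantile
#' (3.84 at 95%); the crossing is located by linear interpolation. A side
#' that reaches the parameter's box edge (or the step budget) without
#' crossing is reported as unbounded. Failed re-optimizations are
#' recorded and the walk continues with a reduced step.
#'
#' @param fit An `hsc_fit` with at least the profiled parameter free.
#' @param param Parameter name (see `fit$estimates$name`).
#' @param level Confidence level (default 0.95).
#' @param step_init Initial step on the transformed scale.
#' @param max_steps Step budget per side.
#' @return A list: `estimate`, `lower`, `upper` (natural scale),
#'   `lower_unbounded`, `upper_unbounded`, and the profile `curve`
#'   (transformed position vs. profiled objective).
#' @export
profile_likelihood_ci <- function(fit, param, level = 0.95,
                                  step_init = NULL, max_steps = 30) {
  tab <- fit$spec$table
  free <- which(!tab$fixed)
  j_all <- match(param, tab$name)
  if (is.na(j_all)) stop("unknown parameter: ", param)
  if (tab$fixed[j_all]) stop("parameter is fixed: ", param)
  j <- match(j_all, free)
  tr <- tab$transform[j_all]

  obj_free <- make_objective(fit$spec, fit$fitdata)
  theta_free_hat <- fit$theta[free]
  ssr_hat <- fit$objective
  delta <- PROFILE_DELTA(level)
  lower <- mapply(trans_to, tab$lower[free], tab$transform[free])
  upper <- mapply(trans_to, tab$upper[free], tab$transform[free])
  # default step: scaled by the objective's curvature along the
  # coordinate (a raw-objective step that costs about one chi-square
  # unit), clamped to a sane range relative to the transformed box
  if (is.null(step_init)) {
    d <- min(0.05, (upper[j] - lower[j]) / 100)
    bump <- function(s) {
      th <- theta_free_hat
      th[j] <- min(upper[j], max(lower[j], th[j] + s))
      obj_free(th)
    }
    hess <- (bump(d) + bump(-d) - 2 * ssr_hat) / d^2
    step_init <- sqrt(2 / max(hess, 1e-4))
    step_init <- min(max(step_init, 2 * d), (upper[j] - lower[j]) / 8, 1.5)
  }

  lo <- profile_walk(obj_free, theta_free_hat, ssr_hat, j, lower, upper,
                     delta, -1, step_init, max_steps)
  hi <- profile_walk(obj_free, theta_free_hat, ssr_hat, j, lower, upper,
                     delta, +1, step_init, max_steps)
  curve <- rbind(lo$curve[nrow(lo$curve):1, ], hi$curve[-1, ])
  curve$value <- trans_from(curve$theta, tr)
  list(param = param,
       estimate = trans_from(fit$theta[j_all], tr),
       lower = trans_from(lo$bound, tr),
       upper = trans_from(hi$bound, tr),
       lower_unbounded = lo$unbounded,
       upper_unbounded = hi$unbounded,
       level = level, curve = curve)
}

#' Profile all (or selected) free parameters
#'
#' @param fit An `hsc_fit`.
#' @param params Parameter names; default all free parameters.
#' @param ... Passed to [profile_likelihood_ci()].
#' @return A `data.frame` with estimate, bounds and unbounded flags per
#'   parameter.
#' @export
profile_all <- function(fit, params = NULL, ...) {
  tab <- fit$spec$table
  if (is.null(params)) params <- tab$name[!tab$fixed]
  rows <- lapply(params, function(p) {
    ci <- profile_likelihood_ci(fit, p, ...)
    data.frame(name = p, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               lower_unbounded = ci$lower_unbounded,
               upper_unbounded = ci$upper_unbounded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Profile a scalar derived quantity q(theta) by the penalty method:
# walk a target value for q away from its best-fit value; at each target
# minimize SSR + w (q - target)^2 with w stiff enough that the achieved q
# tracks the target, and record the achieved (q, SSR). Crossing of
# best + delta is interpolated on the achieved q.
profile_quantity <- function(fit, qfun, level = 0.95, step_frac = 0.05,
                             max_steps = 40, span_limit = 1e3) {
  tab <- fit$spec$table
  free <- which(!tab$fixed)
  obj_free <- make_objective(fit$spec, fit$fitdata)
  th_hat <- fit$theta[free]
  ssr_hat <- fit$objective
  delta <- PROFILE_DELTA(level)
  lower <- mapply(trans_to, tab$lower[free], tab$transform[free])
  upper <- mapply(trans_to, tab$upper[free], tab$transform[free])
  qfree <- function(th_free) {
    th <- fit$theta
    th[free] <- th_free
    qfun(th)
  }
  q_hat <- qfree(th_hat)
  scale <- max(abs(q_hat), 1e-3)
  w <- delta / (0.005 * scale)^2

  walk <- function(direction) {
    step <- step_frac * scale
    target <- q_hat
    warm <- th_hat
    prev_q <- q_hat
    prev_ssr <- ssr_hat
    for (s in seq_len(max_steps)) {
      target <- target + direction * step
      pen <- function(th_free) {
        obj_free(th_free) + w * (qfree(th_free) - target)^2
      }
      res <- reoptimize(pen, warm, lower, upper)
      if (is.null(res)) return(list(bound = prev_q, unbounded = TRUE))
      q_ach <- qfree(res$par)
      ssr_ach <- obj_free(res$par)
      if (ssr_ach > ssr_hat + delta) {
        frac <- (ssr_hat + delta - prev_ssr) / (ssr_ach - prev_ssr)
        return(list(bound = prev_q + (q_ach - prev_q) * frac,
                    unbounded = FALSE))
      }
      dssr <- ssr_ach - prev_ssr
      if (dssr < 0.3) step <- step * 1.7
      else if (dssr > 1.5) step <- step * 0.6
      prev_q <- q_ach
      prev_ssr <- ssr_ach
      warm <- res$par
      if (abs(q_ach - q_hat) > span_limit * scale)
        return(list(bound = q_ach, unbounded = TRUE))
    }
    list(bound = prev_q, unbounded = TRUE)
  }
  lo <- walk(-1)
  hi <- walk(+1)
  list(estimate = q_hat, lower = lo$bound, upper = hi$bound,
       lower_unbounded = lo$unbounded, upper_unbounded = hi$unbounded,
       level = level)
}

#' Prediction profile likelihood band for one model observable
#'
#' The extreme model predictions at a given (dataset, compartment,
#' quantity, time) compatible with the data: the prediction is profiled
#' subject to the objective staying within the chi-square 1-df quantile of
#' the optimum. The band always contains the best-fit prediction; in the
#' zero-noise limit it collapses onto it.
#'
#' @param fit An `hsc_fit`.
#' @param dataset Dataset id.
#' @param compartment `"HSC"`, `"ST-HSC"` or `"MPP"`.
#' @param quantity `"frequency"` (HSC raw labeled frequency),
#'   `"frequency_norm"` (HSC-normalized, ST-HSC/MPP) or `"count"`.
#' @param time Time point (days).
#' @param level Confidence level.
#' @param ... Passed to the internal quantity profiler.
#' @return A list with `estimate`, `lower`, `upper` and unbounded flags.
#' @export
prediction_profile_band <- function(fit, dataset, compartment, quantity,
                                    time, level = 0.95, ...) {
  ci <- match(compartment, OBS_COMPARTMENTS)
  if (is.na(ci)) stop("unknown compartment: ", compartment)
  col <- switch(quantity,
                frequency = 1L,
                frequency_norm = if (ci == 1)
                  stop("normalized frequency is undefined for HSC")
                else ci,
                count = ci + 3L,
                stop("unknown quantity: ", quantity))
  if (quantity == "frequency" && ci != 1)
    stop("raw frequency observable is fit for HSC only")
  if (!dataset %in% names(fit$params$f0))
    stop("unknown dataset: ", dataset)
  qfun <- function(theta) {
    p <- unpack_params(theta, fit$spec)
    predict_matrix(p, p$f0[[dataset]], time)[1, col]
  }
  profile_quantity(fit, qfun, level = level, ...)
}

#' Initial-labeling specificity ratios
#'
#' Per dataset the ratio of initial labeling of the upstream to the
#' downstream HSC subcompartment, \eqn{r_A = f0_{A,U} / f0_{A,D}}, with a
#' profile lower bound (the "minimum ratio"); and between datasets the
#' ratio of ratios \eqn{r_A / r_B}, interpretable as the relative
#' specificity of driver A for HSC-U over HSC-D compared with driver B.
#' Ratios are profiled on the log scale; a side that never crosses the
#' threshold within the search span is flagged unbounded (e.g. when the
#' downstream labeling is compatible with zero).
#'
#' @param fit A converged `hsc_fit` with free `f0` blocks.
#' @param level Confidence level for the profile bounds.
#' @param ci Compute profile bounds (slower); otherwise point estimates
#'   only.
#' @return A list with data frames `ratios` (per dataset) and
#'   `ratio_of_ratios` (per ordered dataset pair).
#' @export
labeling_specificity <- function(fit, level = 0.95, ci = TRUE) {
  ds <- names(fit$params$f0)
  tab <- fit$spec$table
  ratio_q <- function(d) {
    iu <- match(paste0("f0_", d, "_1"), tab$name)
    id <- match(paste0("f0_", d, "_2"), tab$name)
    function(theta) {
      v <- mapply(trans_from, theta[c(iu, id)], tab$transform[c(iu, id)])
      log(v[1] / v[2])
    }
  }
  ratios <- do.call(rbind, lapply(ds, function(d) {
    f0 <- fit$params$f0[[d]]
    est <- f0[1] / f0[2]
    row <- data.frame(dataset = d, ratio = est,
                      lower = NA_real_, upper = NA_real_,
                      lower_unbounded = NA, upper_unbounded = NA)
    if (ci && !tab$fixed[match(paste0("f0_", d, "_1"), tab$name)]) {
      pr <- profile_quantity(fit, ratio_q(d), level = level,
                             step_frac = 0.1)
      row$lower <- exp(pr$lower); row$upper <- exp(pr$upper)
      row$lower_unbounded <- pr$lower_unbounded
      row$upper_unbounded <- pr$upper_unbounded
    }
    row
  }))
  pairs <- NULL
  if (length(ds) >= 2) {
    cmb <- expand.grid(A = ds, B = ds, stringsAsFactors = FALSE)
    cmb <- cmb[cmb$A != cmb$B, ]
    pairs <- do.call(rbind, lapply(seq_len(nrow(cmb)), function(k) {
      a <- cmb$A[k]; b <- cmb$B[k]
      data.frame(A = a, B = b,
                 ratio_of_ratios = ratios$ratio[ratios$dataset == a] /
                                   ratios$ratio[ratios$dataset == b])
    }))
  }
  list(ratios = ratios, ratio_of_ratios = pairs)
}
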