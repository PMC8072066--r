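# Joint weighted-least-squares inference: shared kinetics and compartment
# sizes across datasets, dataset-specific initial labeling, optimization
# on transformed scales (log for positive rates and counts, logit for
# frequencies, identity for the sign-free HSC-U inverse residence time).

trans_to <- function(x, tr) switch(tr, log = log(x), logit = stats::qlogis(x),
                                   identity = x)
trans_from <- function(x, tr) switch(tr, log = exp(x),
                                     logit = stats::plogis(x), identity = x)

# Parameter layout. kappa parameterization: alpha_1..3 (log), kappa_1
# (identity, sign-free: the most immature compartment may expand),
# kappa_2..4 (log), n0_1..4 (log), plus per-dataset f0_1..4 (logit).
# beta parameterization: alpha_1..4 (log) and beta_1..4 (identity) with
# kappa derived as alpha - beta.
build_fit_spec <- function(datasets,
                           parameterization = c("kappa", "beta"),
                           fixed = list(), kappa1_sign_free = TRUE) {
  parameterization <- match.arg(parameterization)
  row <- function(name, transform, lo, hi, box_lo, box_hi, block,
                  dataset = NA_character_)
    data.frame(name = name, transform = transform, lower = lo, upper = hi,
               box_lo = box_lo, box_hi = box_hi, block = block,
               dataset = dataset, fixed = FALSE, value = NA_real_,
               stringsAsFactors = FALSE)
  rows <- list()
  if (parameterization == "kappa") {
    for (i in 1:3)
      rows[[length(rows) + 1]] <- row(paste0("alpha", i), "log", 1e-6, 5,
                                      1e-4, 0.5, "kinetics")
    rows[[length(rows) + 1]] <-
      if (kappa1_sign_free)
        row("kappa1", "identity", -0.1, 0.1, -0.02, 0.02, "kinetics")
      else row("kappa1", "log", 1e-6, 5, 1e-4, 0.5, "kinetics")
    for (i in 2:4)
      rows[[length(rows) + 1]] <- row(paste0("kappa", i), "log", 1e-6, 5,
                                      1e-4, 0.5, "kinetics")
  } else {
    for (i in 1:4)
      rows[[length(rows) + 1]] <- row(paste0("alpha", i), "log", 1e-6, 5,
                                      1e-4, 0.5, "kinetics")
    for (i in 1:4)
      rows[[length(rows) + 1]] <- row(paste0("beta", i), "identity", -1, 1,
                                      -0.05, 0.3, "kinetics")
  }
  for (i in 1:4)
    rows[[length(rows) + 1]] <- row(paste0("n0_", i), "log", 1, 1e7,
                                    50, 1e5, "sizes")
  for (ds in datasets)
    for (i in 1:4)
      rows[[length(rows) + 1]] <- row(paste0("f0_", ds, "_", i), "logit",
                                      1e-6, 1 - 1e-6, 1e-3, 0.9, "f0", ds)
  tab <- do.call(rbind, rows)
  for (nm in names(fixed)) {
    j <- match(nm, tab$name)
    if (is.na(j)) stop("unknown parameter in `fixed`: ", nm)
    tab$fixed[j] <- TRUE
    tab$value[j] <- as.numeric(fixed[[nm]])
  }
  structure(list(table = tab, datasets = datasets,
                 parameterization = parameterization),
            class = "hsc_fit_spec")
}

theta_full <- function(spec) {
  tab <- spec$table
  th <- numeric(nrow(tab))
  if (any(tab$fixed))
    th[tab$fixed] <- unlist(mapply(trans_to, tab$value[tab$fixed],
                                   tab$transform[tab$fixed],
                                   SIMPLIFY = FALSE))
  th
}

unpack_params <- function(theta, spec) {
  tab <- spec$table
  val <- mapply(trans_from, theta, tab$transform)
  names(val) <- tab$name
  if (spec$parameterization == "kappa") {
    alpha <- c(val["alpha1"], val["alpha2"], val["alpha3"], 0)
    kappa <- c(val["kappa1"], val["kappa2"], val["kappa3"], val["kappa4"])
  } else {
    alpha <- val[paste0("alpha", 1:4)]
    kappa <- alpha - val[paste0("beta", 1:4)]
  }
  f0 <- lapply(spec$datasets, function(ds) unname(val[paste0("f0_", ds, "_", 1:4)]))
  names(f0) <- spec$datasets
  list(alpha = unname(alpha), kappa = unname(kappa),
       n0 = unname(val[paste0("n0_", 1:4)]), f0 = f0)
}

pack_params <- function(params, spec) {
  tab <- spec$table
  val <- setNames(rep(NA_real_, nrow(tab)), tab$name)
  if (spec$parameterization == "kappa") {
    val[paste0("alpha", 1:3)] <- params$alpha[1:3]
    val[paste0("kappa", 1:4)] <- params$kappa
  } else {
    val[paste0("alpha", 1:4)] <- params$alpha
    val[paste0("beta", 1:4)] <- params$alpha - params$kappa
  }
  val[paste0("n0_", 1:4)] <- params$n0
  for (ds in spec$datasets)
    val[paste0("f0_", ds, "_", 1:4)] <- params$f0[[ds]]
  mapply(trans_to, val, tab$transform)
}

# Flatten pooled datasets into the structures the objective needs:
# per dataset a unique time grid and index vectors mapping each
# observation to (time index, observable column), with its mean and SEM.
# Observable columns: 1 f_HSC, 2 normalized f_ST, 3 normalized f_MPP,
# 4 n_HSC, 5 n_ST, 6 n_MPP.
build_fitdata <- function(pooled_list) {
  if (is.data.frame(pooled_list)) {
    pooled_list <- split(as.data.frame(pooled_list), pooled_list$dataset)
  }
  ids <- vapply(pooled_list, function(p) unique(p$dataset)[1], "")
  names(pooled_list) <- ids
  ord <- order(ids)
  pooled_list <- pooled_list[ord]
  out <- lapply(pooled_list, function(p) {
    p <- as.data.frame(p)
    need <- c("sem_frequency", "sem_frequency_norm", "sem_count")
    if (!all(need %in% names(p)))
      stop("pooled dataset lacks SEM columns; run add_pooled_sem() first")
    comp_i <- match(p$compartment, OBS_COMPARTMENTS)
    obs <- list()
    add <- function(sel, y, sem, col) {
      ok <- sel & !is.na(y) & !is.na(sem) & sem > 0
      if (!any(ok)) return()
      obs[[length(obs) + 1]] <<- data.frame(
        time = p$time[ok], col = col[ok], y = y[ok], sem = sem[ok],
        compartment = p$compartment[ok],
        quantity = ifelse(col[ok] <= 3,
                          ifelse(col[ok] == 1, "frequency",
                                 "frequency_norm"), "count"))
    }
    add(comp_i == 1, p$mean_frequency, p$sem_frequency,
        rep(1L, nrow(p)))
    add(comp_i > 1, p$mean_frequency_norm, p$sem_frequency_norm, comp_i)
    add(rep(TRUE, nrow(p)), p$mean_count, p$sem_count, comp_i + 3L)
    obs <- do.call(rbind, obs)
    ut <- sort(unique(obs$time))
    list(dataset = unique(p$dataset)[1], times = ut,
         ti = match(obs$time, ut), col = obs$col,
         y = obs$y, sem = obs$sem, meta = obs)
  })
  out
}

# 6-column observable matrix at the dataset's unique times
predict_matrix <- function(params, f0, times) {
  cur <- model_curves(params$kappa, params$alpha, params$n0, f0, times)
  nH <- cur$n[, 1] + cur$n[, 2]
  fH <- (cur$l[, 1] + cur$l[, 2]) / nH
  cbind(fH, cur$f[, 3] / fH, cur$f[, 4] / fH, nH, cur$n[, 3], cur$n[, 4])
}

ssr_params <- function(params, fitdata) {
  tot <- 0
  for (fd in fitdata) {
    P <- predict_matrix(params, params$f0[[fd$dataset]], fd$times)
    pred <- P[cbind(fd$ti, fd$col)]
    if (any(!is.finite(pred))) return(1e12)
    tot <- tot + sum(((pred - fd$y) / fd$sem)^2)
  }
  tot
}

#' Weighted sum of squared residuals
#'
#' The fitting objective: over all datasets, observable streams and bins,
#' the squared residual between model observable and binned mean, weighted
#' by the pooled-variance SEM. Model observables are the aggregate HSC
#' labeled frequency, the HSC-normalized ST-HSC and MPP labeled
#' frequencies (normalized by the modeled HSC frequency at the same bin
#' time), and the HSC/ST-HSC/MPP compartment sizes. Non-finite model
#' output maps to a large penalty (1e12) rather than an error, so
#' optimizers can retreat from pathological parameter proposals.
#'
#' @param params A list with `alpha` (length 4), `kappa` (length 4), `n0`
#'   (length 4), and `f0`: a named list (one length-4 frequency vector per
#'   dataset).
#' @param pooled A pooled dataset (or list of them) with SEM columns from
#'   [add_pooled_sem()].
#' @return The scalar objective.
#' @export
weighted_ssr <- function(params, pooled) {
  ssr_params(params, build_fitdata(pooled))
}

# Fast closure for the optimizer: vectorized inverse transforms and the
# per-dataset residual sum in C++.
make_objective <- function(spec, fitdata) {
  tab <- spec$table
  free <- which(!tab$fixed)
  th0 <- theta_full(spec)
  ilog <- which(tab$transform == "log")
  ilogit <- which(tab$transform == "logit")
  kappa_param <- spec$parameterization == "kappa"
  ia <- match(paste0("alpha", 1:4), tab$name)
  ik <- match(paste0("kappa", 1:4), tab$name)
  ib <- match(paste0("beta", 1:4), tab$name)
  in0 <- match(paste0("n0_", 1:4), tab$name)
  if0 <- lapply(vapply(fitdata, `[[`, "", "dataset"), function(ds)
    match(paste0("f0_", ds, "_", 1:4), tab$name))
  function(theta_free) {
    th <- th0
    th[free] <- theta_free
    val <- th
    val[ilog] <- exp(th[ilog])
    val[ilogit] <- stats::plogis(th[ilogit])
    if (kappa_param) {
      alpha <- c(val[ia[1:3]], 0)
      kappa <- val[ik]
    } else {
      alpha <- val[ia]
      kappa <- alpha - val[ib]
    }
    n0 <- val[in0]
    if (any(!is.finite(kappa)) || any(!is.finite(alpha)) ||
        any(!is.finite(n0)))
      return(1e12)
    tot <- 0
    for (i in seq_along(fitdata)) {
      fd <- fitdata[[i]]
      tot <- tot + obs_ssr_cpp(kappa, alpha, n0, val[if0[[i]]], fd$times,
                               fd$ti, fd$col, fd$y, fd$sem)
    }
    tot
  }
}

# Data-informed starting points: initial labeling read off the earliest
# bins, compartment sizes off the observed counts, and a small set of
# generic rate regimes (quiescent vs. active). These are heuristics over
# the observed data only; they complement, not replace, the random starts.
heuristic_starts <- function(spec, fitdata) {
  tab <- spec$table
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  first_y <- function(fd, column, default) {
    sel <- fd$col == column
    if (!any(sel)) return(default)
    fd$y[sel][which.min(fd$ti[sel])]
  }
  ref <- default_rates()
  rate_sets <- list(
    list(alpha = c(ref$alpha[1:3], 0), kappa = ref$kappa),
    list(alpha = c(0.005, 0.1, 0.05, 0), kappa = c(0, 0.005, 0.03, 0.01)),
    list(alpha = c(0.02, 0.3, 0.1, 0), kappa = c(0.005, 0.05, 0.1, 0.05)))
  starts <- list()
  for (rs in rate_sets) for (u_specific in c(TRUE, FALSE)) {
    f0 <- list()
    n_hsc <- 3000; n_st <- 9000; n_mpp <- 30000
    for (fd in fitdata) {
      fh <- clamp(first_y(fd, 1L, 0.05), 1e-5, 0.99)
      f3 <- clamp(first_y(fd, 2L, 0.1) * fh, 1e-5, 0.99)
      f4 <- clamp(first_y(fd, 3L, 0.1) * fh, 1e-5, 0.99)
      fu <- if (u_specific) clamp(6 * fh, 1e-5, 0.95) else fh
      fdn <- if (u_specific) clamp(fh / 3, 1e-5, 0.95) else fh
      f0[[fd$dataset]] <- c(fu, fdn, f3, f4)
      n_hsc <- first_y(fd, 4L, n_hsc)
      n_st <- first_y(fd, 5L, n_st)
      n_mpp <- first_y(fd, 6L, n_mpp)
    }
    params <- list(alpha = rs$alpha, kappa = rs$kappa,
                   n0 = clamp(c(n_hsc / 6, n_hsc * 5 / 6, n_st, n_mpp),
                              2, 1e6),
                   f0 = f0)
    starts[[length(starts) + 1]] <- pack_params(params, spec)
  }
  m <- do.call(rbind, starts)
  # keep starts strictly inside the transformed box
  free <- which(!tab$fixed)
  lo <- mapply(trans_to, tab$lower[free], tab$transform[free])
  hi <- mapply(trans_to, tab$upper[free], tab$transform[free])
  m <- m[, free, drop = FALSE]
  for (j in seq_along(free)) m[, j] <- clamp(m[, j], lo[j], hi[j])
  m
}

lhs_starts <- function(spec, n_starts, seed) {
  tab <- spec$table
  free <- which(!tab$fixed)
  lo <- mapply(trans_to, tab$box_lo[free], tab$transform[free])
  hi <- mapply(trans_to, tab$box_hi[free], tab$transform[free])
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_starts, length(free))
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

#' Fit the model jointly to one or more pooled datasets
#'
#' Minimizes [weighted_ssr()] with kinetics and compartment sizes shared
#' across datasets and initial labeling frequencies free per dataset.
#' Optimization runs on transformed scales with box constraints, from
#' multiple Latin-hypercube starting points (the objective is screened at
#' all starts and the best `n_optimized` are polished with `nlminb`); the
#' result is deterministic given `seed`. A `start` list (same shape as the
#' `params` of [weighted_ssr()]) may replace the random starts.
#'
#' @param pooled A pooled dataset or (named) list of pooled datasets with
#'   SEM columns.
#' @param parameterization `"kappa"` (default) or `"beta"`; both describe
#'   the same model and yield the same optimum.
#' @param fixed Named list of parameters to fix at given natural values
#'   (names as in the spec table, e.g. `alpha1`, `kappa2`, `n0_1`,
#'   `f0_<dataset>_1`).
#' @param n_starts Latin-hypercube sample size.
#' @param n_optimized Number of screened starts polished by `nlminb`.
#' @param seed Seed for the start sample.
#' @param start Optional explicit start (`params` list); overrides the
#'   random starts.
#' @param control Control list passed to [stats::nlminb()].
#' @return An object of class `hsc_fit`.
#' @export
fit_joint <- function(pooled, parameterization = c("kappa", "beta"),
                      fixed = list(), n_starts = 32, n_optimized = 6,
                      seed = 1, start = NULL,
                      control = list(iter.max = 500, eval.max = 2000)) {
  fitdata <- build_fitdata(pooled)
  datasets <- vapply(fitdata, `[[`, "", "dataset")
  spec <- build_fit_spec(datasets, parameterization, fixed)
  tab <- spec$table
  free <- which(!tab$fixed)
  obj <- make_objective(spec, fitdata)
  n_obs <- sum(vapply(fitdata, function(fd) length(fd$y), 0))

  if (length(free) == 0) {
    th <- theta_full(spec)
    params <- unpack_params(th, spec)
    return(new_fit(spec, th, params, ssr_params(params, fitdata),
                   fitdata, n_obs, convergence = 0L, seed = seed))
  }

  lower <- mapply(trans_to, tab$lower[free], tab$transform[free])
  upper <- mapply(trans_to, tab$upper[free], tab$transform[free])

  starts <- if (!is.null(start)) {
    matrix(pack_params(start, spec)[free], nrow = 1)
  } else {
    s <- rbind(heuristic_starts(spec, fitdata),
               lhs_starts(spec, n_starts, seed))
    sc <- apply(s, 1, obj)
    s[order(sc)[seq_len(min(n_optimized + 4, nrow(s)))], , drop = FALSE]
  }

  # phase 1: short runs from every retained start; phase 2: full polish of
  # the most promising candidates
  phase1 <- lapply(seq_len(nrow(starts)), function(r) {
    tryCatch(
      stats::nlminb(starts[r, ], obj, lower = lower, upper = upper,
                    control = list(iter.max = 150, eval.max = 600)),
      error = function(e) NULL)
  })
  phase1 <- Filter(Negate(is.null), phase1)
  if (length(phase1) == 0) stop("no optimization start converged")
  ord <- order(vapply(phase1, `[[`, 0, "objective"))
  best <- NULL
  for (r in ord[seq_len(min(3, length(ord)))]) {
    res <- tryCatch(
      stats::nlminb(phase1[[r]]$par, obj, lower = lower, upper = upper,
                    control = control),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective))
      best <- res
  }
  if (is.null(best)) best <- phase1[[ord[1]]]

  # finite-difference gradient methods can stall in curved valleys;
  # alternate with a derivative-free polish until neither route improves
  for (k in 1:4) {
    obj_box <- function(th) obj(pmin(upper, pmax(lower, th)))
    nm <- tryCatch(
      stats::optim(best$par, obj_box, method = "Nelder-Mead",
                   control = list(maxit = 2000)),
      error = function(e) NULL)
    start_k <- if (!is.null(nm) && nm$value < best$objective)
      pmin(upper, pmax(lower, nm$par)) else best$par
    res <- tryCatch(
      stats::nlminb(start_k, obj, lower = lower, upper = upper,
                    control = control),
      error = function(e) NULL)
    if (!is.null(res) && res$objective < best$objective - 1e-3) {
      best <- res
    } else {
      if (!is.null(res) && res$objective < best$objective) best <- res
      break
    }
  }

  th <- theta_full(spec)
  th[free] <- best$par
  params <- unpack_params(th, spec)
  new_fit(spec, th, params, best$objective, fitdata, n_obs,
          convergence = best$convergence, seed = seed,
          message = best$message)
}

#' Fit only the initial labeling of a new dataset
#'
#' Out-of-sample prediction check: kinetics and compartment sizes are
#' fixed to previously inferred values (an `hsc_fit` or a
#' [kinetic_rates] plus `n0`) and only the initial labeled frequencies of
#' the new dataset are trained.
#'
#' @param pooled Pooled dataset (with SEMs) of the new experiment.
#' @param kinetics An `hsc_fit` from [fit_joint()], or a [kinetic_rates].
#' @param n0 Initial counts; required when `kinetics` is a
#'   [kinetic_rates].
#' @param fixed Additional fixed parameters (e.g. some `f0` entries); if
#'   all f0 entries are fixed the fixed model is simply evaluated.
#' @param ... Passed to [fit_joint()].
#' @return An `hsc_fit` whose free block is the new dataset's `f0`.
#' @export
fit_fixed_kinetics <- function(pooled, kinetics, n0 = NULL,
                               fixed = list(), ...) {
  if (inherits(kinetics, "hsc_fit")) {
    p <- kinetics$params
    alpha <- p$alpha; kappa <- p$kappa; n0 <- p$n0
  } else if (inherits(kinetics, "kinetic_rates")) {
    if (is.null(n0)) stop("supply `n0` with explicit kinetic rates")
    alpha <- kinetics$alpha; kappa <- kinetics$kappa
  } else stop("`kinetics` must be an hsc_fit or kinetic_rates")
  fx <- list(alpha1 = alpha[1], alpha2 = alpha[2], alpha3 = alpha[3],
             kappa1 = kappa[1], kappa2 = kappa[2], kappa3 = kappa[3],
             kappa4 = kappa[4],
             n0_1 = n0[1], n0_2 = n0[2], n0_3 = n0[3], n0_4 = n0[4])
  fit_joint(pooled, parameterization = "kappa", fixed = c(fx, fixed), ...)
}

new_fit <- function(spec, theta, params, objective, fitdata, n_obs,
                    convergence, seed, message = NULL) {
  tab <- spec$table
  est <- data.frame(name = tab$name, block = tab$block,
                    dataset = tab$dataset, fixed = tab$fixed,
                    estimate = mapply(trans_from, theta, tab$transform),
                    stringsAsFactors = FALSE)
  structure(list(spec = spec, theta = theta, params = params,
                 estimates = est, objective = objective,
                 n_obs = n_obs, n_free = sum(!tab$fixed),
                 convergence = convergence, message = message,
                 fitdata = fitdata, seed = seed),
            class = "hsc_fit")
}

#' @export
print.hsc_fit <- function(x, ...) {
  cat("hsc_fit:", length(x$fitdata), "dataset(s) (",
      paste(vapply(x$fitdata, `[[`, "", "dataset"), collapse = ", "),
      ")\n")
  cat("objective (weighted SSR):", format(x$objective, digits = 6),
      "on", x$n_obs, "observations,", x$n_free, "free parameters\n")
  cat("reduced objective:", format(reduced_objective(x), digits = 4), "\n")
  free <- x$estimates[!x$estimates$fixed, c("name", "estimate")]
  if (nrow(free) > 0) {
    free$estimate <- signif(free$estimate, 4)
    print(free, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.hsc_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$name)
}

#' Reduced fitting objective
#'
#' The weighted SSR divided by its residual degrees of freedom
#' (observations minus free parameters); near 1 when residuals match the
#' assumed measurement error.
#'
#' @param fit An `hsc_fit`.
#' @return Scalar.
#' @export
reduced_objective <- function(fit) {
  fit$objective / (fit$n_obs - fit$n_free)
}

#' Model predictions at the fitted parameters
#'
#' @param fit An `hsc_fit`.
#' @return A `data.frame`: dataset, time, compartment, quantity, observed
#'   mean, SEM, and model prediction.
#' @export
fit_predictions <- function(fit) {
  out <- lapply(fit$fitdata, function(fd) {
    P <- predict_matrix(fit$params, fit$params$f0[[fd$dataset]], fd$times)
    data.frame(dataset = fd$dataset, time = fd$meta$time,
               compartment = fd$meta$compartment,
               quantity = fd$meta$quantity,
               observed = fd$y, sem = fd$sem,
               predicted = P[cbind(fd$ti, fd$col)])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Machine-readable fit report
#'
#' @param fit An `hsc_fit`.
#' @param profiles Optional profile-CI table from [profile_all()].
#' @param path Optional JSON output path.
#' @return The report list, invisibly when written.
#' @export
fit_report <- function(fit, profiles = NULL, path = NULL) {
  rep <- list(
    datasets = vapply(fit$fitdata, `[[`, "", "dataset"),
    objective = fit$objective,
    n_obs = fit$n_obs, n_free = fit$n_free,
    reduced_objective = reduced_objective(fit),
    convergence = fit$convergence,
    seed = fit$seed,
    estimates = fit$estimates)
  if (!is.null(profiles)) rep$profiles <- profiles
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
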