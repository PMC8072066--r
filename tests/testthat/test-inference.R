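# A tiny hand-checkable pooled dataset: 2 bins, one dataset, all SEMs set
# explicitly.
hand_pooled <- function() {
  df <- data.frame(
    dataset = "toy",
    compartment = rep(c("HSC", "ST-HSC", "MPP"), each = 2),
    bin = rep(1:2, 3), bin_lo = 0, bin_hi = 0,
    time = rep(c(0, 30), 3), n_mice = 5L,
    mean_frequency = c(0.04, 0.05, NA, NA, NA, NA),
    var_frequency = 1e-4, n_frequency = rep(c(5, 5, 0, 0, 0, 0)),
    mean_frequency_norm = c(NA, NA, 0.3, 0.5, 0.1, 0.2),
    var_frequency_norm = 1e-3, n_frequency_norm = rep(c(0, 0, 5, 5, 5, 5)),
    mean_count = c(2800, 2900, 9000, 9100, 30000, 31000),
    var_count = 1e4, n_count = 5,
    sem_frequency = c(0.005, 0.005, NA, NA, NA, NA),
    sem_frequency_norm = c(NA, NA, 0.02, 0.02, 0.02, 0.02),
    sem_count = rep(c(100, 300, 1000), each = 2),
    stringsAsFactors = FALSE)
  class(df) <- c("hsc_pooled", "data.frame")
  df
}

test_that("the weighted SSR objective matches hand computation", {
  pooled <- hand_pooled()
  r <- truth_rates()
  params <- list(alpha = r$alpha, kappa = r$kappa, n0 = truth_n0(),
                 f0 = list(toy = c(0.21, 0.01, 0.01, 0.005)))

  # manual recomputation from the model curves
  tr <- solve_label_frequencies(r, initial_state(truth_n0(),
                                                 params$f0$toy),
                                times = c(0, 30))
  nz <- normalize_to_hsc(tr)
  agg <- aggregate_hsc_observable(tr)
  pred <- c(agg$f_hsc, nz$f_st_norm, nz$f_mpp_norm,
            agg$n_hsc, tr$n[, 3], tr$n[, 4])
  y <- c(0.04, 0.05, 0.3, 0.5, 0.1, 0.2, 2800, 2900, 9000, 9100,
         30000, 31000)
  sem <- c(0.005, 0.005, 0.02, 0.02, 0.02, 0.02, 100, 100, 300, 300,
           1000, 1000)
  expect_equal(weighted_ssr(params, pooled), sum(((pred - y) / sem)^2),
               tolerance = 1e-8)

  # model == data means -> objective zero; a single 2-SEM residual -> 4
  fd <- hscflux:::build_fitdata(pooled)[[1]]
  P <- hscflux:::predict_matrix(params, params$f0$toy, fd$times)
  exact <- pooled
  exact$mean_frequency[1:2] <- P[, 1]
  exact$mean_frequency_norm[3:4] <- P[, 2]
  exact$mean_frequency_norm[5:6] <- P[, 3]
  exact$mean_count[1:2] <- P[, 4]
  exact$mean_count[3:4] <- P[, 5]
  exact$mean_count[5:6] <- P[, 6]
  expect_equal(weighted_ssr(params, exact), 0, tolerance = 1e-10)
  off <- exact
  off$mean_frequency[1] <- off$mean_frequency[1] + 2 * 0.005
  expect_equal(weighted_ssr(params, off), 4, tolerance = 1e-6)
})

test_that("noise-free data are fit exactly from a truthful start", {
  pooled <- make_noise_free_pair()
  start <- truth_params(c("tie2-like", "fgd5-like"))
  fit <- fit_joint(pooled, start = start)
  expect_lt(fit$objective, 1e-6)
  expect_equal(fit$params$alpha[1:3], truth_rates()$alpha[1:3],
               tolerance = 1e-3)
  expect_equal(fit$params$kappa, truth_rates()$kappa, tolerance = 1e-2)
})

test_that("the best fit is invariant to dataset order and parameterization", {
  pooled <- make_noise_free_pair()
  start <- truth_params(c("tie2-like", "fgd5-like"))
  f1 <- fit_joint(pooled, start = start)
  f2 <- fit_joint(rev(pooled), start = start)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)

  # beta-parameterization reaches the same optimum
  r <- truth_rates()
  start_beta <- truth_params(c("tie2-like", "fgd5-like"))
  start_beta$alpha <- c(r$alpha[1:3], r$kappa[4] + r$beta[4])
  fb <- fit_joint(pooled, parameterization = "beta", start = start_beta)
  expect_lt(abs(fb$objective - f1$objective), 1e-6)
  expect_equal(fb$params$kappa, f1$params$kappa, tolerance = 1e-2)
})

test_that("profile walk reproduces the analytic interval of a quadratic objective", {
  # correlated quadratic objective: profile CI of theta_j is
  # sqrt(delta * (A^-1)_jj) on either side of the optimum
  A <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3)
  obj <- function(th) drop(t(th) %*% A %*% th)
  delta <- stats::qchisq(0.95, 1)
  half <- sqrt(delta * solve(A)[1, 1])
  lo <- hscflux:::profile_walk(obj, rep(0, 3), 0, 1,
                               lower = rep(-50, 3), upper = rep(50, 3),
                               delta = delta, direction = -1,
                               step_init = 0.1, max_steps = 50)
  hi <- hscflux:::profile_walk(obj, rep(0, 3), 0, 1,
                               lower = rep(-50, 3), upper = rep(50, 3),
                               delta = delta, direction = +1,
                               step_init = 0.1, max_steps = 50)
  expect_false(lo$unbounded || hi$unbounded)
  expect_equal(lo$bound, -half, tolerance = 0.01)
  expect_equal(hi$bound, half, tolerance = 0.01)

  # a parameter the objective ignores is unbounded on both sides
  obj2 <- function(th) th[2]^2
  free <- hscflux:::profile_walk(obj2, c(0, 0), 0, 1,
                                 lower = c(-5, -5), upper = c(5, 5),
                                 delta = delta, direction = +1,
                                 step_init = 0.5, max_steps = 50)
  expect_true(free$unbounded)
})

test_that("profile CIs bracket the estimate and the profile stays above the optimum", {
  pooled <- make_pooled_pair(seed = 314)
  fit <- fit_joint(pooled, seed = 1,
                   start = truth_params(c("tie2-like", "fgd5-like")))
  ci <- profile_likelihood_ci(fit, "alpha2")
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
  expect_true(all(ci$curve$ssr >= fit$objective - 0.05))
  # profile curve is continuous enough for plotting: no huge jumps
  expect_lt(max(diff(ci$curve$ssr[order(ci$curve$theta)])),
            4 * stats::qchisq(0.95, 1))
})

test_that("fixed-kinetics fits recover new initial labeling and degenerate cases", {
  # third cohort from the shared truth with its own labeling
  co <- generate_cohort(truth_rates(), truth_n0(),
                        noise_free_design("krt18-like"), seed = 21)
  pooled <- add_nominal_sem(run_pipeline(co))
  fit <- fit_fixed_kinetics(pooled, kinetic_rates(truth_rates()$alpha,
                                                  beta = truth_rates()$beta),
                            n0 = truth_n0())
  expect_equal(fit$n_free, 4)
  expect_lt(fit$objective, 1e-4)
  expect_equal(fit$params$f0[["krt18-like"]],
               preset_designs("krt18-like")$f0, tolerance = 0.05)

  # empty free block: the fixed model is evaluated unchanged
  f0fix <- preset_designs("krt18-like")$f0
  fit0 <- fit_fixed_kinetics(pooled, fit,
                             fixed = list("f0_krt18-like_1" = f0fix[1],
                                          "f0_krt18-like_2" = f0fix[2],
                                          "f0_krt18-like_3" = f0fix[3],
                                          "f0_krt18-like_4" = f0fix[4]))
  expect_equal(fit0$n_free, 0)
  expect_equal(fit0$objective,
               weighted_ssr(truth_params("krt18-like"), pooled),
               tolerance = 1e-6)

  # labeling truly absent downstream: logit scale still reaches the boundary
  d0 <- noise_free_design("krt18-like")
  d0$f0 <- c(0.45, 0.015, 0, 0)
  co0 <- generate_cohort(truth_rates(), truth_n0(), d0, seed = 22)
  pooled0 <- add_nominal_sem(run_pipeline(co0))
  fit_b <- fit_fixed_kinetics(pooled0, fit)
  expect_lt(fit_b$params$f0[["krt18-like"]][3], 0.01)
  expect_lt(fit_b$params$f0[["krt18-like"]][4], 0.01)
})

test_that("prediction profile bands contain the best fit and collapse without noise", {
  pooled <- make_noise_free_pair()
  fit <- fit_joint(pooled, start = truth_params(c("tie2-like",
                                                  "fgd5-like")))
  band <- prediction_profile_band(fit, "fgd5-like", "ST-HSC",
                                  "frequency_norm", time = 100)
  expect_lte(band$lower, band$estimate)
  expect_gte(band$upper, band$estimate)
  # nominal-SEM noise-free fit: the band is narrow around the curve
  expect_lt(band$upper - band$lower, 0.2 * max(band$estimate, 0.1))
})

test_that("labeling specificity ratios propagate from the f0 block", {
  pooled <- make_noise_free_pair()
  f0t <- preset_designs("tie2-like")$f0
  f0f <- preset_designs("fgd5-like")$f0
  fixed <- list()
  for (i in 1:4) {
    fixed[[paste0("f0_tie2-like_", i)]] <- f0t[i]
    fixed[[paste0("f0_fgd5-like_", i)]] <- f0f[i]
  }
  r <- truth_rates()
  fixed <- c(fixed, list(alpha1 = r$alpha[1], alpha2 = r$alpha[2],
                         alpha3 = r$alpha[3], kappa1 = r$kappa[1],
                         kappa2 = r$kappa[2], kappa3 = r$kappa[3],
                         kappa4 = r$kappa[4], n0_1 = truth_n0()[1],
                         n0_2 = truth_n0()[2], n0_3 = truth_n0()[3],
                         n0_4 = truth_n0()[4]))
  fit <- fit_joint(pooled, fixed = fixed)
  spec <- labeling_specificity(fit, ci = FALSE)
  expect_equal(spec$ratios$ratio[spec$ratios$dataset == "tie2-like"], 21)
  expect_equal(spec$ratios$ratio[spec$ratios$dataset == "fgd5-like"], 4)
  rr <- spec$ratio_of_ratios
  expect_equal(rr$ratio_of_ratios[rr$A == "tie2-like" & rr$B == "fgd5-like"],
               21 / 4)
})
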