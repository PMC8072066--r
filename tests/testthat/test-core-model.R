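test_that("population solver handles degenerate and closed-form cases", {
  # all rates zero: counts constant
  r0 <- kinetic_rates(alpha = rep(0, 4), beta = rep(0, 4))
  tr <- solve_populations(r0, initial_state(c(100, 500, 1000, 5000)),
                          times = seq(0, 50, by = 5))
  expect_equal(max(abs(sweep(tr$n, 2, c(100, 500, 1000, 5000)))), 0,
               tolerance = 1e-9)

  # single compartment: pure exponential decay
  topo1 <- model_topology("HSC")
  r1 <- kinetic_rates(alpha = 0.1, beta = 0, topology = topo1)
  tr1 <- solve_populations(r1, initial_state(1000, topology = topo1),
                           times = c(0, 10))
  expect_equal(unname(tr1$n[2, 1]), 1000 * exp(-1), tolerance = 1e-8)
})

test_that("closed-form cascade reduces to textbook special cases", {
  topo1 <- model_topology("A")
  r1 <- kinetic_rates(alpha = 0.3, beta = 0.1, topology = topo1)
  tr1 <- closed_form_cascade(r1, initial_state(7, topology = topo1),
                             times = c(0, 1, 5))
  expect_equal(tr1$n[, 1], 7 * exp(-0.2 * c(0, 1, 5)))

  # two-compartment chain with kappa = (1, 2), alpha1 = 1, n(0) = (1, 0):
  # n2(t) = exp(-t) - exp(-2t)
  topo2 <- model_topology(c("A", "B"))
  r2 <- kinetic_rates(alpha = c(1, 0), beta = c(0, -2), topology = topo2)
  tt <- seq(0, 4, by = 0.5)
  tr2 <- closed_form_cascade(r2, initial_state(c(1, 0), topology = topo2),
                             times = tt)
  expect_equal(tr2$n[, 2], exp(-tt) - exp(-2 * tt), tolerance = 1e-12)
})

test_that("degenerate spectra are perturbed with a warning or rejected", {
  r <- kinetic_rates(alpha = c(0.1, 0.1, 0.1, 0.1),
                     beta = c(0.05, 0.05, 0.02, 0.01))
  init <- initial_state(c(100, 100, 100, 100))
  expect_warning(closed_form_cascade(r, init, c(0, 10)),
                 "degenerate spectrum")
  expect_error(closed_form_cascade(r, init, c(0, 10), degenerate = "error"),
               "degenerate spectrum")
  # the perturbed solution still matches the ODE integrator closely
  tr_a <- suppressWarnings(closed_form_cascade(r, init, seq(0, 100, 10)))
  tr_n <- solve_populations(r, init, seq(0, 100, 10))
  expect_lt(rel_err(tr_a$n, tr_n$n), 1e-5)
})

test_that("numerical and analytic cascade solutions agree on random instances", {
  set.seed(11)
  for (i in 1:20) {
    inst <- random_instance()
    tt <- seq(0, 100, by = 5)
    ana <- closed_form_cascade(inst$rates, inst$init, tt)
    num <- solve_populations(inst$rates, inst$init, tt,
                             rtol = 1e-11, atol = 1e-13)
    expect_lt(rel_err(num$n, ana$n), 1e-8)
  }
})

test_that("label-frequency dynamics have the expected fixed points and limits", {
  r <- truth_rates()
  n0 <- truth_n0()
  tt <- seq(0, 280, by = 14)

  # uniform initial frequency is a fixed point
  trf <- solve_label_frequencies(r, initial_state(n0, rep(0.3, 4)), tt)
  expect_equal(max(abs(trf$f - 0.3)), 0, tolerance = 1e-10)

  # zero stays zero
  tr0 <- solve_label_frequencies(r, initial_state(n0, rep(0, 4)), tt)
  expect_equal(max(abs(tr0$f)), 0, tolerance = 1e-12)

  # fully labeled top, positive downstream kappa: all frequencies -> 1
  rr <- kinetic_rates(alpha = c(0.05, 0.2, 0.2, 0.2),
                      beta = c(0.05, 0.1, 0.1, 0.1))
  trc <- solve_label_frequencies(rr, initial_state(n0, c(1, 0, 0, 0)),
                                 times = seq(0, 2000, by = 50))
  expect_true(all(trc$f[nrow(trc$f), ] > 0.999))
})

test_that("labeled-count and label-frequency solvers are consistent", {
  r <- truth_rates()
  init <- initial_state(truth_n0(), c(0.3, 0.05, 0.02, 0.01))
  tt <- seq(0, 280, by = 14)
  lc <- solve_labeled_counts(r, init, tt)
  lf <- solve_label_frequencies(r, init, tt)
  expect_lt(rel_err(lc$l / lc$n, lf$f), 1e-8)

  # f0 = 1 everywhere: labeled system identical to the population system
  l1 <- solve_labeled_counts(r, initial_state(truth_n0(), rep(1, 4)), tt)
  expect_equal(l1$l, l1$n, tolerance = 1e-10)
  # f0 = 0: no labeled cells ever
  l0 <- solve_labeled_counts(r, initial_state(truth_n0(), rep(0, 4)), tt)
  expect_equal(max(abs(l0$l)), 0, tolerance = 1e-12)
})

test_that("frequencies stay within [0,1] for random instances", {
  set.seed(22)
  for (i in 1:10) {
    K <- 4
    repeat {
      kappa <- runif(K, -0.02, 0.2)
      if (min(abs(outer(kappa, kappa, "-"))[lower.tri(matrix(0, K, K))]) >
          1e-3) break
    }
    alpha <- runif(K, 0.001, 0.5)
    rates <- kinetic_rates(alpha, beta = alpha - kappa)
    init <- initial_state(runif(K, 10, 1e4), runif(K), rates$topology)
    tr <- solve_label_frequencies(rates, init, times = seq(0, 50, by = 5))
    expect_true(all(tr$f >= -1e-6 & tr$f <= 1 + 1e-6))
  }
})

test_that("HSC-gate aggregation mixes the hidden subcompartments by size", {
  r <- truth_rates()
  tt <- seq(0, 50, by = 10)

  # equal frequencies: aggregate equals the common frequency
  tr <- solve_label_frequencies(r, initial_state(truth_n0(),
                                                 c(0.4, 0.4, 0.4, 0.4)), tt)
  agg <- aggregate_hsc_observable(tr)
  expect_equal(agg$f_hsc, rep(0.4, length(tt)), tolerance = 1e-9)

  # empty HSC-D at t=0: aggregate equals the HSC-U frequency at t=0
  init_d0 <- initial_state(c(400, 0, 9000, 30000), c(0.5, 0, 0, 0))
  tr2 <- solve_labeled_counts(r, init_d0, c(0, 1))
  agg2 <- aggregate_hsc_observable(tr2)
  expect_equal(agg2$f_hsc[1], 0.5, tolerance = 1e-9)

  # equal sizes, frequencies (0.5, 0): mixture gives 0.25
  init_eq <- initial_state(c(1000, 1000, 100, 100), c(0.5, 0, 0, 0))
  tr3 <- solve_label_frequencies(r, init_eq, c(0, 1))
  expect_equal(aggregate_hsc_observable(tr3)$f_hsc[1], 0.25,
               tolerance = 1e-9)
})

test_that("aggregate HSC frequency rises when labeling is U-biased", {
  r <- truth_rates()
  tt <- seq(0, 280, by = 7)
  tr <- solve_label_frequencies(r, initial_state(truth_n0(),
                                                 c(0.5, 0.1, 0.05, 0.02)),
                                tt)
  f <- aggregate_hsc_observable(tr)$f_hsc
  expect_true(all(diff(f) > -1e-10))
})

test_that("normalization to the HSC gate behaves at its fixed points", {
  r <- truth_rates()
  tt <- seq(0, 100, by = 10)
  tr <- solve_label_frequencies(r, initial_state(truth_n0(),
                                                 rep(0.25, 4)), tt)
  nz <- normalize_to_hsc(tr)
  expect_equal(nz$f_st_norm, rep(1, length(tt)), tolerance = 1e-9)
  expect_equal(nz$f_mpp_norm, rep(1, length(tt)), tolerance = 1e-9)
})

test_that("identical kinetics with different HSC-subcompartment labeling give different normalized curves", {
  r <- truth_rates()
  n0 <- truth_n0()
  tt <- seq(0, 280, by = 7)
  trI <- solve_label_frequencies(r, initial_state(n0, c(0.5, 0, 0, 0)), tt)
  trJ <- solve_label_frequencies(r, initial_state(n0, c(0.5, 0.5, 0, 0)), tt)
  expect_lt(rel_err(trI$n, trJ$n), 1e-9)
  dmax <- max(abs(normalize_to_hsc(trI)$f_st_norm -
                  normalize_to_hsc(trJ)$f_st_norm))
  expect_gt(dmax, 0.05)
})

test_that("steady-state model relaxes single-exponentially and matches the general solver", {
  tt <- seq(0, 400, by = 2)
  ss <- steady_state_model(kappa = c(NA, 0.05, 0.02), f0 = c(1, 0, 0), tt)
  expect_equal(ss$f_st, 1 - exp(-0.05 * tt), tolerance = 1e-8)
  expect_equal(ss$f_hsc, rep(1, length(tt)))

  # uniform frequencies stay constant
  ssu <- steady_state_model(kappa = c(NA, 0.1, 0.3), f0 = rep(0.4, 3), tt)
  expect_equal(max(abs(as.matrix(ssu[, c("f_hsc", "f_st", "f_mpp")]) - 0.4)),
               0, tolerance = 1e-10)

  # general non-steady solver with beta chosen for stationary n reproduces it
  topo3 <- model_topology(c("HSC", "ST", "MPP"))
  n0 <- c(1000, 2000, 10000)
  alpha <- c(0.05, 0.1, 0.08)
  kappa <- c(0, alpha[1] * n0[1] / n0[2], alpha[2] * n0[2] / n0[3])
  r3 <- kinetic_rates(alpha, beta = alpha - kappa, topology = topo3)
  f0 <- c(0.8, 0.1, 0)
  gen <- solve_label_frequencies(r3, initial_state(n0, f0, topo3), tt)
  expect_lt(max(abs(gen$n[nrow(gen$n), ] - n0) / n0), 1e-9)  # stationary
  ss3 <- steady_state_model(kappa = kappa, f0 = f0, tt)
  expect_equal(gen$f[, 2], ss3$f_st, tolerance = 1e-8)
  expect_equal(gen$f[, 3], ss3$f_mpp, tolerance = 1e-8)

  expect_error(steady_state_model(kappa = c(NA, -0.1, 0.1),
                                  f0 = c(1, 0, 0), tt),
               "positive")
})

test_that("frequency solver reports the failing compartment for vanishing pools", {
  topo <- model_topology(c("HSC-U", "HSC-D", "ST-HSC", "MPP"))
  r <- kinetic_rates(alpha = c(0, 0, 0, 0), beta = c(0, 0, 0, 0),
                     topology = topo)
  init <- initial_state(c(100, 0, 100, 100), c(0.5, 0, 0, 0), topo)
  expect_error(solve_label_frequencies(r, init, c(0, 10)), "HSC-D")
})
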