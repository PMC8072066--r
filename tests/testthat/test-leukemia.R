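random_split_rates <- function() {
  K <- 4
  repeat {
    alpha <- runif(K, 0.01, 0.4)
    lambda <- runif(K, 0.02, 0.4)
    delta <- runif(K, 0, 0.1)
    kappa <- alpha - (lambda - delta)
    d <- abs(outer(kappa, kappa, "-")); diag(d) <- Inf
    if (min(d) > 1e-3) break
  }
  kinetic_rates(alpha, lambda = lambda, delta = delta)
}

test_that("mutant kinetics follow the proliferation-factor rule", {
  topo1 <- model_topology("X")
  r <- kinetic_rates(alpha = 0.1, lambda = 0.1, delta = 0.02,
                     topology = topo1)
  sc <- mutation_scenario(1, 1.03, topology = topo1)
  mut <- apply_mutation(r, sc)
  # kappa_mut = alpha - (1.03 lambda - delta) = 0.1 - (0.103 - 0.02)
  expect_equal(mut$kappa, 0.017, tolerance = 1e-12)

  # factor 1 leaves everything unchanged
  r4 <- truth_rates()
  expect_equal(apply_mutation(r4, mutation_scenario("HSC-D", 1))$kappa,
               r4$kappa)

  # kappa_mut strictly decreasing in the factor where lambda > 0
  k1 <- apply_mutation(r4, mutation_scenario("ST-HSC", 1.05))$kappa[3]
  k2 <- apply_mutation(r4, mutation_scenario("ST-HSC", 1.10))$kappa[3]
  expect_lt(k2, k1)

  # upstream compartments untouched
  mu <- apply_mutation(r4, mutation_scenario("ST-HSC", 1.2))
  expect_equal(mu$kappa[1:2], r4$kappa[1:2])

  expect_error(mutation_scenario("HSC-U", 0.9), ">= 1")
  rb <- kinetic_rates(r4$alpha, beta = r4$beta)
  expect_error(apply_mutation(rb, mutation_scenario(1, 1.1)), "split")
})

test_that("the mutant cascade coincides with labeled counts at factor 1", {
  r <- truth_rates()
  n0 <- truth_n0()
  f0 <- c(0.2, 0.1, 0.05, 0.02)
  tt <- seq(0, 280, by = 14)
  l <- solve_labeled_counts(r, initial_state(n0, f0), tt)
  # seed the mutant system at the top with the labeled HSC-U count
  m <- solve_mutant(r, mutation_scenario(1, 1, m0 = f0[1] * n0[1]), tt)
  expect_lt(max(abs(m[, 1] - l$l[, 1])), 1e-9)

  # zero founder: no mutants ever
  m0 <- solve_mutant(r, mutation_scenario("HSC-D", 1.1, m0 = 0), tt)
  expect_equal(max(abs(m0)), 0)

  # analytic and ODE routes agree on random instances
  set.seed(5)
  for (i in 1:5) {
    rr <- random_split_rates()
    sc <- mutation_scenario(sample(1:4, 1), 1 + runif(1, 0, 0.2))
    ma <- solve_mutant(rr, sc, tt)
    mo <- solve_mutant(rr, sc, tt, method = "ode")
    expect_lt(max(abs(ma - mo)) / max(ma), 1e-7)
  }
})

test_that("mutant MPP fraction has the expected degenerate behavior", {
  r <- truth_rates()
  n0 <- truth_n0()
  tt <- seq(0, 1000, by = 10)

  # no founder: p identically zero
  p0 <- mutant_mpp_fraction(r, mutation_scenario("MPP", 1.2, m0 = 0),
                            n0, tt)
  expect_equal(max(abs(p0$p)), 0)

  # whole MPP pool mutant at factor 1: identical dynamics under a
  # stationary MPP pool, p constant at 1/2 of the doubled denominator
  rs <- kinetic_rates(alpha = c(0, 0, 0, 0.1), beta = c(0, 0, 0, 0.1),
                      lambda = c(0, 0, 0, 0.1) + 0.1,
                      delta = c(0.1, 0.1, 0.1, 0.1))
  ps <- mutant_mpp_fraction(rs, mutation_scenario("MPP", 1, m0 = n0[4]),
                            n0, tt)
  expect_equal(ps$p, rep(1, length(tt)), tolerance = 1e-5)

  # washout below threshold, saturation above (bounded denominator)
  p_weak <- mutant_mpp_fraction(r, mutation_scenario("MPP", 1.01), n0, tt)
  expect_lt(tail(p_weak$p, 1), 1e-6)
  p_strong <- mutant_mpp_fraction(r, mutation_scenario("MPP", 1.15), n0,
                                  tt, include_mutants = TRUE)
  expect_gt(tail(p_strong$p, 1), 0.999)
})

test_that("bisection and closed-form immortality thresholds agree", {
  # single compartment: x* = (alpha + delta) / lambda = 1.5
  topo1 <- model_topology("X")
  r1 <- kinetic_rates(alpha = 0.1, lambda = 0.1, delta = 0.05,
                      topology = topo1)
  expect_equal(threshold_closed_form(r1, 1)$x_star, 1.5)
  expect_equal(find_immortal_threshold(r1, 1)$x_star, 1.5,
               tolerance = 1e-3)

  set.seed(13)
  for (i in 1:20) {
    rr <- random_split_rates()
    s <- sample(1:4, 1)
    cf <- threshold_closed_form(rr, s)
    bi <- find_immortal_threshold(rr, s)
    expect_lt(abs(cf$x_star - bi$x_star), 1e-3)
    if (cf$x_star > 1)
      expect_equal(cf$critical_compartment, bi$critical_compartment)
  }
})

test_that("thresholds are ordered along the hierarchy and detect expanding origins", {
  set.seed(17)
  for (i in 1:20) {
    rr <- random_split_rates()
    xs <- vapply(1:4, function(s) threshold_closed_form(rr, s)$x_star, 0)
    expect_true(all(diff(xs) >= -1e-12))
  }
  # an origin already expanding at x = 1 needs no increase at all
  r <- truth_rates()
  expect_true(r$kappa[1] < 0)
  expect_equal(threshold_closed_form(r, "HSC-U")$x_star, 1)
  expect_equal(find_immortal_threshold(r, "HSC-U")$x_star, 1)
  expect_true(find_immortal_threshold(r, "HSC-U")$at_one)
})

test_that("sub- and supra-threshold dynamics bracket the threshold", {
  r <- truth_rates()
  n0 <- truth_n0()
  tt <- seq(0, 4000, by = 20)
  for (org in c("ST-HSC", "MPP")) {
    xs <- threshold_closed_form(r, org)$x_star
    below <- mutant_mpp_fraction(r, mutation_scenario(org, xs - 0.01),
                                 n0, tt)
    above <- mutant_mpp_fraction(r, mutation_scenario(org, xs + 0.01),
                                 n0, tt)
    n_half <- length(tt) %/% 2
    # washout below: late fraction far below its peak
    expect_lt(tail(below$p, 1), 0.05 * max(below$p))
    # unbounded mutant growth above
    expect_gt(tail(above$m_mpp, 1), 10 * above$m_mpp[n_half])
  }
})

test_that("the scenario scan reports the standard factor grid", {
  r <- truth_rates()
  scan <- leukemogenesis_scan(r, origins = c("HSC-U", "MPP"),
                              horizon_days = 140, by_days = 14)
  expect_equal(sort(unique(scan$factor)), c(1.03, 1.08, 1.15))
  expect_equal(sort(unique(scan$origin)), c("HSC-U", "MPP"))
  expect_true(all(scan$p >= 0))
})
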