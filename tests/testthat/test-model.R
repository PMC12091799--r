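test_that("right-hand sides reproduce direct arithmetic on the presets", {
  p <- p1_high$params
  # extinction fixed point
  expect_identical(unname(tumor_rhs(c(0, 0), p)), c(0, 0))
  # patient 1 at the initial state, against the independent oracle
  want <- rhs_oracle(0.284, 0.284, p)
  got <- unname(tumor_rhs(c(0.284, 0.284), p))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, c(-0.0034655, -0.1631808), tolerance = 1e-4)
  # untreated, cancer-free: logistic fixed point of x1 at carrying capacity
  p0 <- tumor_params(p$alpha1, p$alpha2, p$K1, p$K2, p$beta1, p$beta2,
                     epsilon = p$epsilon, gamma = 0)
  expect_equal(tumor_rhs(c(p0$K1, 0), p0)[["F1"]], 0)
})

test_that("boundary equilibria and feasibility flags are correct", {
  p <- p1_high$params
  eq <- equilibria(p)
  expect_equal(unname(eq$E0),
               c(p$K1 * (p$alpha1 - p$gamma * p$epsilon) / p$alpha1, 0),
               tolerance = 1e-15)
  expect_equal(eq$E0[["x1"]], 0.381704, tolerance = 1e-5)
  expect_equal(eq$E_star[["x2"]], (0.3396 - 0.75) / 0.3396, tolerance = 1e-6)
  expect_true(eq$E0_feasible)
  expect_false(eq$E_star_feasible)
  # no treatment recovers the carrying capacity
  p0 <- tumor_params(p$alpha1, p$alpha2, p$K1, p$K2, p$beta1, p$beta2,
                     epsilon = 0.3, gamma = 0)
  expect_equal(unname(equilibria(p0)$E0), c(p0$K1, 0))
  # equilibria are fixed points of the rhs (feasible ones to rounding)
  expect_equal(max(abs(tumor_rhs(eq$E0, p))), 0, tolerance = 1e-12)
  expect_equal(max(abs(tumor_rhs(eq$E_star, p))), 0, tolerance = 1e-12)
})

test_that("threshold ratios match their definitions on both dose arms", {
  p <- p1_high$params
  th <- thresholds(p)
  expect_equal(th[["R0"]], 0.3396 / (0.75 + 0.2385), tolerance = 1e-12)
  expect_equal(th[["R0"]], 0.343551, tolerance = 1e-5)
  expect_equal(th[["Rh"]], (9.7041e-4 - 0.0008 * 0.75) / 0.0433,
               tolerance = 1e-12)
  expect_equal(th[["Rh"]], 0.0085545, tolerance = 1e-4)
  plow <- patient_preset(1, "low")$params
  expect_equal(thresholds(plow)[["R0"]], 0.3396 / (0.35 + 0.2385),
               tolerance = 1e-12)
  expect_equal(thresholds(plow)[["R0"]], 0.577060, tolerance = 1e-5)
})

test_that("analytic Jacobian agrees with central finite differences", {
  p <- p1_high$params
  set.seed(7)
  states <- random_state_in_box(25)
  h <- 1e-6
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    J <- tumor_jacobian(s, p)
    fd <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      fd[, j] <- (tumor_rhs(s + e, p) - tumor_rhs(s - e, p)) / (2 * h)
    }
    expect_equal(unname(J), fd, tolerance = 1e-6)
  }
  # frozen entry at E0
  eq <- equilibria(p)
  expect_equal(tumor_jacobian(eq$E0, p)[2, 2],
               0.3396 - 0.75 - 0.2385 * eq$E0[["x1"]], tolerance = 1e-12)
  expect_equal(tumor_jacobian(eq$E0, p)[2, 2], -0.501436, tolerance = 1e-5)
})

test_that("local stability verdicts follow the Matignon condition", {
  p <- p1_high$params
  for (mu in c(0.05, 0.5, 0.75, 1)) {
    st <- local_stability(p, mu)
    # both eigenvalues at E0 real and negative: stable for every mu
    expect_true(all(Re(st$eigenvalues_at_E0) < 0))
    expect_true(all(abs(Im(st$eigenvalues_at_E0)) < 1e-14))
    expect_true(st$matignon_E0)
    expect_true(st$dose_criterion)
  }
  expect_equal(Re(sort(local_stability(p, 1)$eigenvalues_at_E0))[1],
               -0.501436, tolerance = 1e-5)
  # over-irradiated healthy cells: gamma*epsilon > alpha1 destabilizes E0
  pbad <- tumor_params(1e-4, 0.3396, 1, 1, 0.0433, 0.2385,
                       epsilon = 0.5, gamma = 0.75)
  for (mu in c(0.3, 1)) {
    st <- local_stability(pbad, mu)
    expect_false(st$matignon_E0)
    expect_false(st$dose_criterion)
  }
  # as-printed lambda2 on patient 1, for comparison only
  expect_equal(jacobian_E0_printed(p)$eigenvalues[["lambda2"]],
               -0.766528, tolerance = 1e-5)
})

test_that("lambda2 at E0 is negative exactly when alpha2 < gamma + beta2 x1(E0)", {
  set.seed(11)
  for (i in 1:200) {
    p <- tumor_params(alpha1 = stats::runif(1, 1e-4, 0.5),
                      alpha2 = stats::runif(1, 0.05, 2),
                      K1 = stats::runif(1, 0.5, 2), K2 = stats::runif(1, 0.5, 2),
                      beta1 = stats::runif(1, 0, 1), beta2 = stats::runif(1, 0, 1),
                      epsilon = stats::runif(1, 0, 0.01),
                      gamma = stats::runif(1, 0, 1))
    eq <- equilibria(p)
    l2 <- tumor_jacobian(eq$E0, p)[2, 2]
    expect_identical(l2 < 0, p$alpha2 < p$gamma + p$beta2 * eq$E0[["x1"]])
  }
})

test_that("all six treated presets satisfy R0 < 1 and gamma*epsilon < alpha1", {
  for (sc in scenario_list) {
    th <- thresholds(sc$params)
    expect_lt(th[["R0"]], 1)
    expect_lt(sc$params$gamma * sc$params$epsilon, sc$params$alpha1)
  }
})

test_that("invariant-region check flags violations and accepts interior orbits", {
  p <- p1_high$params
  const <- list(times = 0:10, x1 = rep(p$K1 / 2, 11), x2 = rep(p$K2 / 2, 11))
  rep1 <- check_invariant_region(const, p)
  expect_true(rep1$all_inside)
  expect_true(rep1$limsup_ok)
  expect_equal(rep1$fraction_inside, 1)
  bad <- list(times = 0:10, x1 = c(rep(0.5, 10), 1.5 * p$K1), x2 = rep(0.1, 11))
  rep2 <- check_invariant_region(bad, p)
  expect_false(rep2$all_inside)
  expect_lt(rep2$fraction_inside, 1)
  # a treated simulation stays inside the box throughout
  tr <- integrate_classical(p1_high$params, simulation_grid(0.1, t_end = 400),
                            p1_high$init)
  rep3 <- check_invariant_region(tr, p)
  expect_true(rep3$all_inside)
  expect_true(rep3$limsup_ok)
})

test_that("parameter constructor enforces positivity and non-negativity", {
  expect_error(tumor_params(-1, 1, 1, 1, 0, 0), "non-negative")
  expect_error(tumor_params(0, 1, 1, 1, 0, 0), "strictly positive")
  expect_error(tumor_params(1, 1, 0, 1, 0, 0), "strictly positive")
  expect_error(thresholds(tumor_params(1, 1, 1, 1, 0, 0.1)), "degenerate")
})
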