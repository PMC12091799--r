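test_that("scheme weights: newest node, classical collapse, frozen values", {
  for (mu in c(0.3, 0.75, 1)) {
    w <- scheme_weights(12, 12, mu)    # newest node: q = 1, p = 0
    expect_equal(w$w1, 2 + mu, tolerance = 1e-14)
    expect_equal(w$w2, 1, tolerance = 1e-14)
  }
  # mu = 1: (3, 1) for every lag up to p = 10^4
  w <- scheme_weights(10000, 0:10000, 1)
  expect_true(all(abs(w$w1 - 3) < 1e-8))
  expect_true(all(abs(w$w2 - 1) < 1e-8))
  # direct arithmetic at mu = 0.5, q = 2, p = 1
  w <- scheme_weights(1, 0, 0.5)
  expect_equal(w$q, 2); expect_equal(w$p, 1)
  expect_equal(w$w1, sqrt(2) * 3.5 - 4, tolerance = 1e-14)
  expect_equal(w$w2, 2^1.5 - 2.5, tolerance = 1e-14)
  expect_error(scheme_weights(3, 4, 0.5), "v <= r")
})

test_that("scheme weights are positive across lags and orders", {
  q <- 1:1000
  for (mu in c(0.05, 0.3, 0.6, 0.9, 1)) {
    w1 <- q^mu * (q + 1 + mu) - (q - 1)^mu * (1 + 2 * mu + q)
    w2 <- q^(mu + 1) - (q - 1)^mu * (q + mu)
    expect_true(all(w1 > 0), label = sprintf("w1 > 0, mu = %g", mu))
    expect_true(all(w2 > 0), label = sprintf("w2 > 0, mu = %g", mu))
    wi <- scheme_weights(999, 0:999, mu)
    expect_equal(wi$w1, rev(w1), tolerance = 1e-12)
    expect_equal(wi$w2, rev(w2), tolerance = 1e-12)
  }
})

test_that("zero right-hand side leaves the state constant for any (mu, nu)", {
  p <- p1_high$params
  g <- simulation_grid(0.1, t_end = 5)
  for (spec in list(fractional_spec(1, 1), fractional_spec(0.7, 0.9))) {
    tr <- suppressMessages(integrate_ffm(p, spec, g, c(0, 0)))
    expect_true(all(tr$x1 == 0))
    expect_true(all(tr$x2 == 0))
  }
})

test_that("classical limit of the scheme matches the adaptive oracle", {
  g <- simulation_grid(0.01, t_end = 200)
  tr <- integrate_ffm(p1_high$params, classical_spec, g, p1_high$init)
  cl <- integrate_classical(p1_high$params, g, p1_high$init)
  expect_lt(max(abs(tr$x1 - cl$x1), abs(tr$x2 - cl$x2)), 1e-4)
  # initial condition preserved exactly; lengths as specified
  expect_identical(tr$x1[1], p1_high$init[["x1"]])
  expect_identical(tr$x2[1], p1_high$init[["x2"]])
  expect_length(tr$x1, g$n_steps + 1L)
})

test_that("classical oracle reproduces the logistic closed form", {
  p <- tumor_params(alpha1 = 0.2, alpha2 = 1e-9, K1 = 0.8, K2 = 1,
                    beta1 = 0, beta2 = 0, epsilon = 0, gamma = 0)
  g <- simulation_grid(0.5, t_end = 50)
  tr <- integrate_classical(p, g, c(0.1, 0))
  closed <- p$K1 / (1 + (p$K1 / 0.1 - 1) * exp(-p$alpha1 * tr$times))
  expect_equal(tr$x1, closed, tolerance = 1e-8)
  expect_true(all(tr$x2 == 0))
})

test_that("treated patient-1 orbit: fast extinction and dip-then-recover shape", {
  tr <- integrate_classical(p1_high$params, simulation_grid(0.05, t_end = 400),
                            p1_high$init)
  expect_lt(sample_trajectory(tr, 150)$x2, 1e-8)
  # healthy cells dip below their starting value before recovering
  imin <- which.min(tr$x1)
  expect_gt(imin, 1)
  expect_lt(tr$x1[imin], tr$x1[1])
  expect_gt(tr$x1[length(tr$x1)], tr$x1[imin])
})

test_that("self-convergence: second order at mu = 1, monotone refinement at mu < 1", {
  sc <- p1_high
  cs <- convergence_study(sc$params, classical_spec, sc$init, 50,
                          c(0.8, 0.4, 0.2, 0.1))
  expect_true(all(diff(cs$max_diff) < 0))
  expect_equal(cs$order[nrow(cs)], 2, tolerance = 0.25)
  csf <- convergence_study(sc$params, fractional_spec(0.75, 1), sc$init, 50,
                           c(0.8, 0.4, 0.2))
  expect_true(all(diff(csf$max_diff) < 0))
  expect_error(convergence_study(sc$params, classical_spec, sc$init, 50, 0.1),
               "descending")
})

test_that("memory effect: smaller mu holds malignant cells up longer", {
  sc <- p1_high
  mus <- c(0.75, 0.85, 0.95, 1)
  x2_at_100 <- vapply(mus, function(mu) {
    tr <- integrate_ffm(sc$params, fractional_spec(mu, 1),
                        simulation_grid(0.05, t_end = 100), sc$init)
    tr$x2[length(tr$x2)]
  }, numeric(1))
  expect_true(all(diff(x2_at_100) < 0))
})

test_that("trajectories of all treated presets remain in the invariant region", {
  for (sc in scenario_list) {
    tr <- integrate_ffm(sc$params, classical_spec,
                        simulation_grid(0.05, t_end = 400), sc$init)
    rep1 <- check_invariant_region(tr, sc$params)
    expect_true(rep1$all_inside, label = sc$label)
    expect_true(rep1$limsup_ok, label = sc$label)
  }
})

test_that("trajectory CSV is bit-stable with provenance headers", {
  tr <- integrate_ffm(p1_high$params, classical_spec,
                      simulation_grid(0.5, t_end = 10), p1_high$init,
                      label = "patient1-high")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  write_trajectory_csv(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_true(any(startsWith(lines, "# patient=patient1-high")))
  expect_true(any(startsWith(lines, "# scheme=ffm-lagrange2")))
  body <- utils::read.csv(f1, comment.char = "#")
  expect_identical(body$x1, tr$x1)
  unlink(c(f1, f2))
})

test_that("grid construction and integrator input validation", {
  expect_error(simulation_grid(0), "positive")
  expect_error(simulation_grid(0.1), "t_end")
  g <- simulation_grid(0.1, t_end = 1)
  expect_identical(g$n_steps, 10L)
  expect_error(integrate_ffm(p1_high$params, classical_spec, g, c(-0.1, 0)),
               "non-negative")
})
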