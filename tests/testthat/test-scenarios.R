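test_that("patient presets carry the published parameters and initial states", {
  sc <- patient_preset(1, "high")
  expect_equal(sc$params$gamma, 0.75)
  expect_equal(unname(sc$init), c(0.284, 0.284))
  expect_equal(sc$params$alpha1, 9.7041e-4)
  expect_equal(sc$params$alpha2, 0.3396)
  expect_equal(sc$params$beta1, 0.0433)
  expect_equal(sc$params$beta2, 0.2385)
  expect_equal(sc$params$epsilon, 0.0008)
  expect_equal(sc$params$K1, 1); expect_equal(sc$params$K2, 1)
  expect_equal(patient_preset(2, "high")$params$gamma, 0.65)
  expect_equal(unname(patient_preset(2, "high")$init), c(0.174, 0.174))
  expect_equal(patient_preset(3, "low")$params$gamma, 0.35)
  expect_equal(unname(patient_preset(3, "low")$init), c(0.306, 0.306))
  expect_error(patient_preset(4, "high"), "must be 1, 2 or 3")
  expect_error(patient_preset(1, "medium"))
})

test_that("preset table round-trips bit-exactly through reconstruction", {
  tab <- patient_table()
  expect_identical(nrow(tab), 6L)
  for (i in seq_len(nrow(tab))) {
    rebuilt <- tumor_params(tab$alpha1[i], tab$alpha2[i], tab$K1[i], tab$K2[i],
                            tab$beta1[i], tab$beta2[i], tab$epsilon[i],
                            tab$gamma[i])
    orig <- patient_preset(tab$patient[i], tab$arm[i])$params
    expect_identical(unclass(rebuilt), unclass(orig))
  }
})

test_that("published-table fixture has the expected extinction structure", {
  for (p in 1:3) {
    pt <- printed_tables(p)
    expect_identical(dim(pt$cancer), c(8L, 4L))
    # cancer-cell values non-increasing down every column
    expect_true(all(apply(pt$cancer, 2, function(col) all(diff(col) <= 0))))
    # and non-increasing in mu across every row
    expect_true(all(apply(pt$cancer, 1, function(row) all(diff(row) <= 0))))
  }
  expect_identical(printed_tables(1)$cancer["150", "1"], 0)
  expect_identical(printed_tables(2)$cancer["150", "1"], 0)
  expect_identical(printed_tables(3)$cancer["200", "1"], 0)
})

test_that("synthetic observations: exactness at zero noise, seeded determinism", {
  sc <- patient_preset(1, "high")
  g <- simulation_grid(0.5, t_end = 50)
  tr <- integrate_ffm(sc$params, classical_spec, g, sc$init)
  obs0 <- synthesize_observations(sc, classical_spec, g, 0, seed = 4L)
  expect_identical(obs0$x1_obs, tr$x1)
  expect_identical(obs0$x2_obs, tr$x2)
  obs1 <- synthesize_observations(sc, classical_spec, g, 0.005, seed = 4L)
  obs2 <- synthesize_observations(sc, classical_spec, g, 0.005, seed = 4L)
  expect_identical(obs1$x1_obs, obs2$x1_obs)
  obs3 <- synthesize_observations(sc, classical_spec, g, 0.005, seed = 5L)
  expect_false(identical(obs1$x1_obs, obs3$x1_obs))
  # residual standard deviation near the nominal level
  res <- c(obs1$x1_obs - tr$x1, obs1$x2_obs - tr$x2)
  expect_gt(stats::sd(res), 0.004)
  expect_lt(stats::sd(res), 0.006)
})

test_that("observation CSV round-trips", {
  sc <- patient_preset(2, "high")
  obs <- synthesize_observations(sc, classical_spec,
                                 simulation_grid(1, t_end = 20), 0.002,
                                 seed = 8L)
  f <- tempfile(fileext = ".csv")
  write_observations_csv(obs, f)
  back <- read_observations_csv(f)
  expect_equal(back$times, obs$times)
  expect_equal(back$x1_obs, obs$x1_obs)
  expect_equal(back$x2_obs, obs$x2_obs)
  expect_error(read_observations_csv({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), f2, row.names = FALSE); f2
  }), "columns")
  unlink(f)
})

test_that("zero-noise fits recover free parameters to high accuracy", {
  sc <- patient_preset(1, "high")
  g <- simulation_grid(0.25, t_end = 50)
  obs <- synthesize_observations(sc, classical_spec, g, 0, seed = 2L)
  fit <- least_squares_fit(obs, sc, free = "gamma",
                           lower = c(gamma = 0.1), upper = c(gamma = 2),
                           spec = classical_spec, n_starts = 3L, seed = 2L)
  expect_lt(abs(fit$par[["gamma"]] - 0.75), 1e-4)
  expect_true(fit$converged)
  # two free parameters, self-consistency of the optimum
  fit2 <- least_squares_fit(obs, sc, free = c("alpha2", "gamma"),
                            lower = c(alpha2 = 0.05, gamma = 0.1),
                            upper = c(alpha2 = 1, gamma = 2),
                            spec = classical_spec, n_starts = 4L, seed = 3L)
  expect_lt(fit2$rss, 1e-10)
})

test_that("fit input validation", {
  sc <- patient_preset(1, "high")
  obs <- synthesize_observations(sc, classical_spec,
                                 simulation_grid(1, t_end = 10), 0, seed = 1L)
  expect_error(least_squares_fit(obs, sc, free = "not_a_param",
                                 lower = c(not_a_param = 0),
                                 upper = c(not_a_param = 1),
                                 spec = classical_spec), "model parameter")
  expect_error(least_squares_fit(obs, sc, free = "gamma",
                                 lower = c(gamma = 1), upper = c(gamma = 0.1),
                                 spec = classical_spec), "bounds")
})

test_that("flat key-value config parses numerics and rejects malformed lines", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "gamma = 0.75", "mu = 0.85", "label = run-a", ""), f)
  cfg <- read_config(f)
  expect_identical(cfg$gamma, 0.75)
  expect_identical(cfg$mu, 0.85)
  expect_identical(cfg$label, "run-a")
  writeLines("garbage line", f)
  expect_error(read_config(f), "malformed")
  unlink(f)
})
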