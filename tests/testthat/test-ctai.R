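test_that("min-max normalization maps to [0,1] and inverts exactly", {
  r <- minmax_normalize(c(1, 2, 3))
  expect_equal(r$x, c(0, 0.5, 1))
  expect_equal(r$min, 1); expect_equal(r$max, 3)
  # idempotent on a unit-range vector
  expect_equal(minmax_normalize(c(0, 0.25, 1))$x, c(0, 0.25, 1))
  set.seed(5)
  v <- rnorm(50)
  r <- minmax_normalize(v)
  expect_equal(r$x * (r$max - r$min) + r$min, v, tolerance = 1e-12)
  expect_equal(range(r$x), c(0, 1))
  expect_error(minmax_normalize(rep(1, 5)), "degenerate")
  expect_error(minmax_normalize(1), "2 elements")
})

test_that("component regression matches closed-form least squares", {
  t <- seq(0, 1, length.out = 10)
  expect_equal(fit_component_regression(t, t)[c("slope", "intercept")],
               list(slope = 1, intercept = 0), tolerance = 1e-12)
  expect_equal(fit_component_regression(t, t)$theta, pi / 4,
               tolerance = 1e-12)
  r <- fit_component_regression(t, 0.5 * t + 0.2)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 0.2, tolerance = 1e-12)
  set.seed(9)
  y <- 0.8 * t + 0.1 + rnorm(10, sd = 0.05)
  r <- fit_component_regression(t, y)
  o <- ols_line(t, y)
  expect_equal(r$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(r$intercept, unname(o["intercept"]), tolerance = 1e-10)
  expect_error(fit_component_regression(rep(0.3, 5), t[1:5]),
               "degenerate")
})

test_that("identical instruments give zero deltas and master predictions", {
  for (seed in c(2, 13)) {
    sc <- generate_scenario(scenario_config(
      seed = seed, gain_scale = 1, gain_amplitude = 0,
      offset_amplitude = 0, scatter_sd = 0, noise_sd_slave = 0,
      baseline_amplitude = 0))
    m <- ctai(sc$master_cal, slave_x = sc$master_cal$spectra, ncomp = 3)
    expect_equal(m$delta_theta, rep(0, 3), tolerance = 1e-10)
    expect_equal(m$delta_b, rep(0, 3), tolerance = 1e-10)
    Xt <- sc$slave_test$spectra
    expect_equal(predict(m, Xt), predict(m$master, Xt),
                 tolerance = 1e-10)
  }
})

test_that("a pure prediction offset is corrected exactly", {
  sc <- generate_scenario(scenario_config(
    seed = 6, gain_scale = 1, gain_amplitude = 0, offset_amplitude = 0,
    scatter_sd = 0, noise_sd_slave = 0, baseline_amplitude = 0))
  master <- sc$master_cal
  m0 <- pls1(master, ncomp = 3)
  # build a slave whose pseudo-predictions are shifted by a constant:
  # add c * beta / ||beta||^2 to every spectrum
  shift <- 0.4 * m0$beta / sum(m0$beta^2)
  slave_cal <- sweep(master$spectra, 2L, shift, `+`)
  slave_test <- sweep(sc$slave_test_master_view$spectra, 2L, shift, `+`)
  expect_equal(predict(m0, slave_cal), predict(m0, master$spectra) + 0.4,
               tolerance = 1e-8)
  m <- ctai(master, slave_x = slave_cal, ncomp = 3,
            denorm_reference = "master")
  expect_equal(m$delta_theta, rep(0, 3), tolerance = 1e-8)
  expect_equal(predict(m, slave_test),
               predict(m0, sc$slave_test_master_view$spectra),
               tolerance = 1e-8)
})

test_that("delta angles are differences of principal arctangents", {
  sc <- generate_scenario(scenario_config(seed = 3))
  m <- ctai(sc$master_cal, slave_x = sc$slave_cal, ncomp = 4)
  th_m <- vapply(m$master_regs, `[[`, numeric(1), "theta")
  th_s <- vapply(m$slave_regs, `[[`, numeric(1), "theta")
  expect_true(all(abs(th_m) < pi / 2), all(abs(th_s) < pi / 2))
  expect_equal(m$delta_theta, th_m - th_s, tolerance = 1e-12)
  expect_equal(m$delta_b,
               vapply(m$master_regs, `[[`, numeric(1), "intercept") -
                 vapply(m$slave_regs, `[[`, numeric(1), "intercept"),
               tolerance = 1e-12)
  expect_true(all(abs(m$delta_theta) < pi))
  # antisymmetry: swapping the instruments negates the deltas
  swapped <- ctai(sc$master_cal, slave_x = sc$slave_cal, ncomp = 4)
  th_rev <- vapply(swapped$slave_regs, `[[`, numeric(1), "theta") -
    vapply(swapped$master_regs, `[[`, numeric(1), "theta")
  expect_equal(th_rev, -swapped$delta_theta, tolerance = 1e-12)
})

test_that("calibration normalization attains both extremes exactly", {
  sc <- generate_scenario(scenario_config(seed = 8))
  m <- ctai(sc$master_cal, slave_x = sc$slave_cal, ncomp = 3)
  Tm <- scores(m$master, sc$master_cal$spectra)
  for (i in 1:3) {
    r <- m$master_regs[[i]]
    tn <- (Tm[, i] - r$t_min) / (r$t_max - r$t_min)
    expect_equal(range(tn), c(0, 1), tolerance = 1e-12)
  }
})

test_that("the final prediction is the mean of per-component columns", {
  sc <- generate_scenario(scenario_config(seed = 10))
  m <- ctai(sc$master_cal, slave_x = sc$slave_cal, ncomp = 4)
  pc <- predict(m, sc$slave_test, components = TRUE)
  expect_equal(rowMeans(pc), predict(m, sc$slave_test),
               tolerance = 1e-12)
  expect_equal(dim(pc), c(20L, 4L))
})

test_that("correction reduces RMSEP on the default distorted scenario", {
  wins <- 0L
  ratios <- numeric(0)
  for (seed in 1:8) {
    sc <- generate_scenario(scenario_config(seed = seed))
    m <- ctai(sc$master_cal, slave_x = sc$slave_cal,
              ncomp = sc$config$k_components)
    u <- rmse(sc$slave_test$reference,
              predict(m$master, sc$slave_test))
    co <- rmse(sc$slave_test$reference, predict(m, sc$slave_test))
    wins <- wins + (co < u)
    ratios <- c(ratios, co / u)
  }
  expect_gte(wins, 7L)
  expect_lt(median(ratios), 0.5)
})

test_that("slave coefficient projection reproduces corrected predictions", {
  sc <- generate_scenario(scenario_config(seed = 14, n_test = 30, p = 25))
  m <- ctai(sc$master_cal, slave_x = sc$slave_cal, ncomp = 3)
  Xt <- sc$slave_test$spectra  # 30 x 25: full column rank
  sb <- slave_coefficients(m, Xt)
  yhat <- predict(m, Xt)
  # projection residual matches an independent pseudo-inverse solve
  beta_pinv <- drop(MASS::ginv(Xt) %*% yhat)
  expect_equal(sqrt(sum((yhat - Xt %*% beta_pinv)^2)), sb$residual_norm,
               tolerance = 1e-8)
  expect_false(sb$rank_deficient)
  # identity instruments: centered projection recovers the master beta
  # keep slave noise so the test batch has full column rank and the
  # least-squares solution is unique
  sc0 <- generate_scenario(scenario_config(
    seed = 15, n_test = 40, p = 30, gain_scale = 1, gain_amplitude = 0,
    offset_amplitude = 0, scatter_sd = 0, baseline_amplitude = 0))
  m0 <- ctai(sc0$master_cal, slave_x = sc0$master_cal$spectra, ncomp = 3)
  sb0 <- slave_coefficients(m0, sc0$slave_test$spectra, center = TRUE)
  expect_equal(sb0$beta, m0$master$beta, tolerance = 1e-6)
})

test_that("channel mismatches and degenerate ranges raise errors", {
  sc <- generate_scenario(scenario_config(seed = 1, p = 30))
  expect_error(ctai(sc$master_cal, slave_x = matrix(0, 10, 20),
                    ncomp = 2), "channel")
  flat <- matrix(1, 30, 30)
  expect_error(ctai(sc$master_cal, slave_x = flat, ncomp = 2),
               "degenerate")
})
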