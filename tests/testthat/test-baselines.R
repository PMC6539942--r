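test_that("slope/bias correction inverts an exact linear distortion", {
  y <- c(1, 2, 3, 4, 5)
  m <- fit_sbc(y, y)
  expect_equal(m$slope, 1, tolerance = 1e-12)
  expect_equal(m$bias, 0, tolerance = 1e-12)
  expect_equal(apply_sbc(m, y), y, tolerance = 1e-12)

  ys <- 0.5 * y + 1
  m <- fit_sbc(y, ys)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$bias, -2, tolerance = 1e-12)
  expect_equal(apply_sbc(m, ys), y, tolerance = 1e-12)

  set.seed(2)
  ys <- 0.7 * y + 0.3 + rnorm(5, sd = 0.1)
  m <- fit_sbc(y, ys)
  o <- ols_line(ys, y)
  expect_equal(m$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(m$bias, unname(o["intercept"]), tolerance = 1e-10)
  expect_error(fit_sbc(y, rep(2, 5)), "constant")
})

test_that("MSC leaves the reference shape invariant", {
  set.seed(3)
  ref_row <- abs(rnorm(40)) + sin(seq(0, 3, length.out = 40))
  X <- rbind(ref_row, 2 * ref_row + 3)
  r <- msc_reference(matrix(ref_row, 1))
  out <- msc_correct(X, r)
  expect_equal(out[1, ], ref_row, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(out[2, ], ref_row, tolerance = 1e-10, ignore_attr = TRUE)
  # corrected rows regress on the reference with slope 1, intercept 0
  Xr <- t(sapply(1:6, function(i) runif(1, 0.5, 2) * ref_row +
                   runif(1, -1, 1) + rnorm(40, sd = 0.01)))
  outr <- msc_correct(Xr, r)
  for (i in 1:6) {
    o <- ols_line(ref_row, outr[i, ])
    expect_equal(unname(o["slope"]), 1, tolerance = 1e-10)
    expect_equal(unname(o["intercept"]), 0, tolerance = 1e-10)
  }
})

test_that("PDS self-transfer is the identity and the band is sparse", {
  set.seed(4)
  sc <- generate_scenario(scenario_config(seed = 4, p = 40, n_cal = 25))
  S <- sc$master_cal$spectra[1:12, ]
  m <- fit_pds(S, S, window = 3, inner_lv = 3)
  expect_equal(apply_pds(m, S), S, tolerance = 1e-8, ignore_attr = TRUE)
  half <- (m$window - 1) / 2
  idx <- abs(row(m$transfer_matrix) - col(m$transfer_matrix)) > half
  expect_true(all(m$transfer_matrix[idx] == 0))
})

test_that("PDS inverts a smooth channel-wise gain on the standards", {
  sc <- generate_scenario(scenario_config(seed = 5, p = 50, n_cal = 30))
  M <- sc$master_cal$spectra
  g <- 1 + 0.3 * sin(seq(0, pi, length.out = 50))
  S <- sweep(M, 2L, g, `*`)
  m <- fit_pds(M, S, window = 3, inner_lv = 3)
  corrected <- apply_pds(m, S)
  expect_equal(corrected, M, tolerance = 1e-6 * max(abs(M)),
               ignore_attr = TRUE)
})

test_that("baseline self-transfer leaves predictions unchanged", {
  sc <- generate_scenario(scenario_config(seed = 6, p = 40))
  master <- pls1(sc$master_cal, ncomp = 3)
  X <- sc$master_cal$spectra
  pred <- predict(master, X)
  # SBC with identical instruments
  sm <- fit_sbc(pred, pred)
  expect_equal(apply_sbc(sm, pred), pred, tolerance = 1e-8)
  # MSC of the master spectra against their own mean, then predict
  r <- msc_reference(X)
  # only scatter-free rows map exactly; build exact multiples of the mean
  Z <- t(sapply(1:10, function(i) runif(1, 0.8, 1.2) * r$ref_spectrum))
  expect_equal(msc_correct(Z, r),
               matrix(r$ref_spectrum, 10, 40, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
  # PDS self-transfer then predict
  pm <- fit_pds(X[1:15, ], X[1:15, ], window = 5, inner_lv = 5)
  expect_equal(predict(master, apply_pds(pm, X[1:15, ])), pred[1:15],
               tolerance = 1e-6)
})

test_that("hyperparameter search finds a planted optimal window", {
  # slave = master shifted by one channel: window 3 can undo it, window
  # degenerating checks the grid machinery rather than the chemistry
  sc <- generate_scenario(scenario_config(seed = 7, p = 30, n_cal = 40))
  master <- pls1(sc$master_cal, ncomp = 3)
  M <- sc$master_cal$spectra
  g <- 1 + 0.2 * cos(seq(0, pi, length.out = 30))
  S <- sweep(M, 2L, g, `*`)
  ks <- kennard_stone(M, 20)
  std <- ks$calibration
  sel <- select_hyperparams("pds", master, M[std, ], S[std, ],
                            sc$master_cal$reference[std],
                            windows = c(3, 9, 15), folds = 5, seed = 1,
                            n_std_candidates = NULL)
  expect_true(sel$window %in% c(3, 9, 15))
  expect_equal(unname(which.min(sel$window_rmsecv)),
               which(c(3, 9, 15) == sel$window))
  # a channel-local distortion is best served by the smallest window
  expect_equal(sel$window, 3)

  # single candidate is returned unchanged
  one <- select_hyperparams("pds", master, M[std, ], S[std, ],
                            sc$master_cal$reference[std],
                            windows = 5, n_std_candidates = NULL)
  expect_equal(one$window, 5)

  # standard-count search over the Kennard-Stone prefix
  sbc_sel <- select_hyperparams("sbc", master, M[std, ], S[std, ],
                                sc$master_cal$reference[std],
                                n_std_candidates = 5:15)
  expect_true(sbc_sel$n_std %in% 5:15)
  expect_equal(unname(sbc_sel$n_std_rmse[as.character(sbc_sel$n_std)]),
               min(sbc_sel$n_std_rmse))
})

test_that("the default PDS window grid is the odd values 3 to 15", {
  expect_equal(eval(formals(select_hyperparams)$windows),
               c(3, 5, 7, 9, 11, 13, 15))
})
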