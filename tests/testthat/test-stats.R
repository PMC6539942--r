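test_that("rmse matches a direct two-line computation", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  set.seed(1)
  y <- rnorm(30); yhat <- rnorm(30)
  expect_equal(rmse(y, yhat), sqrt(sum((y - yhat)^2) / 30),
               tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("bias and SEP follow the bias-corrected convention", {
  y <- c(1, 2, 3)
  r <- bias_se(y, y + 1)
  expect_equal(r$bias, -1)
  expect_equal(r$se, 0)
  expect_equal(bias_se(y, y), list(bias = 0, se = 0))
  set.seed(2)
  y <- rnorm(25); yhat <- y + rnorm(25, 0.3, 0.5)
  e <- y - yhat
  r <- bias_se(y, yhat)
  expect_equal(r$bias, mean(e), tolerance = 1e-12)
  expect_equal(r$se, sqrt(sum((e - mean(e))^2) / 24), tolerance = 1e-12)
})

test_that("error decomposition rmse^2 = bias^2 + se^2 (n-1)/n holds", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    y <- rnorm(n); yhat <- y + rnorm(n, sd = runif(1, 0.1, 2))
    r <- bias_se(y, yhat)
    expect_equal(rmse(y, yhat)^2,
                 r$bias^2 + r$se^2 * (n - 1) / n, tolerance = 1e-10)
  }
})

test_that("improvement percent reproduces the published comparison", {
  expect_equal(improvement(1, 1), 0)
  expect_equal(improvement(0, 2), 100)
  # printed corn-moisture RMSEPs give 87.36% by direct evaluation
  expect_equal(improvement(0.21095, 1.6689), 87.36, tolerance = 0.005)
  expect_error(improvement(1, 0), "positive")
})

test_that("pearson correlation test matches the textbook formula", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_test(a, 2 * a + 1)$r, 1, tolerance = 1e-12)
  expect_lt(pearson_test(a, 2 * a + 1)$p, 1e-10)
  expect_equal(pearson_test(c(1, 2, 3), c(3, 2, 1))$r, -1,
               tolerance = 1e-12)
  set.seed(4)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(18 / (1 - r^2))
  p <- 2 * pt(-abs(tstat), 18)
  got <- pearson_test(x, y)
  expect_equal(got$r, r, tolerance = 1e-10)
  expect_equal(got$p, p, tolerance = 1e-10)
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
})

test_that("one-sample t reproduces standard critical values", {
  expect_equal(one_sample_t(rnorm(16), alpha = 0.05)$critical, 2.131,
               tolerance = 5e-4)
  expect_equal(one_sample_t(rnorm(50), alpha = 0.05)$critical, 2.01,
               tolerance = 5e-3)
  d <- c(0.5, 1.5, 1, 1)
  got <- one_sample_t(d, 0)
  expect_equal(got$t, mean(d) / sd(d) * sqrt(4), tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(got$t), 3), tolerance = 1e-12)
  expect_error(one_sample_t(rep(0, 6), 0), "variance")
})

test_that("wilcoxon exact mode equals full sign-flip enumeration", {
  # smallest attainable two-sided p at n = 5, all one sign
  got <- wilcoxon_signed_rank(6:10, 1:5, mode = "exact")
  expect_equal(got$p, 0.0625)
  expect_equal(got$stat, 15)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- wilcoxon_signed_rank(a, b, mode = "exact")
    oracle <- wilcoxon_enumerate(a, b)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
    expect_equal(got$stat, oracle$stat)
  }
})

test_that("wilcoxon normal mode uses the tie-corrected variance", {
  # n = 16, all differences one sign, distinct magnitudes
  a <- (1:16) + (1:16) / 10; b <- 1:16
  got <- wilcoxon_signed_rank(a, b, mode = "normal")
  mu <- 16 * 17 / 4
  sigma <- sqrt(16 * 17 * 33 / 24)
  z <- (got$stat - mu) / sigma
  expect_equal(round(z, 3), 3.516)
  expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_lt(abs(got$p - 4.4e-4), 5e-5)
  expect_error(wilcoxon_signed_rank(1:4, 1:4 + 0.1), ">= 5")
  expect_error(wilcoxon_signed_rank(1:5, 1:5), ">= 5")
})

test_that("auto mode switches on ties and size", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(wilcoxon_signed_rank(a, b, mode = "auto")$mode, "normal")
  expect_equal(wilcoxon_signed_rank(a[1:10], b[1:10], "auto")$mode,
               "exact")
  tied <- c(1, 1, 2, 2, 3, 3)
  expect_equal(wilcoxon_signed_rank(tied + 0, rev(tied) * 2,
                                    mode = "auto")$mode, "normal")
})

test_that("evaluate_transfer composes the individual statistics", {
  set.seed(8)
  y <- runif(20, 8, 12)
  pred <- list(ctai = y + rnorm(20, 0, 0.1),
               sbc = y + rnorm(20, 0.3, 0.4))
  rep_ <- evaluate_transfer(y, pred, reference_method = "ctai")
  expect_s3_class(rep_, "transfer_eval")
  expect_equal(nrow(rep_), 2L)
  i <- which(rep_$method == "sbc")
  expect_equal(rep_$rmsep[i], rmse(y, pred$sbc), tolerance = 1e-12)
  bs <- bias_se(y, pred$sbc)
  expect_equal(rep_$bias[i], bs$bias, tolerance = 1e-12)
  expect_equal(rep_$se[i], bs$se, tolerance = 1e-12)
  expect_equal(rep_$r[i], pearson_test(y, pred$sbc)$r, tolerance = 1e-12)
  expect_equal(rep_$h[i],
               improvement(rmse(y, pred$ctai), rmse(y, pred$sbc)),
               tolerance = 1e-12)
  wx <- wilcoxon_signed_rank(abs(y - pred$ctai), abs(y - pred$sbc))
  expect_equal(rep_$wilcoxon_p[i], wx$p, tolerance = 1e-12)
  expect_true(is.na(rep_$h[rep_$method == "ctai"]))
  # perfect predictions give zero rmse and bias
  perfect <- evaluate_transfer(y, list(m = y))
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$bias, 0)
  # identical methods: wilcoxon degenerate is flagged as NA, h = 0
  two <- evaluate_transfer(y, list(a = pred$ctai, b = pred$ctai))
  expect_true(is.na(two$wilcoxon_p[2]))
  expect_equal(two$h[2], 0)
  expect_error(evaluate_transfer(y, pred, "nope"), "not among")
})
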