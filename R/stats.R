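#' Root-mean-square error
#'
#' @param y measured values.
#' @param yhat predicted values, same length.
#' @return `sqrt(mean((y - yhat)^2))`. Conventionally reported as RMSEC on
#'   the calibration set, RMSECV under cross-validation and RMSEP on a test
#'   set.
#' @export
rmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 1)
    stop("y and yhat must have equal length >= 1", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Bias and standard error of prediction
#'
#' `bias` is the mean signed error `mean(y - yhat)`; `se` is the
#' bias-corrected standard error of prediction,
#' `sqrt(sum((e - mean(e))^2) / (n - 1))` with `e = y - yhat`. Under this
#' convention `rmse^2 = bias^2 + se^2 * (n - 1) / n`.
#'
#' @param y measured values.
#' @param yhat predicted values, same length (>= 2).
#' @return List with `bias` and `se` (both in property units).
#' @export
bias_se <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 2)
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  e <- y - yhat
  list(bias = mean(e), se = sqrt(sum((e - mean(e))^2) / (length(e) - 1)))
}

#' Rate of improvement between two prediction errors
#'
#' `h = (1 - rmsep / rmsep_other) * 100`: the percent reduction in RMSEP of
#' one method relative to another. Positive values favour the first method.
#'
#' @param rmsep RMSEP of the method of interest.
#' @param rmsep_other RMSEP of the comparator (must be positive).
#' @return Improvement in percent (at most 100).
#' @examples
#' improvement(0.21095, 1.6689)
#' @export
improvement <- function(rmsep, rmsep_other) {
  if (!is.finite(rmsep_other) || rmsep_other <= 0)
    stop("rmsep_other must be positive", call. = FALSE)
  if (rmsep < 0) stop("rmsep must be non-negative", call. = FALSE)
  (1 - rmsep / rmsep_other) * 100
}

#' Pearson correlation and its significance test
#'
#' Sample Pearson correlation with the two-sided t test
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, used
#' to check for a linear relation between the two instruments' prediction
#' series.
#'
#' @param a,b paired numeric vectors, length >= 3, neither constant.
#' @return List with `r` and `p`.
#' @export
pearson_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' One-sample t test with its critical value
#'
#' Tests whether the mean of `d` differs from `mu0`; used to decide whether
#' a systematic bias adjustment of slave predictions is warranted. Reports
#' the two-sided critical value at level `alpha` alongside the statistic,
#' for direct comparison.
#'
#' @param d numeric vector, length >= 2, non-constant.
#' @param mu0 hypothesized mean (default 0).
#' @param alpha two-sided significance level for the critical value.
#' @return List with `t`, `p`, `critical` (`qt(1 - alpha/2, n - 1)`) and
#'   `df`.
#' @export
one_sample_t <- function(d, mu0 = 0, alpha = 0.05) {
  d <- as.numeric(d)
  if (length(d) < 2) stop("need length >= 2", call. = FALSE)
  if (stats::sd(d) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(d, mu = mu0, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       critical = stats::qt(1 - alpha / 2, df = length(d) - 1),
       df = length(d) - 1L)
}

#' Wilcoxon signed rank test for paired series
#'
#' Two-sided paired test of whether `a` and `b` differ systematically,
#' typically applied to the absolute prediction residuals of two transfer
#' methods. Zero differences are dropped. In `"exact"` mode (default for
#' n <= 25 with no tied ranks under `"auto"`) the p-value is computed from
#' the exact null distribution of the signed rank sum; otherwise a normal
#' approximation with tie-corrected variance and no continuity correction
#' is used.
#'
#' @param a,b paired numeric vectors; at least 5 nonzero differences.
#' @param mode `"exact"`, `"normal"` or `"auto"`.
#' @return List with `stat` (V, the positive-rank sum), `p`, `n` (nonzero
#'   differences) and `mode` (the mode actually used).
#' @export
wilcoxon_signed_rank <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need >= 5 nonzero differences", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  use <- if (mode == "auto") {
    if (n <= 25 && !ties) "exact" else "normal"
  } else mode
  if (use == "exact") {
    if (n > 30)
      stop("exact mode limited to n <= 30; use mode = 'normal'",
           call. = FALSE)
    # exact null distribution of V by convolution over the 2^n equally
    # likely sign assignments; doubling the ranks keeps tied (half-integer)
    # midranks on an integer grid
    r2 <- as.integer(round(2 * r))
    pmf <- numeric(sum(r2) + 1L) # index i holds P(2V = i - 1)
    pmf[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), pmf[seq_len(length(pmf) - rk)])
      pmf <- (pmf + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_lo <- sum(pmf[seq_len(v2 + 1L)])
    p_hi <- sum(pmf[(v2 + 1L):length(pmf)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r[duplicated(r) | duplicated(r, fromLast = TRUE)])
    tie_sizes <- as.numeric(tie_tab)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(stat = V, p = p, n = n, mode = use)
}

#' Evaluate and compare transfer methods on a common test set
#'
#' Computes, for each method's prediction series: RMSEP, bias, SE, the
#' Pearson correlation (and test) against the measured values, a one-sample
#' t test of the signed residuals against zero (with its critical value),
#' the improvement `h` of the reference method over each other method, and
#' a Wilcoxon signed rank test of the paired absolute residuals of the
#' reference method versus each other method.
#'
#' @param y_true measured reference values of the test samples.
#' @param predictions named list of prediction vectors, one per method.
#' @param reference_method name of the method the comparisons are anchored
#'   on (default: the first).
#' @param alpha significance level for the t critical value.
#' @return A `data.frame` of class `"transfer_eval"`, one row per method,
#'   with columns `method`, `rmsep`, `bias`, `se`, `r`, `r_p`, `t`, `t_p`,
#'   `t_critical`, `h` (improvement of the reference over this method, NA
#'   for the reference itself), `wilcoxon_v`, `wilcoxon_p`.
#' @export
evaluate_transfer <- function(y_true, predictions,
                              reference_method = names(predictions)[1],
                              alpha = 0.05) {
  stopifnot(is.list(predictions), length(predictions) >= 1,
            !is.null(names(predictions)))
  if (!reference_method %in% names(predictions))
    stop("reference method '", reference_method,
         "' not among predictions: ",
         paste(names(predictions), collapse = ", "), call. = FALSE)
  y_true <- as.numeric(y_true)
  ref_abs <- abs(y_true - as.numeric(predictions[[reference_method]]))
  ref_rmsep <- rmse(y_true, predictions[[reference_method]])
  rows <- lapply(names(predictions), function(nm) {
    yhat <- as.numeric(predictions[[nm]])
    if (length(yhat) != length(y_true))
      stop("prediction length mismatch for method '", nm, "'",
           call. = FALSE)
    bs <- bias_se(y_true, yhat)
    na2 <- list(r = NA_real_, p = NA_real_)
    pr <- tryCatch(pearson_test(y_true, yhat), error = function(e) na2)
    tt <- tryCatch(one_sample_t(y_true - yhat, 0, alpha),
                   error = function(e)
                     list(t = NA_real_, p = NA_real_,
                          critical = stats::qt(1 - alpha / 2,
                                               length(y_true) - 1)))
    is_ref <- nm == reference_method
    wx <- if (is_ref) list(stat = NA_real_, p = NA_real_) else {
      tryCatch(wilcoxon_signed_rank(ref_abs, abs(y_true - yhat)),
               error = function(e) list(stat = NA_real_, p = NA_real_))
    }
    data.frame(method = nm, rmsep = rmse(y_true, yhat), bias = bs$bias,
               se = bs$se, r = pr$r, r_p = pr$p, t = tt$t, t_p = tt$p,
               t_critical = tt$critical,
               h = if (is_ref) NA_real_ else
                 improvement(ref_rmsep, rmse(y_true, yhat)),
               wilcoxon_v = wx$stat, wilcoxon_p = wx$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_method") <- reference_method
  class(out) <- c("transfer_eval", "data.frame")
  out
}

#' @export
print.transfer_eval <- function(x, ...) {
  cat("Transfer evaluation (reference method: ",
      attr(x, "reference_method"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
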