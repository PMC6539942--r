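#' Min-max normalization to the unit interval
#'
#' Rescales a vector linearly onto \[0, 1\] and returns the bounds needed to
#' invert the map. Used to put score vectors and prediction vectors of the
#' two instruments on a common scale before their slopes and intercepts are
#' compared.
#'
#' @param v numeric vector with at least 2 elements.
#' @return A list with `x` (the normalized vector), `min` and `max`.
#' @examples
#' minmax_normalize(c(1, 2, 3))
#' @export
minmax_normalize <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2) stop("need at least 2 elements", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12)
    stop("degenerate range: max - min < 1e-12", call. = FALSE)
  list(x = (v - lo) / (hi - lo), min = lo, max = hi)
}

#' Per-component score/prediction regression
#'
#' Ordinary least squares of normalized predictions on a normalized score
#' vector plus an intercept. The slope is reported both directly and as the
#' angle `theta = atan(slope)` of the regression line, the quantity the
#' affine correction rotates.
#'
#' @param t_norm normalized score vector.
#' @param y_norm normalized prediction vector, same length.
#' @return List with `slope`, `intercept`, `theta` (radians in
#'   (-pi/2, pi/2)).
#' @export
fit_component_regression <- function(t_norm, y_norm) {
  t_norm <- as.numeric(t_norm); y_norm <- as.numeric(y_norm)
  if (length(t_norm) != length(y_norm) || length(t_norm) < 2)
    stop("t_norm and y_norm must have equal length >= 2", call. = FALSE)
  vt <- sum((t_norm - mean(t_norm))^2)
  if (vt < 1e-24)
    stop("degenerate predictor: score vector is constant", call. = FALSE)
  slope <- sum((t_norm - mean(t_norm)) * (y_norm - mean(y_norm))) / vt
  intercept <- mean(y_norm) - slope * mean(t_norm)
  list(slope = slope, intercept = intercept, theta = atan(slope))
}

# Normalize the scores and predictions of one instrument and fit the
# per-component regressions. Returns a list of A records, one per latent
# variable, each holding the regression and the normalization bounds.
.ctai_instrument_regs <- function(Tmat, yhat, label) {
  yn <- tryCatch(minmax_normalize(yhat), error = function(e)
    stop("degenerate prediction range on the ", label, " instrument: ",
         conditionMessage(e), call. = FALSE))
  lapply(seq_len(ncol(Tmat)), function(i) {
    tn <- tryCatch(minmax_normalize(Tmat[, i]), error = function(e)
      stop("degenerate score range on the ", label,
           " instrument, component ", i, ": ", conditionMessage(e),
           call. = FALSE))
    reg <- fit_component_regression(tn$x, yn$x)
    c(reg, list(t_min = tn$min, t_max = tn$max,
                y_min = yn$min, y_max = yn$max))
  })
}

#' Calibration transfer by affine invariance (CTAI)
#'
#' Fits a transfer model that lets a PLS1 calibration built on a *master*
#' spectrometer predict from spectra measured on a *slave* spectrometer,
#' without any transfer standards: the slave calibration samples need no
#' reference values and need not correspond row-wise to the master's.
#'
#' The method rests on an affine-invariance assumption: for each latent
#' variable, the linear relation between (min-max normalized) scores and
#' predictions differs between the two instruments only by a rotation and a
#' translation. Fitting proceeds by (1) building the master PLS1 model,
#' (2) pushing both instruments' calibration spectra through it to obtain
#' scores and (pseudo-)predictions, (3) normalizing each score column and
#' each prediction vector to \[0, 1\] per instrument, (4) regressing
#' normalized predictions on normalized scores per component on each
#' instrument, and (5) recording the per-component angle differences
#' `delta_theta[i]` and intercept differences `delta_b[i]` between the two
#' regression lines. Prediction applies the inverse rotation/translation in
#' normalized coordinates (see [predict.ctai()]).
#'
#' @param master_x master calibration spectra: n_m x p matrix or
#'   [spectra_set()] (whose reference supplies `master_y`).
#' @param master_y reference values for the master calibration samples.
#' @param slave_x slave calibration spectra: n_s x p matrix or
#'   [spectra_set()]; reference values are not used.
#' @param ncomp number of latent variables, or `"auto"` to choose by
#'   cross-validated RMSECV over `a_range` (see [select_lv()]).
#' @param denorm_reference which instrument's calibration prediction bounds
#'   rescale the corrected normalized predictions back to property units:
#'   `"master"` (default) or `"slave"`. With `"master"`, a pure additive
#'   offset between the instruments' predictions is removed exactly.
#' @param a_range,folds,seed passed to [select_lv()] when `ncomp = "auto"`.
#'
#' @return An object of class `"ctai"`: list with `master` (the [pls1()]
#'   fit), `master_regs` and `slave_regs` (per-component regression records
#'   with normalization bounds), `delta_theta`, `delta_b`, `ncomp`,
#'   `denorm_reference`.
#' @examples
#' sc <- generate_scenario(scenario_config(seed = 7))
#' m <- ctai(sc$master_cal, slave_x = sc$slave_cal, ncomp = 3)
#' m
#' @export
ctai <- function(master_x, master_y = NULL, slave_x, ncomp = "auto",
                 denorm_reference = c("master", "slave"),
                 a_range = 1:15, folds = 10, seed = 1) {
  denorm_reference <- match.arg(denorm_reference)
  if (inherits(master_x, "spectra_set")) {
    if (is.null(master_y)) master_y <- master_x$reference
    master_x <- master_x$spectra
  }
  if (inherits(slave_x, "spectra_set")) slave_x <- slave_x$spectra
  master_x <- as.matrix(master_x); slave_x <- as.matrix(slave_x)
  if (ncol(master_x) != ncol(slave_x))
    stop("master and slave spectra must share the channel count (",
         ncol(master_x), " vs ", ncol(slave_x), ")", call. = FALSE)
  if (identical(ncomp, "auto")) {
    a_range <- a_range[a_range <= min(nrow(master_x) -
                                        ceiling(nrow(master_x) / folds) - 1L,
                                      ncol(master_x))]
    sel <- select_lv(master_x, master_y, a_range = a_range, folds = folds,
                     seed = seed)
    ncomp <- sel$ncomp
  } else sel <- NULL

  master <- pls1(master_x, master_y, ncomp = ncomp)
  Tm <- scores(master, master_x)
  yhat_m <- predict(master, master_x)
  Ts <- scores(master, slave_x)
  yhat_s <- predict(master, slave_x)

  master_regs <- .ctai_instrument_regs(Tm, yhat_m, "master")
  slave_regs <- .ctai_instrument_regs(Ts, yhat_s, "slave")

  delta_theta <- vapply(seq_len(ncomp), function(i)
    master_regs[[i]]$theta - slave_regs[[i]]$theta, numeric(1))
  delta_b <- vapply(seq_len(ncomp), function(i)
    master_regs[[i]]$intercept - slave_regs[[i]]$intercept, numeric(1))
  near_vertical <- abs(cos(delta_theta)) < 1e-9
  if (any(near_vertical))
    warning("near-vertical rotation (|cos delta_theta| < 1e-9) for ",
            "component(s) ", paste(which(near_vertical), collapse = ", "),
            call. = FALSE)

  structure(list(master = master, master_regs = master_regs,
                 slave_regs = slave_regs, delta_theta = delta_theta,
                 delta_b = delta_b, ncomp = ncomp,
                 denorm_reference = denorm_reference,
                 lv_selection = sel, call = match.call()),
            class = "ctai")
}

#' Predict from a CTAI transfer model
#'
#' Corrects slave-instrument spectra through the fitted affine map. For each
#' latent variable `i`: the test pseudo-score and pseudo-prediction are
#' computed with the master model; both are normalized with the *slave
#' calibration* bounds (so single-sample prediction is well defined); the
#' point is rotated and translated in normalized coordinates,
#' \deqn{y' = t_n \sin\Delta\theta_i + (y_n - \tilde b_i^s)\cos\Delta\theta_i
#'   + b_i^m,}
#' and `y'` is mapped back to property units with the calibration prediction
#' bounds of the instrument chosen at fit time (`denorm_reference`). The
#' final prediction is the mean of the per-component corrected predictions.
#'
#' @param object a fitted [ctai()] model.
#' @param newdata slave spectra to predict from: k x p matrix or
#'   [spectra_set()].
#' @param components if `TRUE`, return the k x A matrix of per-component
#'   corrected predictions instead of its row mean.
#' @param ... unused.
#' @return Numeric vector of k corrected predictions (property units), or
#'   the per-component matrix if `components = TRUE`.
#' @export
predict.ctai <- function(object, newdata, components = FALSE, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$spectra
  newdata <- as.matrix(newdata)
  Tt <- scores(object$master, newdata)
  yt <- predict(object$master, newdata)
  A <- object$ncomp
  per_comp <- matrix(0, nrow(newdata), A)
  for (i in seq_len(A)) {
    sr <- object$slave_regs[[i]]
    mr <- object$master_regs[[i]]
    t_n <- (Tt[, i] - sr$t_min) / (sr$t_max - sr$t_min)
    y_n <- (yt - sr$y_min) / (sr$y_max - sr$y_min)
    y_corr <- t_n * sin(object$delta_theta[i]) +
      (y_n - sr$intercept) * cos(object$delta_theta[i]) + mr$intercept
    ref <- if (object$denorm_reference == "master") mr else sr
    per_comp[, i] <- y_corr * (ref$y_max - ref$y_min) + ref$y_min
  }
  if (components) per_comp else rowMeans(per_comp)
}

#' @export
print.ctai <- function(x, ...) {
  cat(sprintf("CTAI transfer model: %d latent variables, %d channels\n",
              x$ncomp, length(x$master$beta)))
  cat(sprintf("  master RMSEC: %.6g\n", x$master$rmsec))
  cat(sprintf("  delta_theta (deg): %s\n",
              paste(formatC(x$delta_theta * 180 / pi, format = "f",
                            digits = 3), collapse = " ")))
  cat(sprintf("  delta_b (norm.):   %s\n",
              paste(formatC(x$delta_b, format = "g", digits = 4),
                    collapse = " ")))
  invisible(x)
}

#' @export
summary.ctai <- function(object, ...) {
  print(object)
  df <- data.frame(
    component = seq_len(object$ncomp),
    theta_master = vapply(object$master_regs, `[[`, numeric(1), "theta"),
    theta_slave = vapply(object$slave_regs, `[[`, numeric(1), "theta"),
    delta_theta = object$delta_theta,
    b_master = vapply(object$master_regs, `[[`, numeric(1), "intercept"),
    b_slave = vapply(object$slave_regs, `[[`, numeric(1), "intercept"),
    delta_b = object$delta_b)
  print(df, row.names = FALSE, digits = 5)
  invisible(df)
}

#' @export
coef.ctai <- function(object, ...) coef(object$master)

#' Equivalent slave-instrument regression coefficients
#'
#' Projects the CTAI-corrected predictions of a slave test batch back onto
#' the slave spectra by least squares, yielding the coefficient vector a
#' direct slave-side linear model would need to reproduce the corrected
#' predictions. A diagnostic view of the transferred model; prediction
#' itself should use [predict.ctai()].
#'
#' The solve uses the singular value decomposition, so a test batch with
#' fewer samples than channels (the common NIR case) yields the
#' minimum-norm solution; rank deficiency is flagged, not masked.
#'
#' @param object a fitted [ctai()] model.
#' @param slave_x_test slave test spectra (k x p matrix or
#'   [spectra_set()]).
#' @param center if `TRUE`, column-center the spectra and predictions
#'   before projecting, removing the intercept from the coefficient view.
#' @return List with `beta` (length-p coefficients), `intercept` (0 when
#'   `center = FALSE`), `residual_norm` (Euclidean norm of the projection
#'   residual) and `rank_deficient` (logical).
#' @export
slave_coefficients <- function(object, slave_x_test, center = FALSE) {
  stopifnot(inherits(object, "ctai"))
  if (inherits(slave_x_test, "spectra_set"))
    slave_x_test <- slave_x_test$spectra
  X <- as.matrix(slave_x_test)
  yhat <- predict(object, X)
  intercept <- 0
  if (center) {
    xm <- colMeans(X); ym <- mean(yhat)
    X <- sweep(X, 2L, xm)
    yhat <- yhat - ym
  }
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  beta <- drop(sv$v[, keep, drop = FALSE] %*%
                 ((crossprod(sv$u[, keep, drop = FALSE], yhat)) /
                    sv$d[keep]))
  if (center) intercept <- ym - sum(xm * beta)
  res <- yhat - drop(X %*% beta)
  list(beta = beta, intercept = intercept,
       residual_norm = sqrt(sum(res^2)),
       rank_deficient = sum(keep) < min(dim(X)))
}
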