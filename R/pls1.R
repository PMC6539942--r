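#' Fit a univariate partial least squares (PLS1) regression model
#'
#' Bespoke PLS1 with the classical NIPALS-style deflation scheme. `X` and `y`
#' are mean-centered; for each component the weight vector is the (unit-norm)
#' direction maximizing covariance between `Xw` and `y` — equivalently the
#' dominant eigenvector of \eqn{X^T y y^T X}, i.e. \eqn{w = X^T y / \|X^T y\|}
#' — then `X` is deflated by the rank-one score/loading product. `y` is not
#' deflated. The regression coefficient vector is reconstructed as
#' \eqn{\beta = W (P^T W)^{-1} q^T}, so predictions are
#' \eqn{\hat y = (X - \bar x)\beta + \bar y}.
#'
#' The sign of each weight vector is fixed so its largest-magnitude element
#' is positive, which makes serialized models reproducible; signs have no
#' effect on predictions.
#'
#' @param X numeric matrix, n samples x p channels (or a [spectra_set()],
#'   in which case `y` defaults to its reference values).
#' @param y numeric response vector of length n.
#' @param ncomp number of latent variables A, `1 <= A <= min(n - 1, p)`.
#' @param keep_residuals if `TRUE`, store the training residual matrices
#'   `E` (spectral) and `F` (response) on the fitted object.
#'
#' @return An object of class `"pls1"`: a list with elements `x_mean`,
#'   `y_mean`, `W` (p x A weights, unit-norm columns), `P` (p x A loadings),
#'   `q` (length-A y-loadings), `beta` (length-p coefficients), `ncomp`,
#'   `rmsec`, `fitted.values`, `residuals`, and optionally `E`, `F`.
#' @seealso [predict.pls1()], [scores()], [select_lv()]
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' y <- X %*% c(1, -2, 0, 0.5, 0) + rnorm(20, sd = 0.01)
#' m <- pls1(X, y, ncomp = 3)
#' m
#' @export
pls1 <- function(X, y = NULL, ncomp, keep_residuals = FALSE) {
  if (inherits(X, "spectra_set")) {
    if (is.null(y)) y <- X$reference
    X <- X$spectra
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    stop("y has length ", length(y), " but X has ", n, " rows",
         call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in [1, min(n-1, p)] = [1, ", min(n - 1L, p), "]",
         call. = FALSE)
  if (stats::sd(y) == 0)
    stop("y is constant; PLS1 is undefined", call. = FALSE)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tmat <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- Xc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300)
      stop("residual covariance vanished at component ", a,
           "; reduce ncomp", call. = FALSE)
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p_a <- drop(crossprod(Xd, t)) / tt
    q[a] <- sum(t * yc) / tt
    Xd <- Xd - tcrossprod(t, p_a)
    W[, a] <- w; P[, a] <- p_a; Tmat[, a] <- t
  }
  R <- W %*% solve(crossprod(P, W)) # p x A projection, T = Xc R
  beta <- drop(R %*% q)
  fitted <- drop(Xc %*% beta) + y_mean
  resid <- y - fitted
  out <- list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
              beta = beta, ncomp = ncomp,
              rmsec = sqrt(mean(resid^2)),
              fitted.values = fitted, residuals = resid,
              call = match.call())
  if (keep_residuals) {
    out$E <- Xd
    out$F <- yc - drop(Tmat %*% q)
  }
  class(out) <- "pls1"
  out
}

#' Predict from a fitted PLS1 model
#'
#' @param object a [pls1()] fit.
#' @param newdata numeric matrix (k x p) or [spectra_set()]; if omitted,
#'   training fitted values are returned.
#' @param ... unused.
#' @return Numeric vector of k predictions,
#'   \eqn{(X - \bar x)\beta + \bar y}.
#' @export
predict.pls1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "spectra_set")) newdata <- newdata$spectra
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$x_mean), call. = FALSE)
  drop(sweep(newdata, 2L, object$x_mean) %*% object$beta) + object$y_mean
}

#' Latent-variable scores
#'
#' Projects spectra onto the latent space of a fitted model:
#' \eqn{T = (X - \bar x) W (P^T W)^{-1}}. On the training data the score
#' columns are mutually orthogonal.
#'
#' @param object a fitted model.
#' @param newdata matrix or [spectra_set()] to project.
#' @param ... passed to methods.
#' @return k x A score matrix.
#' @export
scores <- function(object, newdata, ...) UseMethod("scores")

#' @rdname scores
#' @export
scores.pls1 <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$spectra
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$x_mean), call. = FALSE)
  R <- object$W %*% solve(crossprod(object$P, object$W))
  sweep(newdata, 2L, object$x_mean) %*% R
}

#' @export
coef.pls1 <- function(object, ...) object$beta

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 model: %d latent variables, %d channels\n",
              x$ncomp, length(x$beta)))
  cat(sprintf("  RMSEC: %.6g\n", x$rmsec))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  cat(sprintf("PLS1 model with %d latent variables (%d channels)\n",
              object$ncomp, length(object$beta)))
  cat(sprintf("  RMSEC       %.6g\n", object$rmsec))
  cat(sprintf("  y-loadings  %s\n",
              paste(formatC(object$q, format = "g", digits = 4),
                    collapse = " ")))
  invisible(object)
}

#' Choose the number of latent variables by cross-validation
#'
#' Runs k-fold cross-validation over a candidate range of component counts
#' and picks the one with the lowest RMSECV (root-mean-square error of the
#' pooled held-out predictions). Folds are formed by a seeded random
#' permutation followed by a contiguous split, so results are reproducible.
#' Ties are broken toward the smaller (more parsimonious) count.
#'
#' @param X n x p matrix or [spectra_set()].
#' @param y response vector (defaults to the spectra_set reference).
#' @param a_range candidate component counts; the default search range is
#'   1 to 15.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `"lv_selection"`: list with `ncomp` (chosen
#'   count), `rmsecv` (named vector over candidates), `folds`, `seed`.
#' @export
select_lv <- function(X, y = NULL, a_range = 1:15, folds = 10, seed = 1) {
  if (inherits(X, "spectra_set")) {
    if (is.null(y)) y <- X$reference
    X <- X$spectra
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop("folds must be in [2, n]", call. = FALSE)
  a_range <- sort(unique(as.integer(a_range)))
  sizes <- diff(round(seq(0, n, length.out = folds + 1)))
  min_train <- n - max(sizes)
  if (max(a_range) > min(min_train - 1L, ncol(X)))
    stop("largest candidate ncomp (", max(a_range),
         ") infeasible for fold training size ", min_train, call. = FALSE)
  perm <- withr_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(folds), times = sizes)
  press <- matrix(NA_real_, n, length(a_range))
  for (f in seq_len(folds)) {
    te <- which(fold_of == f)
    tr <- setdiff(seq_len(n), te)
    m_full <- pls1(X[tr, , drop = FALSE], y[tr], ncomp = max(a_range))
    R_cum <- m_full$W %*% solve(crossprod(m_full$P, m_full$W))
    Tc <- sweep(X[te, , drop = FALSE], 2L, m_full$x_mean) %*% R_cum
    for (j in seq_along(a_range)) {
      a <- a_range[j]
      pred <- drop(Tc[, seq_len(a), drop = FALSE] %*%
                     m_full$q[seq_len(a)]) + m_full$y_mean
      press[te, j] <- (y[te] - pred)^2
    }
  }
  rmsecv <- sqrt(colMeans(press))
  names(rmsecv) <- a_range
  chosen <- a_range[which.min(rmsecv)]
  structure(list(ncomp = chosen, rmsecv = rmsecv, folds = folds,
                 seed = seed),
            class = "lv_selection")
}

#' @export
print.lv_selection <- function(x, ...) {
  cat(sprintf("Latent-variable selection: A = %d (%d-fold CV, RMSECV %.6g)\n",
              x$ncomp, x$folds, min(x$rmsecv)))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
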