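#' Slope/bias correction (SBC)
#'
#' The classical standards-based transfer: predictions of a set of standard
#' samples measured on both instruments are related by ordinary least
#' squares, and slave predictions are corrected through the fitted line.
#'
#' @param master_pred_std master-model predictions of the standards measured
#'   on the master instrument.
#' @param slave_pred_std master-model predictions of the same standards
#'   measured on the slave instrument (paired, same order).
#' @return Object of class `"sbc"` with `slope` and `bias`.
#' @export
fit_sbc <- function(master_pred_std, slave_pred_std) {
  m <- as.numeric(master_pred_std); s <- as.numeric(slave_pred_std)
  if (length(m) != length(s) || length(m) < 2)
    stop("need paired predictions of >= 2 standards", call. = FALSE)
  vs <- sum((s - mean(s))^2)
  if (vs < 1e-24)
    stop("degenerate predictor: slave predictions are constant",
         call. = FALSE)
  slope <- sum((s - mean(s)) * (m - mean(m))) / vs
  bias <- mean(m) - slope * mean(s)
  structure(list(slope = slope, bias = bias), class = "sbc")
}

#' @rdname fit_sbc
#' @param m a fitted `"sbc"` model.
#' @param slave_pred slave predictions to correct.
#' @return `apply_sbc`: the corrected predictions `slope * y + bias`.
#' @export
apply_sbc <- function(m, slave_pred) {
  stopifnot(inherits(m, "sbc"))
  m$slope * as.numeric(slave_pred) + m$bias
}

#' Multiplicative scatter correction (MSC) transfer
#'
#' `msc_reference` takes the mean spectrum of a calibration set as the
#' reference; `msc_correct` regresses each spectrum on that reference,
#' `x = a + b * ref + e`, and replaces it by `(x - a) / b`, removing
#' additive and multiplicative scatter relative to the master's calibration
#' space.
#'
#' @param X spectra matrix or [spectra_set()].
#' @return `msc_reference`: object of class `"msc_reference"` holding the
#'   mean spectrum.
#' @export
msc_reference <- function(X) {
  if (inherits(X, "spectra_set")) X <- X$spectra
  structure(list(ref_spectrum = colMeans(as.matrix(X))),
            class = "msc_reference")
}

#' @rdname msc_reference
#' @param ref an `"msc_reference"`.
#' @return `msc_correct`: the corrected spectra matrix.
#' @export
msc_correct <- function(X, ref) {
  stopifnot(inherits(ref, "msc_reference"))
  is_set <- inherits(X, "spectra_set")
  Xm <- if (is_set) X$spectra else as.matrix(X)
  r <- ref$ref_spectrum
  if (ncol(Xm) != length(r))
    stop("channel count mismatch with reference spectrum", call. = FALSE)
  rc <- r - mean(r)
  vr <- sum(rc^2)
  out <- Xm
  for (k in seq_len(nrow(Xm))) {
    x <- Xm[k, ]
    b <- sum(rc * (x - mean(x))) / vr
    if (abs(b) < 1e-12)
      stop("degenerate row ", k, ": zero slope against reference spectrum",
           call. = FALSE)
    a <- mean(x) - b * mean(r)
    out[k, ] <- (x - a) / b
  }
  if (is_set) spectra_set(out, X$wavelengths, X$reference, X$ids) else out
}

#' Piecewise direct standardization (PDS)
#'
#' Builds a banded transfer matrix mapping slave spectra into the master
#' instrument's spectral space: each master channel is regressed (by a PLS1
#' sub-model) on a window of slave channels centered at the same index,
#' using standard samples measured on both instruments. Windows shrink
#' symmetrically at the spectrum edges so the output keeps all p channels.
#'
#' @param master_std,slave_std paired standard spectra (same samples, same
#'   row order) on the two instruments; matrices or [spectra_set()]s.
#' @param window odd window width >= 3 (number of slave channels feeding
#'   each master channel).
#' @param inner_lv latent variables of each windowed PLS1 sub-model; capped
#'   at the window width and at one less than the number of standards.
#' @return Object of class `"pds"` with `transfer_matrix` (p x p, banded:
#'   entries beyond `(window - 1) / 2` off the diagonal are exactly zero),
#'   `intercepts` (length p), `window`, `inner_lv`.
#' @export
fit_pds <- function(master_std, slave_std, window = 5, inner_lv = 2) {
  if (inherits(master_std, "spectra_set")) master_std <- master_std$spectra
  if (inherits(slave_std, "spectra_set")) slave_std <- slave_std$spectra
  M <- as.matrix(master_std); S <- as.matrix(slave_std)
  if (!all(dim(M) == dim(S)))
    stop("master and slave standards must be paired (same dimensions)",
         call. = FALSE)
  p <- ncol(M); n <- nrow(M)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (window > p) stop("window exceeds the channel count", call. = FALSE)
  if (n < 3L) stop("need at least 3 standard samples", call. = FALSE)
  half <- (window - 1L) %/% 2L
  Fmat <- matrix(0, p, p)
  intercepts <- numeric(p)
  for (j in seq_len(p)) {
    win <- max(1L, j - half):min(p, j + half)
    a <- min(inner_lv, length(win), n - 1L)
    sub <- pls1(S[, win, drop = FALSE], M[, j], ncomp = a)
    Fmat[j, win] <- sub$beta
    intercepts[j] <- sub$y_mean - sum(sub$x_mean * sub$beta)
  }
  structure(list(transfer_matrix = Fmat, intercepts = intercepts,
                 window = window, inner_lv = inner_lv), class = "pds")
}

#' @rdname fit_pds
#' @param m a fitted `"pds"` model.
#' @param slave_x slave spectra to map into master space.
#' @return `apply_pds`: matrix (or [spectra_set()], matching the input) of
#'   master-space spectra.
#' @export
apply_pds <- function(m, slave_x) {
  stopifnot(inherits(m, "pds"))
  is_set <- inherits(slave_x, "spectra_set")
  X <- if (is_set) slave_x$spectra else as.matrix(slave_x)
  if (ncol(X) != ncol(m$transfer_matrix))
    stop("channel count mismatch with transfer matrix", call. = FALSE)
  out <- tcrossprod(X, m$transfer_matrix) +
    matrix(m$intercepts, nrow(X), ncol(X), byrow = TRUE)
  if (is_set) spectra_set(out, slave_x$wavelengths, slave_x$reference,
                          slave_x$ids) else out
}

#' Hyperparameter search for the standards-based baselines
#'
#' For PDS, searches the window width over `windows` (default the odd
#' values 3 to 15) by k-fold cross-validation over the standard samples:
#' for each fold the transfer matrix is fitted on the training standards,
#' the held-out slave standards are mapped to master space and predicted
#' with the master model, and the pooled RMSECV against the standards'
#' reference values is minimized. For SBC (and optionally PDS), searches
#' the number of standards over `n_std_candidates` (default 5 to 30),
#' taking the first k samples in Kennard-Stone order and minimizing the
#' RMSE of the corrected standards against their reference values.
#'
#' @param method `"pds"` or `"sbc"`.
#' @param master_model the master [pls1()] fit.
#' @param master_std,slave_std paired candidate standards in Kennard-Stone
#'   order (all candidates; subsets are taken from the top).
#' @param y_std reference values of the standards.
#' @param windows candidate PDS window widths.
#' @param n_std_candidates candidate standard counts; `NULL` fixes the
#'   count at `nrow(master_std)`.
#' @param inner_lv PDS inner latent variables.
#' @param folds,seed cross-validation folds and seed (PDS window search).
#' @return List with the chosen `window` (PDS), `n_std`, and the error
#'   curve(s) used for the choice.
#' @export
select_hyperparams <- function(method = c("pds", "sbc"), master_model,
                               master_std, slave_std, y_std,
                               windows = seq(3, 15, by = 2),
                               n_std_candidates = 5:30,
                               inner_lv = 2, folds = 5, seed = 1) {
  method <- match.arg(method)
  if (inherits(master_std, "spectra_set")) master_std <- master_std$spectra
  if (inherits(slave_std, "spectra_set")) slave_std <- slave_std$spectra
  n <- nrow(master_std); p <- ncol(master_std)
  if (!is.null(n_std_candidates))
    n_std_candidates <- n_std_candidates[n_std_candidates <= n &
                                           n_std_candidates >= 2]
  out <- list(method = method)

  if (method == "pds") {
    feasible <- windows[windows <= p]
    if (length(feasible) < length(windows))
      warning("dropped infeasible window(s) > p = ", p, call. = FALSE)
    if (!length(feasible)) stop("no feasible window", call. = FALSE)
    if (length(feasible) == 1L) {
      out$window <- feasible
      out$window_rmsecv <- stats::setNames(NA_real_, feasible)
      return(out)
    }
    folds <- min(folds, n)
    sizes <- diff(round(seq(0, n, length.out = folds + 1)))
    perm <- withr_seed(seed, sample.int(n))
    fold_of <- integer(n)
    fold_of[perm] <- rep(seq_len(folds), times = sizes)
    rmsecv <- vapply(feasible, function(w) {
      press <- numeric(0)
      for (f in seq_len(folds)) {
        te <- which(fold_of == f); tr <- setdiff(seq_len(n), te)
        if (length(tr) < 3) next
        pm <- fit_pds(master_std[tr, , drop = FALSE],
                      slave_std[tr, , drop = FALSE],
                      window = w, inner_lv = inner_lv)
        pred <- predict(master_model,
                        apply_pds(pm, slave_std[te, , drop = FALSE]))
        press <- c(press, (y_std[te] - pred)^2)
      }
      sqrt(mean(press))
    }, numeric(1))
    out$window_rmsecv <- stats::setNames(rmsecv, feasible)
    out$window <- feasible[which.min(rmsecv)]
  }

  if (!is.null(n_std_candidates) && length(n_std_candidates)) {
    rmse_k <- vapply(n_std_candidates, function(k) {
      idx <- seq_len(k)
      if (method == "sbc") {
        mp <- predict(master_model, master_std[idx, , drop = FALSE])
        sp <- predict(master_model, slave_std[idx, , drop = FALSE])
        sm <- fit_sbc(mp, sp)
        corr <- apply_sbc(sm, sp)
      } else {
        w <- out$window %||% max(windows[windows <= p])
        pm <- fit_pds(master_std[idx, , drop = FALSE],
                      slave_std[idx, , drop = FALSE],
                      window = w, inner_lv = inner_lv)
        corr <- predict(master_model,
                        apply_pds(pm, slave_std[idx, , drop = FALSE]))
      }
      sqrt(mean((y_std[idx] - corr)^2))
    }, numeric(1))
    out$n_std_rmse <- stats::setNames(rmse_k, n_std_candidates)
    out$n_std <- n_std_candidates[which.min(rmse_k)]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
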