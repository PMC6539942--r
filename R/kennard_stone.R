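#' Kennard-Stone calibration/test split
#'
#' Deterministic max-min sample selection on Euclidean distances between
#' spectra: the first two selected samples are the most distant pair; each
#' subsequent sample maximizes its minimum distance to the already-selected
#' set. The result is a representative, space-filling calibration set with
#' the remainder as test set. Distances are taken on the raw absorbance
#' values (no autoscaling), and ties are broken toward the lowest index so
#' the split is bitwise reproducible.
#'
#' @param X n x p matrix or [spectra_set()].
#' @param n_select number of calibration samples, `2 <= n_select <= n`.
#' @return List of class `"ks_split"` with `calibration` (indices in
#'   selection order) and `test` (the complement, ascending).
#' @examples
#' X <- matrix(c(0, 5, 10), ncol = 1)
#' kennard_stone(X, 2)$calibration  # the extreme pair: 1, 3
#' @export
kennard_stone <- function(X, n_select) {
  if (inherits(X, "spectra_set")) X <- X$spectra
  X <- as.matrix(X)
  n <- nrow(X)
  n_select <- as.integer(n_select)
  if (n_select < 2L || n_select > n)
    stop("n_select must be in [2, n] = [2, ", n, "]", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  # seed pair: maximum distance, lowest indices on ties
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- c(best[1, 1], best[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- which.max(mind) # which.max returns the first (lowest) index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(calibration = as.integer(sel),
                 test = setdiff(seq_len(n), sel)),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d calibration, %d test samples\n",
              length(x$calibration), length(x$test)))
  invisible(x)
}
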