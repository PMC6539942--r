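# Independent oracles, coded from first principles and kept free of the
# package's own code paths.

# Greedy max-min Kennard-Stone, written directly from the algorithm
# statement with explicit loops (no shared code with the package).
ks_bruteforce <- function(X, n_select) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- d(i, j)
    if (dij > bestd) { bestd <- dij; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    scores <- vapply(cand, function(i)
      min(vapply(sel, function(j) d(i, j), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(scores)])
  }
  as.integer(sel)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences.
wilcoxon_enumerate <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  list(stat = v_obs, p = p)
}

# Closed-form simple OLS (slope, intercept) of y on x.
ols_line <- function(x, y) {
  s <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = s, intercept = mean(y) - s * mean(x))
}

# Random full-rank regression problem for PLS oracle checks.
random_pls_problem <- function(n = 20, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.1)
  list(X = X, y = y)
}
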