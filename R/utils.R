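# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state.  All exported stochastic functions route their randomness
# through this, so a seed argument fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite number", call. = FALSE)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed and a stream index, staying below
# 2^31 so the result is a valid R integer seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647
}

check_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok)
    stop(sprintf("`%s` must be a single number in %s%g, %g%s", name,
                 if (open) "(" else "[", lo, hi, if (open) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == round(x)
  if (!ok)
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Rows of a Q matrix must lie on the probability simplex.
check_simplex <- function(theta, tol = 1e-6) {
  if (any(!is.finite(theta)) || any(theta < -tol) || any(theta > 1 + tol))
    stop("admixture proportions must lie in [0, 1]", call. = FALSE)
  dev <- abs(rowSums(theta) - 1)
  if (any(dev > tol)) {
    bad <- which(dev > tol)[1L]
    stop(sprintf("admixture row %d sums to %.8f, not 1", bad,
                 rowSums(theta)[bad]), call. = FALSE)
  }
  invisible(theta)
}

# Mean-impute missing dosages column-wise (used for regression / PCA /
# kinship computations only; stored matrices keep their NAs).
impute_mean <- function(X, means = NULL) {
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  means[!is.finite(means)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- means[idx[, 2L]]
  list(X = X, means = means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
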