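# Component-environment correlations and RDA-based variation
# partitioning of admixture proportions into climate / geography /
# shared / residual fractions.

#' Correlations between admixture components and environmental variables
#'
#' Pearson correlation for every (component, variable) pair with
#' two-sided p values; significance is controlled by a Bonferroni
#' correction whose family is every tested pair (`K x n_vars`).
#'
#' @param Q N x K admixture matrix (rownames = sample ids).
#' @param env data.frame with `sample_id` and numeric variables.
#' @param alpha family-wise significance level.
#' @return List of class `env_correlations`: matrices `r`, `p`,
#'   `significant` (logical, at `alpha / family_size`), plus
#'   `family_size` and `threshold`.
#' @export
component_env_correlations <- function(Q, env, alpha = 0.01) {
  Q <- as.matrix(Q)
  ids <- intersect(rownames(Q), env$sample_id)
  if (length(ids) < 3) stop("need >= 3 joined samples", call. = FALSE)
  Qm <- Q[ids, , drop = FALSE]
  vars <- names(env)[vapply(env, is.numeric, logical(1))]
  E <- as.matrix(env[match(ids, env$sample_id), vars, drop = FALSE])
  K <- ncol(Qm); V <- ncol(E)
  rmat <- pmat <- matrix(NA_real_, K, V,
                         dimnames = list(colnames(Qm), vars))
  for (k in seq_len(K)) for (v in seq_len(V)) {
    if (stats::sd(E[, v]) == 0 || stats::sd(Qm[, k]) == 0) {
      warning("zero-variance pair skipped: ", colnames(Qm)[k], " / ", vars[v])
      next
    }
    ct <- stats::cor.test(Qm[, k], E[, v])
    rmat[k, v] <- unname(ct$estimate)
    pmat[k, v] <- ct$p.value
  }
  family <- K * V
  structure(list(r = rmat, p = pmat,
                 significant = !is.na(pmat) & pmat < alpha / family,
                 family_size = family, threshold = alpha / family),
            class = "env_correlations")
}

#' @export
print.env_correlations <- function(x, ...) {
  cat(sprintf("Component-environment correlations: %d pairs, Bonferroni threshold %.3g\n",
              x$family_size, x$threshold))
  cat(sprintf("  significant pairs: %d\n", sum(x$significant, na.rm = TRUE)))
  invisible(x)
}

# fraction of trace(Y'Y) explained by OLS of centered Y on centered X
rda_fraction <- function(Y, X) {
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  H <- X %*% solve(crossprod(X), t(X))
  sum((H %*% Y)^2) / sum(Y^2)
}

residualize <- function(A, Z) {
  A <- scale(as.matrix(A), center = TRUE, scale = FALSE)
  Z <- scale(as.matrix(Z), center = TRUE, scale = FALSE)
  qrZ <- qr(Z)
  A - qr.fitted(qrZ, A)
}

#' Partition admixture variation between climate and geography
#'
#' Redundancy analysis implemented as multivariate least squares: the
#' fraction of total admixture variance explained by a predictor set is
#' `trace(Yhat' Yhat) / trace(Y' Y)` for centered matrices.  The
#' partition reports the climate-only fraction `a` (partial RDA of Y on
#' climate, conditioned on geography), the geography-only fraction `c`
#' (the converse), the shared fraction `b = full - a - c`, and the
#' residual `1 - full`, which sum to one exactly.  Significance of the
#' full model comes from permuting the rows of Y.
#'
#' @param Q N x K admixture matrix (rownames = sample ids).
#' @param climate data.frame or matrix of climate predictors (may carry a
#'   `sample_id` column).
#' @param geography data.frame or matrix of geographic predictors
#'   (latitude, longitude, optionally elevation).
#' @param n_perm permutations for the full-model test.
#' @param seed integer seed.
#' @return List of class `rda_partition`: `fraction_climate_only`,
#'   `fraction_shared`, `fraction_geography_only`, `residual`, `full`,
#'   `permutation_p`.
#' @export
rda_partition <- function(Q, climate, geography, n_perm = 999, seed = 1) {
  Y <- as.matrix(Q)
  strip <- function(d) {
    d <- as.data.frame(d)
    as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  }
  C <- strip(climate); Gg <- strip(geography)
  n <- nrow(Y)
  stopifnot(nrow(C) == n, nrow(Gg) == n)
  if (ncol(C) + ncol(Gg) >= n)
    stop("more predictors than samples", call. = FALSE)
  drop_collinear <- function(X) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    qrX <- qr(Xc)
    if (qrX$rank < ncol(X)) {
      warning("dropping collinear predictor column(s)")
      X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    } else X
  }
  C <- drop_collinear(C); Gg <- drop_collinear(Gg)

  full <- rda_fraction(Y, cbind(C, Gg))
  # partial fractions: residualize response and predictors on the
  # conditioning set, expressed relative to the total variance of Y
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  tot <- sum(Yc^2)
  part <- function(X, Z) {
    Yr <- residualize(Y, Z); Xr <- residualize(X, Z)
    qrX <- qr(Xr)
    sum(qr.fitted(qrX, Yr)^2) / tot
  }
  a <- part(C, Gg)
  c_ <- part(Gg, C)
  b <- full - a - c_
  p <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      if (rda_fraction(Y[sample.int(n), , drop = FALSE], cbind(C, Gg)) >= full)
        count <- count + 1L
    }
    (1 + count) / (n_perm + 1)
  })
  structure(list(fraction_climate_only = a, fraction_shared = b,
                 fraction_geography_only = c_, residual = 1 - full,
                 full = full, permutation_p = p),
            class = "rda_partition")
}

#' @export
print.rda_partition <- function(x, ...) {
  cat("Variation partitioning of admixture proportions\n")
  cat(sprintf("  climate only:   %6.1f%%\n", 100 * x$fraction_climate_only))
  cat(sprintf("  shared:         %6.1f%%\n", 100 * x$fraction_shared))
  cat(sprintf("  geography only: %6.1f%%\n", 100 * x$fraction_geography_only))
  cat(sprintf("  residual:       %6.1f%%\n", 100 * x$residual))
  cat(sprintf("  full model r2 = %.3f (permutation p = %.3g)\n",
              x$full, x$permutation_p))
  invisible(x)
}
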