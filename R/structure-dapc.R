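# DAPC-style arm of K determination: PCA reduction, k-means/BIC scan,
# linear discriminant analysis, and Q-based hierarchical assignment.

#' Principal-component scores of a genotype matrix
#'
#' Dosages are mean-imputed and column-centered, then decomposed by SVD.
#' Signs are fixed by making the largest-magnitude loading of each
#' component positive, so scores are fully deterministic.
#'
#' @param G a [genotype_matrix()].
#' @param n_components components to keep (truncated to the matrix rank,
#'   with a warning).
#' @return An object of class `pca_scores`: list with `scores` (N x P),
#'   `loadings`, `explained` (variance fractions, non-increasing).
#' @export
pca_scores <- function(G, n_components = 80) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_components <- check_count(n_components, "n_components")
  X <- impute_mean(G$dosage)$X
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  rank <- sum(pos)
  if (n_components > rank) {
    warning(sprintf("n_components reduced from %d to rank %d",
                    n_components, rank))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  V <- sv$v[, keep, drop = FALSE]
  flip <- vapply(keep, function(j) {
    sign(V[which.max(abs(V[, j])), j])
  }, numeric(1))
  V <- sweep(V, 2L, flip, "*")
  scores <- Xc %*% V
  rownames(scores) <- rownames(G$dosage)
  colnames(scores) <- sprintf("PC%d", keep)
  structure(list(scores = scores, loadings = V,
                 explained = sv$d[keep]^2 / sum(sv$d[pos]^2)),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf("PCA scores: %d samples x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained)))
  invisible(x)
}

# k-means++ initial centers
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < K) {
    d2 <- apply(X, 1L, function(r) min(colSums((t(centers) - r)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, X[sample.int(n, 1L), , drop = FALSE])
    } else {
      centers <- rbind(centers, X[sample.int(n, 1L, prob = d2), , drop = FALSE])
    }
  }
  centers
}

#' BIC scan over the number of k-means clusters
#'
#' For each K the best of `n_starts` seeded k-means++ runs (lowest
#' within-cluster sum of squares, WSS) is kept and scored with
#' `BIC(K) = N log(WSS / N) + K log(N)`.  The argmin locates the number of
#' groups supported by the reduced genotype space.
#'
#' @param scores a [pca_scores()] object (or a plain score matrix).
#' @param K_range candidate cluster counts; capped at N - 1 (with a
#'   warning) since WSS = 0 at K = N makes the criterion degenerate.
#' @param n_starts k-means restarts per K.
#' @param seed integer seed.
#' @return Object of class `bic_curve`: data.frame `K`, `BIC`, with
#'   cluster `assignments` (list) and `best_K` as attributes.
#' @export
bic_scan <- function(scores, K_range, n_starts = 10, seed = 1) {
  X <- if (inherits(scores, "pca_scores")) scores$scores else as.matrix(scores)
  N <- nrow(X)
  if (any(K_range >= N)) {
    warning("K_range capped at N - 1")
    K_range <- K_range[K_range < N]
  }
  if (!length(K_range)) stop("empty K_range after capping", call. = FALSE)
  res <- with_seed(seed, lapply(K_range, function(K) {
    best <- NULL
    for (s in seq_len(n_starts)) {
      km <- tryCatch({
        cen <- kmeanspp_centers(X, K)
        stats::kmeans(X, centers = cen, iter.max = 100)
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best))                     # all starts degenerate
      best <- stats::kmeans(X, centers = K, iter.max = 100, nstart = 1)
    best
  }))
  wss <- vapply(res, function(km) km$tot.withinss, numeric(1))
  bic <- N * log(pmax(wss, .Machine$double.eps) / N) + K_range * log(N)
  out <- data.frame(K = K_range, WSS = wss, BIC = bic)
  attr(out, "assignments") <- lapply(res, function(km) km$cluster)
  attr(out, "best_K") <- K_range[which.min(bic)]
  class(out) <- c("bic_curve", "data.frame")
  out
}

#' Discriminant analysis of principal components
#'
#' Classic pooled-covariance linear discriminant analysis on retained
#' principal components: finds up to `n_groups - 1` axes maximizing the
#' between- over within-group variance ratio and returns Gaussian
#' posterior group memberships.  The number of PCs used is truncated to
#' `N - n_groups` to keep the within-group covariance well conditioned.
#'
#' @param scores a [pca_scores()] object or score matrix.
#' @param groups group labels, one per sample (>= 2 groups, each with
#'   >= 2 members).
#' @return List of class `dapc_fit`: `axes` (discriminant loadings on the
#'   PCs), `ld_scores`, `posterior`, `assigned`, `groups`.
#' @export
dapc_fit <- function(scores, groups) {
  X <- if (inherits(scores, "pca_scores")) scores$scores else as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 members",
                                   call. = FALSE)
  pmax_use <- max(1L, nrow(X) - nlevels(groups))
  if (ncol(X) > pmax_use) X <- X[, seq_len(pmax_use), drop = FALSE]
  fit <- tryCatch(MASS::lda(X, grouping = groups),
                  error = function(e) {
                    warning("singular within-group covariance; ridge-regularizing")
                    Xr <- X + matrix(stats::rnorm(length(X), 0,
                                                  sqrt(mean(diag(stats::var(X))) * 1e-8)),
                                     nrow(X))
                    MASS::lda(Xr, grouping = groups)
                  })
  pr <- stats::predict(fit, X)
  structure(list(axes = fit$scaling, ld_scores = pr$x,
                 posterior = pr$posterior, assigned = pr$class,
                 groups = groups, lda = fit),
            class = "dapc_fit")
}

#' Assign samples to populations by clustering admixture vectors
#'
#' Agglomerative clustering (average linkage / UPGMA on Euclidean
#' distances between Q-matrix rows) cut at `K_groups` clusters.  Labels
#' are `P1, P2, ...` ordered by decreasing cluster size.
#'
#' @param Q N x K admixture matrix.
#' @param K_groups number of populations to cut.
#' @return Named character vector of population labels.
#' @export
cluster_by_admixture <- function(Q, K_groups) {
  Q <- as.matrix(Q)
  K_groups <- check_count(K_groups, "K_groups")
  if (K_groups > nrow(Q)) stop("K_groups exceeds the number of samples",
                               call. = FALSE)
  hc <- stats::hclust(stats::dist(Q), method = "average")
  cl <- stats::cutree(hc, k = K_groups)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(sprintf("P%d", seq_along(sizes)), names(sizes))
  out <- relabel[as.character(cl)]
  names(out) <- rownames(Q) %||% sprintf("S%03d", seq_len(nrow(Q)))
  out
}
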