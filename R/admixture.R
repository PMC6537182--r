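# Admixture estimation under the standard binomial likelihood
#   L(Q, F) = sum_ij [ g_ij log(p_ij) + (2 - g_ij) log(1 - p_ij) ],
#   p_ij = sum_k q_ik f_kj,
# maximized with plain multiplicative EM updates (monotone by construction).
# Missing dosages simply drop out of the likelihood.

FREQ_CLIP <- 1e-6

admix_loglik <- function(Q, F, Gz, W) {
  P <- Q %*% F
  P <- pmin(pmax(P, FREQ_CLIP), 1 - FREQ_CLIP)
  sum(W * (Gz * log(P) + (2 - Gz) * log1p(-P)))
}

# EM main loop; updates Q (always) and F (unless fixed) from the same
# responsibilities, which is the classical frequency/ancestry EM.  The
# mixture dosage probabilities P are computed once per iteration and
# shared between the likelihood evaluation and the M-step.
admix_em_run <- function(Q, F, Gz, W, update_F, tol, max_iter) {
  G2 <- W * (2 - Gz)
  Gw <- W * Gz
  denomQ <- 2 * rowSums(W)
  tF <- t(F); tF1 <- 1 - tF
  trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(max_iter + 1L)) {
    P <- Q %*% F
    P[P < FREQ_CLIP] <- FREQ_CLIP
    P[P > 1 - FREQ_CLIP] <- 1 - FREQ_CLIP
    ll_new <- sum(Gw * log(P)) + sum(G2 * log1p(-P))
    if (!is.finite(ll_new)) stop("non-finite likelihood in EM", call. = FALSE)
    if (ll_new < ll - max(1e-8, abs(ll) * 1e-10))
      stop("EM log-likelihood decreased; this indicates a bug", call. = FALSE)
    trace <- c(trace, ll_new)
    done <- (ll_new - ll < tol) || it > max_iter
    ll <- ll_new
    if (done) break
    A <- Gw / P
    B <- G2 / (1 - P)
    Qn <- Q * (A %*% tF + B %*% tF1) / denomQ
    if (update_F) {
      n1 <- F * crossprod(Q, A)
      n0 <- (1 - F) * crossprod(Q, B)
      F <- n1 / (n1 + n0)
      F[!is.finite(F)] <- 0.5
      F[F < FREQ_CLIP] <- FREQ_CLIP
      F[F > 1 - FREQ_CLIP] <- 1 - FREQ_CLIP
      tF <- t(F); tF1 <- 1 - tF
    }
    Q <- Qn / rowSums(Qn)
  }
  list(Q = Q, F = F, loglik = ll, trace = trace,
       converged = length(trace) <= max_iter)
}

normalize_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    out <- stats::setNames(as.character(labels[[2L]]),
                           as.character(labels[[1L]]))
  } else out <- stats::setNames(as.character(labels),
                                names(labels) %||% sample_ids)
  out[names(out) %in% sample_ids]
}

#' Estimate admixture proportions in supervised mode
#'
#' Ancestral allele frequencies are estimated from labelled samples as
#' per-class observed frequencies (with a 0.5 pseudo-count per class and
#' locus); every sample's admixture vector is then the maximizer of the
#' binomial log-likelihood over the simplex, found by multiplicative EM
#' updates with the frequencies held fixed.
#'
#' @param G a [genotype_matrix()].
#' @param labels population labels for a subset of samples: either a named
#'   character vector (names = sample ids) or a two-column data.frame
#'   (sample_id, population).
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter maximum EM iterations.
#'
#' @return An object of class `admixture_fit`: list with `Q` (N x K, rows
#'   on the simplex, columns named by label class), `F` (K x M ancestral
#'   frequencies), `loglik`, `loglik_trace`, `mode`.
#' @export
estimate_q_supervised <- function(G, labels, tol = 1e-7, max_iter = 2000) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosage
  labels <- normalize_labels(labels, rownames(X))
  if (!length(labels)) stop("no labelled samples found in G", call. = FALSE)
  classes <- sort(unique(labels))
  K <- length(classes)
  if (any(rowSums(!is.na(X)) == 0))
    stop("sample with all genotypes missing: ",
         rownames(X)[which(rowSums(!is.na(X)) == 0)[1L]], call. = FALSE)

  # per-class frequencies with +-0.5 pseudo-count
  F <- t(vapply(classes, function(cl) {
    Xi <- X[rownames(X) %in% names(labels)[labels == cl], , drop = FALSE]
    alt <- colSums(Xi, na.rm = TRUE)
    n2 <- 2 * colSums(!is.na(Xi))
    (alt + 0.5) / (n2 + 1)
  }, numeric(ncol(X))))
  rownames(F) <- classes
  F <- pmin(pmax(F, FREQ_CLIP), 1 - FREQ_CLIP)

  W <- (!is.na(X)) * 1
  Gz <- X; Gz[is.na(Gz)] <- 0
  Q <- matrix(1 / K, nrow(X), K, dimnames = list(rownames(X), classes))
  if (K == 1L) {
    fit <- list(Q = Q, F = F, loglik = admix_loglik(Q, F, Gz, W),
                trace = NA_real_, converged = TRUE)
  } else {
    fit <- admix_em_run(Q, F, Gz, W, update_F = FALSE,
                        tol = tol, max_iter = max_iter)
  }
  structure(list(Q = fit$Q, F = fit$F, loglik = fit$loglik,
                 loglik_trace = fit$trace, mode = "supervised",
                 converged = fit$converged),
            class = "admixture_fit")
}

#' Estimate admixture proportions and ancestral frequencies (unsupervised)
#'
#' Alternating EM updates of Q (rows on the simplex) and F (entries
#' clipped away from 0/1) maximizing the binomial likelihood.  The run is
#' initialized from k-means clustering on the top-10 PCA scores of the
#' mean-imputed dosage matrix, perturbed by seeded noise; the
#' log-likelihood trace is checked to be non-decreasing on every run.
#' Components are ordered by descending total weight, so labels are
#' canonical up to that ordering (cross-run comparisons should still match
#' components, e.g. with [match_components()]).
#'
#' @param G a [genotype_matrix()].
#' @param K number of ancestral components (1 <= K <= N).
#' @param seed integer seed for the initialization.
#' @param tol,max_iter EM convergence controls.
#'
#' @return An `admixture_fit` (see [estimate_q_supervised()]), with
#'   `mode = "unsupervised"`.
#' @export
estimate_admixture_unsupervised <- function(G, K, seed = 1, tol = 1e-7,
                                            max_iter = 2000) {
  stopifnot(inherits(G, "genotype_matrix"))
  K <- check_count(K, "K")
  X <- G$dosage
  if (K > nrow(X)) stop("K exceeds the number of samples", call. = FALSE)
  W <- (!is.na(X)) * 1
  Gz <- X; Gz[is.na(Gz)] <- 0

  if (K == 1L) {
    p <- colSums(Gz) / pmax(2 * colSums(W), 1)
    F <- matrix(pmin(pmax(p, FREQ_CLIP), 1 - FREQ_CLIP), 1,
                dimnames = list("K1", colnames(X)))
    Q <- matrix(1, nrow(X), 1, dimnames = list(rownames(X), "K1"))
    return(structure(list(Q = Q, F = F,
                          loglik = admix_loglik(Q, F, Gz, W),
                          loglik_trace = NA_real_, mode = "unsupervised",
                          converged = TRUE),
                     class = "admixture_fit"))
  }

  init <- with_seed(seed, {
    Xi <- impute_mean(X)$X
    Xc <- scale(Xi, center = TRUE, scale = FALSE)
    npc <- min(10L, nrow(Xc) - 1L, ncol(Xc))
    sv <- svd(Xc, nu = npc, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(npc)], npc)
    km <- tryCatch(stats::kmeans(scores, centers = K, nstart = 5),
                   error = function(e) list(cluster = sample(rep_len(seq_len(K), nrow(Xc)))))
    Q0 <- matrix(0.5 / K, nrow(X), K)
    Q0[cbind(seq_len(nrow(X)), km$cluster)] <-
      Q0[cbind(seq_len(nrow(X)), km$cluster)] + 0.5
    Q0 <- Q0 * matrix(stats::runif(length(Q0), 0.95, 1.05), nrow(Q0))
    Q0 <- Q0 / rowSums(Q0)
    F0 <- t(vapply(seq_len(K), function(k) {
      Xi_k <- X[km$cluster == k, , drop = FALSE]
      (colSums(Xi_k, na.rm = TRUE) + 0.5) /
        (2 * pmax(colSums(!is.na(Xi_k)), 0) + 1)
    }, numeric(ncol(X))))
    list(Q = Q0, F = pmin(pmax(F0, FREQ_CLIP), 1 - FREQ_CLIP))
  })

  fit <- admix_em_run(init$Q, init$F, Gz, W, update_F = TRUE,
                      tol = tol, max_iter = max_iter)
  ord <- order(colSums(fit$Q), decreasing = TRUE)
  Q <- fit$Q[, ord, drop = FALSE]
  F <- fit$F[ord, , drop = FALSE]
  dimnames(Q) <- list(rownames(X), sprintf("K%d", seq_len(K)))
  dimnames(F) <- list(sprintf("K%d", seq_len(K)), colnames(X))
  structure(list(Q = Q, F = F, loglik = fit$loglik,
                 loglik_trace = fit$trace, mode = "unsupervised",
                 converged = fit$converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture fit (%s): %d samples, K = %d, log-likelihood %.2f\n",
              x$mode, nrow(x$Q), ncol(x$Q), x$loglik))
  invisible(x)
}

#' Cross-validation error curve over candidate K
#'
#' For each fold a seeded random mask hides `mask_fraction` of the
#' non-missing genotype entries; the admixture model is fit on the
#' unmasked entries only, and the fold error is the root-mean-square of
#' `g_ij - 2 * sum_k q_ik f_kj` over the masked entries.  The curve
#' reports the mean over folds for each K; its minimum indicates the
#' number of components supported by the data.
#'
#' @param G a [genotype_matrix()].
#' @param K_range candidate component counts.
#' @param n_folds number of masked folds per K.
#' @param mask_fraction fraction of non-missing entries hidden per fold
#'   (must be > 0).
#' @param seed integer seed.
#' @param ... passed to [estimate_admixture_unsupervised()] (e.g.
#'   `max_iter` to bound runtime).
#'
#' @return An object of class `cv_error_curve`: data.frame `K`,
#'   `mean_error`, plus `fold_errors` (K x folds matrix) as an attribute.
#' @export
admixture_cv_error <- function(G, K_range, n_folds = 5, mask_fraction = 0.1,
                               seed = 1, ...) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!length(K_range)) stop("`K_range` is empty", call. = FALSE)
  check_fraction(mask_fraction, "mask_fraction")
  if (mask_fraction <= 0) stop("`mask_fraction` must be > 0", call. = FALSE)
  n_folds <- check_count(n_folds, "n_folds")
  X <- G$dosage
  obs <- which(!is.na(X))

  masks <- with_seed(seed, lapply(seq_len(n_folds), function(f) {
    for (try in 1:20) {
      m <- sample(obs, max(1L, round(mask_fraction * length(obs))))
      Xm <- X; Xm[m] <- NA
      if (all(rowSums(!is.na(Xm)) > 0) && all(colSums(!is.na(Xm)) > 0))
        return(m)
    }
    stop("masking emptied a sample or locus in every retry", call. = FALSE)
  }))

  errs <- matrix(NA_real_, length(K_range), n_folds,
                 dimnames = list(paste0("K", K_range), NULL))
  for (ki in seq_along(K_range)) {
    for (f in seq_len(n_folds)) {
      Xm <- X; Xm[masks[[f]]] <- NA
      Gm <- genotype_matrix(Xm, sample_ids = rownames(X),
                            variant_ids = colnames(X))
      fit <- estimate_admixture_unsupervised(
        Gm, K_range[ki], seed = child_seed(seed, ki * 1000 + f), ...)
      pred <- 2 * (fit$Q %*% fit$F)
      errs[ki, f] <- sqrt(mean((X[masks[[f]]] - pred[masks[[f]]])^2))
    }
  }
  out <- data.frame(K = K_range, mean_error = rowMeans(errs))
  attr(out, "fold_errors") <- errs
  class(out) <- c("cv_error_curve", "data.frame")
  out
}

#' Pairwise Fst between ancestral components
#'
#' Nei's ratio-of-averages estimator on the ancestral allele frequencies:
#' for components a and b, `Fst = (mean_j H_T - mean_j H_S) / mean_j H_T`
#' with within heterozygosity `H_S = (2 f_a (1 - f_a) + 2 f_b (1 - f_b)) / 2`
#' and total heterozygosity `H_T = 2 fbar (1 - fbar)`, `fbar = (f_a + f_b)/2`.
#'
#' @param F K x M matrix of ancestral allele frequencies.
#' @return Symmetric K x K matrix with zero diagonal; `NA` (with a
#'   warning) where every locus is monomorphic in both components.
#' @export
fst_pairwise <- function(F) {
  F <- as.matrix(F)
  K <- nrow(F)
  if (K < 2) stop("need at least two components", call. = FALSE)
  out <- matrix(0, K, K, dimnames = list(rownames(F), rownames(F)))
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    fa <- F[a, ]; fb <- F[b, ]
    hs <- (2 * fa * (1 - fa) + 2 * fb * (1 - fb)) / 2
    fbar <- (fa + fb) / 2
    ht <- 2 * fbar * (1 - fbar)
    if (mean(ht) == 0) {
      warning(sprintf("Fst undefined for components %d and %d", a, b))
      out[a, b] <- out[b, a] <- NA_real_
    } else {
      out[a, b] <- out[b, a] <- (mean(ht) - mean(hs)) / mean(ht)
    }
  }
  out
}

#' Inbreeding coefficient per population
#'
#' For each population, `Fis = 1 - mean_j(Ho_j) / mean_j(He_j)` over the
#' loci polymorphic in that population, with observed heterozygosity
#' `Ho_j` the fraction of dosage-1 calls and expected heterozygosity
#' `He_j = 2 p_j (1 - p_j)` from the within-population allele frequency.
#'
#' @param G a [genotype_matrix()].
#' @param labels population labels (named vector or two-column data.frame).
#' @return Named numeric vector of Fis values; `NA` where a population has
#'   no polymorphic locus.
#' @export
fis_per_population <- function(G, labels) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosage
  labels <- normalize_labels(labels, rownames(X))
  pops <- sort(unique(labels))
  vapply(pops, function(pp) {
    Xi <- X[rownames(X) %in% names(labels)[labels == pp], , drop = FALSE]
    if (nrow(Xi) < 2) stop("population ", pp, " has fewer than 2 samples",
                           call. = FALSE)
    ncall <- colSums(!is.na(Xi))
    p <- colSums(Xi, na.rm = TRUE) / (2 * ncall)
    poly <- which(ncall > 0 & p > 0 & p < 1)
    if (!length(poly)) return(NA_real_)
    ho <- colSums(Xi[, poly, drop = FALSE] == 1, na.rm = TRUE) / ncall[poly]
    he <- 2 * p[poly] * (1 - p[poly])
    1 - mean(ho) / mean(he)
  }, numeric(1))
}

# All permutations of 1..n (n small), used for component matching.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

#' Match admixture components between two Q matrices
#'
#' Finds the column permutation of `Q2` maximizing the summed Pearson
#' correlation with the columns of `Q1` (exhaustive over permutations;
#' intended for the small K of admixture analyses).  Used to undo label
#' switching before comparing runs.
#'
#' @param Q1,Q2 N x K matrices on the same samples.
#' @return Integer permutation `perm` such that `Q2[, perm]` aligns with
#'   `Q1`.
#' @export
match_components <- function(Q1, Q2) {
  K <- ncol(Q1)
  stopifnot(ncol(Q2) == K, nrow(Q1) == nrow(Q2))
  if (K > 8) stop("exhaustive matching supported up to K = 8", call. = FALSE)
  cc <- suppressWarnings(stats::cor(Q1, Q2))
  cc[!is.finite(cc)] <- 0
  best <- NULL; best_val <- -Inf
  for (p in all_perms(K)) {
    v <- sum(cc[cbind(seq_len(K), p)])
    if (v > best_val) { best_val <- v; best <- p }
  }
  unlist(best)
}
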