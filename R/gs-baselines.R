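# Five standard genomic-prediction baselines behind one fit/predict
# contract.  All methods consume the same design matrix: dosages
# mean-imputed and column-centered with training-set statistics.

gs_design <- function(X, means = NULL, centers = NULL) {
  imp <- impute_mean(X, means)
  centers <- centers %||% colMeans(imp$X)
  list(W = sweep(imp$X, 2L, centers), means = imp$means, centers = centers)
}

# Single-kernel REML via the eigenvalues of the kinship restricted to the
# orthogonal complement of the intercept; returns the GLS intercept and
# the solution alpha = (K + delta I)^{-1} (y - mu).
reml_kernel <- function(K, y) {
  n <- length(y)
  # normalize the kernel scale so equivalent parameterizations (e.g. WW'
  # vs WW'/c) walk the identical objective, including at the boundary
  kscale <- mean(diag(K))
  if (kscale > 0) K <- K / kscale else kscale <- 1
  Tm <- qr.Q(qr(cbind(1, diag(n))))[, 2:n, drop = FALSE]  # basis of 1-perp
  A <- crossprod(Tm, K %*% Tm)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  theta <- pmax(ev$values, 0)
  eta <- drop(crossprod(ev$vectors, crossprod(Tm, y)))
  obj <- function(ldelta) {
    d <- 10^ldelta
    (n - 1) * log(sum(eta^2 / (theta + d))) + sum(log(theta + d))
  }
  opt <- stats::optimize(obj, c(-8, 8), tol = 1e-6)
  # polish: golden search only localizes to ~1e-4 relative; solve the
  # score equation so equivalent parameterizations agree to machine level
  grad <- function(ldelta) {
    d <- 10^ldelta
    s0 <- sum(eta^2 / (theta + d))
    s1 <- sum(eta^2 / (theta + d)^2)
    -(n - 1) * s1 / s0 + sum(1 / (theta + d))
  }
  root <- opt$minimum
  for (half_width in c(0.5, 1, 2, 4, 8)) {
    lo <- max(-8, opt$minimum - half_width)
    hi <- min(8, opt$minimum + half_width)
    found <- tryCatch({
      if (sign(grad(lo)) != sign(grad(hi)))
        stats::uniroot(grad, c(lo, hi), tol = 1e-13)$root
      else NULL
    }, error = function(e) NULL)
    if (!is.null(found)) { root <- found; break }
  }
  delta <- 10^root
  Hinv <- solve(K + diag(delta, n))
  mu <- drop(crossprod(rep(1, n), Hinv %*% y) /
               crossprod(rep(1, n), Hinv %*% rep(1, n)))
  # alpha is expressed against the caller's (unnormalized) kernel
  alpha <- drop(Hinv %*% (y - mu)) / kscale
  list(mu = mu, delta = delta * kscale, alpha = alpha)
}

rinvchisq <- function(nu, scale) nu * scale / stats::rchisq(1, nu)

bayesb_gibbs <- function(W, y, pi0, nu, n_iter, burn_in) {
  n <- nrow(W); M <- ncol(W)
  cj <- colSums(W^2)
  vy <- stats::var(y)
  # prior scale: expected included-marker variance matches half the
  # phenotypic variance spread over the expected number of included markers
  vtarget <- (vy / 2) / max((1 - pi0) * sum(cj) / n, .Machine$double.eps)
  S <- vtarget * (nu - 2) / nu
  mu <- mean(y)
  beta <- numeric(M)
  incl <- logical(M)
  sig2 <- rep(S * nu / (nu - 2), M)
  sige <- vy / 2
  e <- y - mu
  beta_sum <- numeric(M); mu_sum <- 0; kept <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(M)) {
      if (cj[j] == 0) next
      ej <- if (incl[j]) e + W[, j] * beta[j] else e
      r <- sum(W[, j] * ej)
      v1 <- cj[j] * sig2[j] + sige
      logbf <- 0.5 * (log(sige / v1) + r^2 * sig2[j] / (sige * v1))
      p1 <- 1 / (1 + pi0 / (1 - pi0) * exp(-logbf))
      if (stats::runif(1) < p1) {
        prec <- cj[j] + sige / sig2[j]
        bj <- stats::rnorm(1, r / prec, sqrt(sige / prec))
        e <- ej - W[, j] * bj
        beta[j] <- bj; incl[j] <- TRUE
        sig2[j] <- rinvchisq(nu + 1, (S * nu + bj^2) / (nu + 1))
      } else {
        if (incl[j]) e <- ej
        beta[j] <- 0; incl[j] <- FALSE
        sig2[j] <- rinvchisq(nu, S)
      }
    }
    dmu <- stats::rnorm(1, mean(e + mu) - mu, sqrt(sige / n))
    mu <- mu + dmu
    e <- e - dmu
    sige <- rinvchisq(n + 4, (sum(e^2) + 4 * vy / 2) / (n + 4))
    if (it > burn_in) {
      beta_sum <- beta_sum + beta
      mu_sum <- mu_sum + mu
      kept <- kept + 1L
    }
  }
  list(mu = mu_sum / kept, effects = beta_sum / kept)
}

#' Fit a genomic-selection model
#'
#' One interface over five standard whole-genome regression methods:
#' \describe{
#'   \item{rrblup}{ridge-regression BLUP: `y = 1 mu + W u`,
#'     `u ~ N(0, sigma_u^2 I)`; the variance ratio is estimated by REML
#'     through the eigendecomposition of `W W'`.}
#'   \item{gblup}{kinship BLUP with the VanRaden genomic relationship
#'     `G = W W' / c`, `c = sum 2 p_j (1 - p_j)`; mathematically equivalent
#'     to rrblup, parameterized by genetic values instead of marker
#'     effects.}
#'   \item{bayesb}{Gibbs sampler with per-marker inclusion (prior
#'     exclusion probability `pi0`) and scaled-t effect prior; posterior
#'     mean effects.  Chain length defaults are ours and configurable.}
#'   \item{rkhs}{Gaussian kernel `exp(-d2/h)` with the median-squared-
#'     distance bandwidth heuristic; kernel ridge with the penalty chosen
#'     by generalized cross-validation.}
#'   \item{lasso}{`glmnet` coordinate descent with the penalty from
#'     internal 5-fold cross-validation (1-SE rule), seeded folds.}
#' }
#'
#' @param G_train a [genotype_matrix()] (>= 10 samples).
#' @param y_train trait values: named vector or data.frame
#'   (`sample_id`/`accession`, value).
#' @param method one of `"rrblup"`, `"gblup"`, `"bayesb"`, `"rkhs"`,
#'   `"lasso"`.
#' @param seed integer seed (bayesb chain, lasso folds).
#' @param hyper named list of hyperparameters: `pi0`, `nu`, `n_iter`,
#'   `burn_in` (bayesb); `lambda_grid` (rkhs); `nfolds` (lasso).
#'
#' @return Object of class `genomic_model`.
#' @export
fit_genomic_model <- function(G_train, y_train,
                              method = c("rrblup", "gblup", "bayesb",
                                         "rkhs", "lasso"),
                              seed = 1, hyper = list()) {
  method <- match.arg(method)
  stopifnot(inherits(G_train, "genotype_matrix"))
  if (is.data.frame(y_train)) {
    idcol <- intersect(c("sample_id", "accession"), names(y_train))[1L]
    y_train <- stats::setNames(y_train[[setdiff(names(y_train), idcol)[1L]]],
                               y_train[[idcol]])
  }
  X <- G_train$dosage
  if (!is.null(names(y_train))) {
    common <- intersect(names(y_train), rownames(X))
    X <- X[common, , drop = FALSE]
    y <- as.numeric(y_train[common])
  } else y <- as.numeric(y_train)
  if (length(y) != nrow(X)) stop("trait/genotype sample mismatch", call. = FALSE)
  if (nrow(X) < 10) stop("need >= 10 training samples", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero-variance trait", call. = FALSE)

  des <- gs_design(X)
  W <- des$W
  model <- list(method = method, markers = colnames(X),
                impute_means = des$means, centers = des$centers,
                seed = seed)

  if (method %in% c("rrblup", "gblup")) {
    if (method == "rrblup") {
      K <- tcrossprod(W)
      fit <- reml_kernel(K, y)
      model$mu <- fit$mu
      model$effects <- drop(crossprod(W, fit$alpha))
    } else {
      p <- colMeans(impute_mean(X)$X) / 2
      cvr <- sum(2 * p * (1 - p))
      K <- tcrossprod(W) / cvr
      fit <- reml_kernel(K, y)
      model$mu <- fit$mu
      model$alpha <- fit$alpha
      model$W_train <- W
      model$c_vanraden <- cvr
    }
  } else if (method == "bayesb") {
    h <- utils::modifyList(list(pi0 = 0.95, nu = 4.2, n_iter = 5000,
                                burn_in = 1000), hyper)
    fit <- with_seed(seed, bayesb_gibbs(W, y, h$pi0, h$nu, h$n_iter,
                                        h$burn_in))
    model$mu <- fit$mu
    model$effects <- fit$effects
    model$hyper <- h
  } else if (method == "rkhs") {
    h <- utils::modifyList(list(lambda_grid = 10^seq(-4, 4, length.out = 41)),
                           hyper)
    D2 <- as.matrix(stats::dist(W))^2
    bw <- stats::median(D2[lower.tri(D2)])
    if (bw == 0) bw <- 1
    Kk <- exp(-D2 / bw)
    mu <- mean(y)
    yc <- y - mu
    ev <- eigen(Kk, symmetric = TRUE)
    gcv <- vapply(h$lambda_grid, function(l) {
      shrink <- ev$values / (ev$values + l)
      fitted <- ev$vectors %*% (shrink * crossprod(ev$vectors, yc))
      trH <- sum(shrink)
      length(y) * sum((yc - fitted)^2) / (length(y) - trH)^2
    }, numeric(1))
    lambda <- h$lambda_grid[which.min(gcv)]
    model$mu <- mu
    model$alpha <- drop(solve(Kk + diag(lambda, nrow(Kk)), yc))
    model$W_train <- W
    model$bandwidth <- bw
    model$lambda <- lambda
  } else {   # lasso
    h <- utils::modifyList(list(nfolds = 5), hyper)
    cvfit <- with_seed(seed, glmnet::cv.glmnet(W, y, nfolds = h$nfolds))
    cf <- as.numeric(stats::coef(cvfit, s = "lambda.1se"))
    model$mu <- cf[1L]
    model$effects <- cf[-1L]
    model$lambda <- cvfit$lambda.1se
  }
  structure(model, class = "genomic_model")
}

#' @export
print.genomic_model <- function(x, ...) {
  cat(sprintf("Genomic model (%s): %d markers, intercept %.4g\n",
              x$method, length(x$markers), x$mu))
  invisible(x)
}

#' Predict phenotypes with a fitted genomic model
#'
#' Markers must match the training set by id (any order); missing dosages
#' are imputed with the training means and columns centered with the
#' training centers.
#'
#' @param object a [fit_genomic_model()] result.
#' @param G_new a [genotype_matrix()] on the same markers.
#' @param ... unused.
#' @return data.frame `sample_id`, `predicted`.
#' @export
predict.genomic_model <- function(object, G_new, ...) {
  stopifnot(inherits(G_new, "genotype_matrix"))
  X <- G_new$dosage
  if (!setequal(colnames(X), object$markers)) {
    extra <- setdiff(colnames(X), object$markers)
    lack <- setdiff(object$markers, colnames(X))
    stop("marker mismatch; missing: ",
         paste(utils::head(lack, 5), collapse = ", "),
         if (length(lack) > 5) " ...", "; unexpected: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ...", call. = FALSE)
  }
  X <- X[, object$markers, drop = FALSE]
  W <- gs_design(X, means = object$impute_means, centers = object$centers)$W
  yhat <- if (object$method %in% c("rrblup", "bayesb", "lasso")) {
    object$mu + drop(W %*% object$effects)
  } else if (object$method == "gblup") {
    Kx <- tcrossprod(W, object$W_train) / object$c_vanraden
    object$mu + drop(Kx %*% object$alpha)
  } else {   # rkhs
    D2 <- outer(rowSums(W^2), rowSums(object$W_train^2), "+") -
      2 * tcrossprod(W, object$W_train)
    Kx <- exp(-pmax(D2, 0) / object$bandwidth)
    object$mu + drop(Kx %*% object$alpha)
  }
  data.frame(sample_id = rownames(X), predicted = unname(yhat),
             stringsAsFactors = FALSE)
}

#' @rdname predict.genomic_model
#' @param model a `genomic_model`.
#' @export
predict_genomic <- function(model, G_new) predict.genomic_model(model, G_new)
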