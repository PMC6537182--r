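# Trait prediction from admixture proportions: LS means from augmented
# block designs, best-minimum-model search over admixture components,
# and prediction on new samples.

#' Least-squares means of accessions from a blocked design
#'
#' Fits the two-way fixed-effects model
#' `y_ijk = mu + block_i + accession_j + e_ijk` by ordinary least squares
#' (treatment contrasts) and returns, for each accession, its predicted
#' value averaged with equal weight over all blocks — the LS mean, which
#' corrects accession means for block effects in unbalanced (augmented)
#' designs.
#'
#' @param raw data.frame with columns `accession`, `block`, and the score
#'   (third column or named via `response`).
#' @param response name of the score column; defaults to the first
#'   non-design column.
#' @return data.frame `accession`, `ls_mean`.
#' @export
ls_means <- function(raw, response = NULL) {
  stopifnot(all(c("accession", "block") %in% names(raw)))
  response <- response %||% setdiff(names(raw), c("accession", "block"))[1L]
  df <- data.frame(y = raw[[response]],
                   block = factor(raw$block),
                   accession = factor(raw$accession))
  if (nlevels(df$accession) < 2) stop("need >= 2 accessions", call. = FALSE)

  if (nlevels(df$block) > 1L) {
    # connectivity: blocks sharing accessions must form one component
    inc <- table(df$block, df$accession) > 0
    adj <- inc %*% t(inc) > 0
    comp <- seq_len(nrow(adj))
    repeat {
      new <- apply(adj, 1L, function(r) min(comp[r]))
      if (identical(new, comp)) break
      comp <- new
    }
    if (length(unique(comp)) > 1L)
      stop("disconnected block design; components: ",
           paste(tapply(rownames(adj), comp, paste, collapse = "+"),
                 collapse = " | "), call. = FALSE)
  }

  fit <- if (nlevels(df$block) > 1L) {
    stats::lm(y ~ block + accession, data = df)
  } else stats::lm(y ~ accession, data = df)
  grid <- expand.grid(block = levels(df$block),
                      accession = levels(df$accession))
  pred <- stats::predict(fit, newdata = grid)
  out <- stats::aggregate(pred, list(accession = grid$accession), mean)
  data.frame(accession = as.character(out$accession), ls_mean = out$x,
             stringsAsFactors = FALSE)
}

subset_bic <- function(fit) {
  n <- length(stats::residuals(fit))
  rss <- sum(stats::residuals(fit)^2)
  p <- length(stats::coef(fit))
  n * log(rss / n) + p * log(n)
}

#' Best-minimum linear model of a trait on admixture components
#'
#' Because admixture proportions sum to one, the full K-component model is
#' collinear; the search space is therefore every non-empty proper subset
#' of the components.  Each candidate is fit by OLS with an intercept, the
#' candidate with the smallest BIC wins (ties broken by fewer terms, then
#' lexicographic component order), and backward pruning then drops the
#' largest-p term while any term exceeds `alpha`.  A stepwise search is
#' available for large K.
#'
#' @param traits data.frame `sample_id` (or `accession`) plus one trait
#'   column, or a named numeric vector.
#' @param Q N x K admixture matrix with rownames matching the trait ids.
#' @param alpha significance level each retained component must meet.
#' @param search `"exhaustive"` (default, feasible for the usual K <= 12)
#'   or `"stepwise"` (bidirectional BIC steps from the intercept model).
#'
#' @return Object of class `admixture_lm`: `terms` (selected component
#'   names), `coefficients` table (estimate, std. error, t, p), `r2`,
#'   `model_p`, `n`, `alpha`, and the underlying `lm` fit.
#' @export
fit_admixture_lm <- function(traits, Q, alpha = 0.05,
                             search = c("exhaustive", "stepwise")) {
  search <- match.arg(search)
  check_fraction(alpha, "alpha", open = TRUE)
  Q <- as.matrix(Q)
  if (ncol(Q) < 2) stop("need K >= 2 components", call. = FALSE)
  if (is.data.frame(traits)) {
    idcol <- intersect(c("sample_id", "accession"), names(traits))[1L]
    y <- stats::setNames(traits[[setdiff(names(traits), idcol)[1L]]],
                         traits[[idcol]])
  } else y <- traits
  common <- intersect(names(y), rownames(Q))
  if (length(common) < ncol(Q) + 2)
    stop("need at least K + 2 samples with both trait and Q", call. = FALSE)
  y <- y[common]
  X <- Q[common, , drop = FALSE]
  comps <- colnames(X)
  dat <- data.frame(y = as.numeric(y), X, check.names = FALSE)

  fit_subset <- function(ss) stats::lm(
    stats::reformulate(sprintf("`%s`", ss), response = "y"), data = dat)

  if (stats::sd(dat$y) == 0) {
    best <- stats::lm(y ~ 1, data = dat)
    sel <- character(0)
  } else if (search == "exhaustive") {
    subsets <- unlist(lapply(seq_len(length(comps) - 1L), function(m)
      utils::combn(comps, m, simplify = FALSE)), recursive = FALSE)
    bics <- vapply(subsets, function(ss) subset_bic(fit_subset(ss)), numeric(1))
    # tie-break: fewer terms, then lexicographic order of the subset
    ord <- order(bics, lengths(subsets),
                 vapply(subsets, function(s) paste(s, collapse = ","),
                        character(1)))
    sel <- subsets[[ord[1L]]]
    best <- fit_subset(sel)
  } else {
    null <- stats::lm(y ~ 1, data = dat)
    full <- stats::reformulate(sprintf("`%s`", comps[-length(comps)]),
                               response = "y")
    best <- stats::step(null, scope = list(lower = ~1, upper = full),
                        direction = "both", k = log(nrow(dat)), trace = 0)
    sel <- setdiff(all.vars(stats::formula(best)), "y")
    if (length(sel)) best <- fit_subset(sel)
  }

  # backward pruning at alpha
  repeat {
    if (!length(sel)) { best <- stats::lm(y ~ 1, data = dat); break }
    tab <- summary(best)$coefficients
    pv <- tab[-1L, 4L]
    if (all(pv <= alpha)) break
    sel <- sel[-which.max(pv)]
    best <- if (length(sel)) fit_subset(sel) else stats::lm(y ~ 1, data = dat)
  }
  if (!length(sel))
    warning("no component subset with all terms significant; ",
            "returning the intercept-only model")

  sm <- summary(best)
  model_p <- if (length(sel)) {
    fs <- sm$fstatistic
    stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  } else NA_real_
  structure(list(terms = sel, coefficients = sm$coefficients,
                 r2 = if (length(sel)) sm$r.squared else 0,
                 model_p = unname(model_p), n = nrow(dat), alpha = alpha,
                 fit = best),
            class = "admixture_lm")
}

#' @export
print.admixture_lm <- function(x, ...) {
  cat(sprintf("Admixture-component linear model (n = %d)\n", x$n))
  if (length(x$terms)) {
    stats::printCoefmat(x$coefficients, digits = 4)
    cat(sprintf("r2 = %.3g, model p = %.3g\n", x$r2, x$model_p))
  } else cat("  intercept-only (no significant component)\n")
  invisible(x)
}

#' @export
coef.admixture_lm <- function(object, ...) stats::coef(object$fit)

#' Predict a trait from admixture proportions
#'
#' @param object an [fit_admixture_lm()] result.
#' @param Q admixture matrix containing the components named in the fit.
#' @param ... unused.
#' @return data.frame `sample_id`, `predicted`.
#' @export
predict.admixture_lm <- function(object, Q, ...) {
  Q <- as.matrix(Q)
  missing <- setdiff(object$terms, colnames(Q))
  if (length(missing))
    stop("Q lacks component column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  nd <- as.data.frame(Q, check.names = FALSE)
  data.frame(sample_id = rownames(Q) %||% seq_len(nrow(Q)),
             predicted = unname(stats::predict(object$fit, newdata = nd)),
             stringsAsFactors = FALSE)
}

#' @rdname predict.admixture_lm
#' @param fit an `admixture_lm` object.
#' @export
predict_trait <- function(fit, Q) predict.admixture_lm(fit, Q)
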