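# Repeated stratified k-fold cross-validation, Pearson reliability, and
# Kruskal-Wallis method comparison with a compact letter display.

#' Repeated stratified fold plans
#'
#' For every round each population's members are shuffled (seeded) and
#' dealt round-robin into `k` folds from a random starting fold, so each
#' fold's per-population count differs from proportionality by at most
#' one; populations with fewer than `k` members contribute to as many
#' folds as they have members.
#'
#' @param populations population labels, named by sample id.
#' @param k folds per round.
#' @param rounds number of rounds.
#' @param seed integer seed.
#' @return Object of class `fold_plan`: a list of rounds, each a list of
#'   `k` character vectors of test-sample ids.
#' @export
stratified_folds <- function(populations, k = 5, rounds = 50, seed = 1) {
  k <- check_count(k, "k", min = 2)
  rounds <- check_count(rounds, "rounds")
  ids <- names(populations)
  if (is.null(ids)) stop("`populations` must be named by sample id",
                         call. = FALSE)
  if (k > length(ids)) stop("k exceeds the number of samples", call. = FALSE)
  plan <- with_seed(seed, lapply(seq_len(rounds), function(r) {
    folds <- vector("list", k)
    for (pp in unique(populations)) {
      members <- sample(ids[populations == pp])
      start <- sample.int(k, 1L)
      f <- ((start - 1L + seq_along(members) - 1L) %% k) + 1L
      for (i in seq_along(members))
        folds[[f[i]]] <- c(folds[[f[i]]], members[i])
    }
    folds
  }))
  structure(plan, class = "fold_plan", k = k, rounds = rounds, seed = seed)
}

#' Cross-validated prediction reliability
#'
#' For every fold of every round, the predictor is fit on the training
#' complement and used to predict the test fold; the fold's reliability is
#' the Pearson correlation between predicted and observed trait values.
#' Folds with zero variance in either vector are skipped and logged.
#'
#' A predictor is a list with elements `fit(ids, y, seed)` (returning any
#' model object) and `predict(model, ids)` (returning predictions named by
#' sample id); see [whogem_predictor()] and [gs_predictor()].  Note that
#' the admixture-proportion predictor uses Q estimated once on all
#' samples, mirroring the original protocol; the resulting (mild)
#' information leakage into test folds is a property of that protocol.
#'
#' @param predictor predictor object (see above).
#' @param y named numeric trait vector.
#' @param plan a [stratified_folds()] plan.
#' @param seed integer seed passed to fold-level fits.
#' @return Object of class `cv_reliability`: numeric vector of per-fold
#'   correlations, with `skipped` and `errors` attributes.
#' @export
repeated_cv <- function(predictor, y, plan, seed = 1) {
  stopifnot(is.list(predictor), is.function(predictor$fit),
            is.function(predictor$predict))
  ids_all <- names(y)
  rel <- numeric(0); skipped <- character(0); errors <- character(0)
  for (r in seq_along(plan)) {
    for (f in seq_along(plan[[r]])) {
      test <- intersect(plan[[r]][[f]], ids_all)
      train <- setdiff(ids_all, test)
      if (length(test) < 3) { skipped <- c(skipped, sprintf("r%df%d: tiny fold", r, f)); next }
      pred <- tryCatch({
        model <- predictor$fit(train, y[train],
                               child_seed(seed, r * 100 + f))
        predictor$predict(model, test)[test]
      }, error = function(e) {
        structure(conditionMessage(e), class = "cv_fold_error")
      })
      if (inherits(pred, "cv_fold_error")) {
        errors <- c(errors, sprintf("r%df%d: %s", r, f, unclass(pred)))
      } else if (stats::sd(y[test]) == 0 || stats::sd(pred) == 0) {
        skipped <- c(skipped, sprintf("r%df%d: zero variance", r, f))
      } else {
        rel <- c(rel, stats::cor(pred, y[test]))
      }
    }
  }
  structure(rel, class = "cv_reliability", skipped = skipped, errors = errors)
}

#' @export
print.cv_reliability <- function(x, ...) {
  cat(sprintf("CV reliability: %d folds, mean r = %.3f (median %.3f)\n",
              length(x), mean(unclass(x)), stats::median(unclass(x))))
  invisible(x)
}

#' Predictor wrappers for cross-validation
#'
#' `whogem_predictor` predicts traits from admixture proportions via
#' [fit_admixture_lm()]; `gs_predictor` wraps any [fit_genomic_model()]
#' method.
#'
#' @param Q N x K admixture matrix (all samples).
#' @param alpha,search passed to [fit_admixture_lm()].
#' @return A predictor list for [repeated_cv()].
#' @export
whogem_predictor <- function(Q, alpha = 0.05, search = "exhaustive") {
  Q <- as.matrix(Q)
  list(
    fit = function(ids, y, seed) fit_admixture_lm(y, Q[ids, , drop = FALSE],
                                                  alpha = alpha,
                                                  search = search),
    predict = function(model, ids) {
      pr <- predict_trait(model, Q[ids, , drop = FALSE])
      stats::setNames(pr$predicted, pr$sample_id)
    })
}

#' @rdname whogem_predictor
#' @param G a [genotype_matrix()] covering all samples.
#' @param method,hyper passed to [fit_genomic_model()].
#' @export
gs_predictor <- function(G, method, hyper = list()) {
  stopifnot(inherits(G, "genotype_matrix"))
  list(
    fit = function(ids, y, seed) {
      Gi <- genotype_matrix(G$dosage[ids, , drop = FALSE],
                            sample_ids = ids,
                            variant_ids = colnames(G$dosage))
      fit_genomic_model(Gi, y, method = method, seed = seed, hyper = hyper)
    },
    predict = function(model, ids) {
      Gi <- genotype_matrix(G$dosage[ids, , drop = FALSE],
                            sample_ids = ids,
                            variant_ids = colnames(G$dosage))
      pr <- predict_genomic(model, Gi)
      stats::setNames(pr$predicted, pr$sample_id)
    })
}

# maximal fully-non-significant subsets of methods -> compact letters
letter_display <- function(methods, nonsig) {
  m <- length(methods)
  subsets <- list()
  for (mask in seq_len(2^m - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (length(members) == 1L ||
        all(nonsig[t(utils::combn(members, 2))])) {
      subsets[[length(subsets) + 1L]] <- members
    }
  }
  # keep maximal subsets only
  keep <- vapply(seq_along(subsets), function(i) {
    !any(vapply(subsets, function(s)
      length(s) > length(subsets[[i]]) && all(subsets[[i]] %in% s),
      logical(1)))
  }, logical(1))
  groups <- subsets[keep]
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  letters_out <- rep("", m)
  for (gi in seq_along(groups))
    letters_out[groups[[gi]]] <- paste0(letters_out[groups[[gi]]],
                                        letters[gi])
  stats::setNames(letters_out, methods)
}

#' Compare method reliabilities with a Kruskal-Wallis test and letters
#'
#' Omnibus Kruskal-Wallis rank test (tie-corrected) across methods,
#' followed by pairwise two-sided Mann-Whitney tests with Holm adjustment;
#' methods sharing a letter are not significantly different at `alpha`.
#'
#' @param results named list of per-fold reliability vectors (e.g.
#'   [repeated_cv()] outputs).
#' @param alpha significance level for the letter grouping.
#' @return List of class `method_comparison`: `statistic` (H), `df`, `p`,
#'   `letters`, `pairwise_p` matrix, `medians`.
#' @export
compare_methods <- function(results, alpha = 0.01) {
  if (length(results) < 2) stop("need >= 2 methods", call. = FALSE)
  if (any(lengths(results) < 2)) stop("each method needs >= 2 values",
                                      call. = FALSE)
  methods <- names(results) %||% paste0("method", seq_along(results))
  values <- unlist(lapply(results, unclass), use.names = FALSE)
  groups <- factor(rep(methods, lengths(results)), levels = methods)
  if (stats::sd(values) == 0) {
    return(structure(list(statistic = 0, df = length(results) - 1L, p = 1,
                          letters = stats::setNames(rep("a", length(methods)),
                                                    methods),
                          pairwise_p = NULL,
                          medians = vapply(results, stats::median, numeric(1))),
                     class = "method_comparison"))
  }
  kw <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = "holm",
                                exact = FALSE))
  pp <- matrix(1, length(methods), length(methods),
               dimnames = list(methods, methods))
  tab <- pw$p.value
  for (i in rownames(tab)) for (j in colnames(tab))
    if (!is.na(tab[i, j])) pp[i, j] <- pp[j, i] <- tab[i, j]
  nonsig <- pp > alpha
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, letters = letter_display(methods, nonsig),
                 pairwise_p = pp,
                 medians = vapply(results, stats::median, numeric(1))),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  tab <- data.frame(median = round(x$medians, 3), group = x$letters)
  print(tab)
  invisible(x)
}
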