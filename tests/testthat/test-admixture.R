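# Admixture estimation (both modes), the CV error curve, Fst and Fis.

test_that("supervised estimation recovers purebred and admixed samples", {
  G <- fix_sim3$genotypes
  fit <- estimate_q_supervised(G, fix_labels3, max_iter = 500)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-8))
  # likelihood trace is non-decreasing
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))

  # parameter recovery against the generator truth (components are named
  # by population label here, which matches P1..P3 <-> K1..K3)
  Qhat <- fit$Q[, order(colnames(fit$Q))]
  perm <- match_components(fix_sim3$q_true, Qhat)
  err <- mean(abs(Qhat[, perm] - fix_sim3$q_true))
  expect_lt(err, 0.05)

})

test_that("purebred queries against well-separated references score > 0.95", {
  # fully purebred reference world (fst 0.3, M = 2000), plus queries whose
  # genotype is the rounded expected dosage 2 * f_1j
  q_pure <- diag(3)[rep(1:3, each = 20), ]
  rownames(q_pure) <- sprintf("S%03d", 1:60)
  gen <- simulate_genotypes(q_pure, 2000, fst_f = 0.3, seed = 8)
  F <- gen$freqs_true
  query <- matrix(round(2 * F[1, ]), 5, ncol(F), byrow = TRUE)
  rownames(query) <- sprintf("query%d", 1:5)
  colnames(query) <- colnames(gen$genotypes$dosage)
  Gp <- genotype_matrix(rbind(gen$genotypes$dosage, query))
  labels <- stats::setNames(sprintf("P%d", rep(1:3, each = 20)),
                            sprintf("S%03d", 1:60))
  fitp <- estimate_q_supervised(Gp, labels, max_iter = 500)
  expect_true(all(fitp$Q[sprintf("query%d", 1:5), "P1"] > 0.95))
})

test_that("supervised K = 1 and error cases behave", {
  G <- fix_sim3$genotypes
  one <- estimate_q_supervised(G, stats::setNames(rep("only", 90),
                                                  rownames(G$dosage)))
  expect_equal(unname(one$Q), matrix(1, 90, 1))
  X <- G$dosage; X[1, ] <- NA
  expect_error(estimate_q_supervised(genotype_matrix(X), fix_labels3),
               "missing")
})

test_that("supervised accuracy improves with more loci", {
  errs <- vapply(c(100, 1000), function(M) {
    gen <- simulate_genotypes(fix_sim3$q_true, M, 0.2, seed = 31)
    fit <- estimate_q_supervised(gen$genotypes, fix_labels3, max_iter = 300)
    Qhat <- fit$Q[, order(colnames(fit$Q))]
    perm <- match_components(fix_sim3$q_true, Qhat)
    mean(abs(Qhat[, perm] - fix_sim3$q_true))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("unsupervised EM is monotone and recovers K_true = 3 structure", {
  fit <- estimate_admixture_unsupervised(fix_sim3$genotypes, K = 3,
                                         seed = 2, max_iter = 400)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  perm <- match_components(fix_sim3$q_true, fit$Q)
  expect_lt(mean(abs(fit$Q[, perm] - fix_sim3$q_true)), 0.08)
  # canonical order: descending component mass
  expect_true(all(diff(colSums(fit$Q)) <= 1e-8))

  # K = 1 closed form: F is the observed frequency vector (clipped away
  # from the boundary at monomorphic loci)
  f1 <- estimate_admixture_unsupervised(fix_sim3$genotypes, K = 1)
  pobs <- colMeans(fix_sim3$genotypes$dosage, na.rm = TRUE) / 2
  expect_equal(unname(f1$F[1, ]),
               unname(pmin(pmax(pobs, 1e-6), 1 - 1e-6)), tolerance = 1e-12)
  expect_equal(unname(f1$Q), matrix(1, 90, 1))
  expect_error(estimate_admixture_unsupervised(fix_sim3$genotypes, K = 500),
               "K exceeds")
})

test_that("cv error curve flags overfitting and guards its inputs", {
  # K_true = 1 data: no structure, so error does not improve past K = 1
  g1 <- simulate_genotypes(matrix(1, 60, 1), 200, 0.2, seed = 13)
  cv <- admixture_cv_error(g1$genotypes, 1:3, n_folds = 3, seed = 1,
                           max_iter = 80)
  fe <- attr(cv, "fold_errors")
  se1 <- stats::sd(fe[1, ]) / sqrt(ncol(fe))
  expect_lt(cv$mean_error[1], min(cv$mean_error) + se1 + 1e-12)
  expect_error(admixture_cv_error(g1$genotypes, 1:2, mask_fraction = 0),
               "mask_fraction")
})

test_that("Fst matches hand arithmetic and responds to differentiation", {
  expect_equal(fst_pairwise(rbind(c(0.3, 0.6), c(0.3, 0.6)))[1, 2], 0)
  expect_equal(fst_pairwise(rbind(0, 1))[1, 2], 1)
  # f_a = 0.1, f_b = 0.9: H_S = 0.18, H_T = 0.5, Fst = 0.64
  expect_equal(fst_pairwise(rbind(0.1, 0.9))[1, 2], 0.64)
  expect_warning(out <- fst_pairwise(rbind(c(0, 0), c(0, 0))), "undefined")
  expect_true(is.na(out[1, 2]))

  # permutation invariance over loci, and growth in the generator fst_f
  F <- fix_sim3$freqs_true
  set.seed(17)
  perm <- sample(ncol(F))
  expect_equal(fst_pairwise(F[, perm]), fst_pairwise(F))
  med_fst <- vapply(c(0.05, 0.15, 0.3), function(f) {
    Fs <- simulate_genotypes(fix_sim3$q_true, 400, f, seed = 3)$freqs_true
    stats::median(fst_pairwise(Fs)[lower.tri(diag(3))])
  }, numeric(1))
  expect_true(all(diff(med_fst) > 0))
})

test_that("Fis matches hand arithmetic", {
  # all homozygous -> Fis = 1
  Xh <- rbind(c(0, 2), c(2, 0), c(0, 0), c(2, 2))
  lab <- stats::setNames(rep("p", 4), rownames(genotype_matrix(Xh)$dosage))
  expect_equal(unname(fis_per_population(genotype_matrix(Xh), lab)), 1)
  # exact HWE counts 1xAA 2xAa 1xaa -> Fis = 0
  Xw <- matrix(c(0, 1, 1, 2), 4)
  expect_equal(unname(fis_per_population(genotype_matrix(Xw),
                                         stats::setNames(rep("p", 4),
                                                         sprintf("S%03d", 1:4)))),
               0)
  # counts 2xAA(dosage 2), 1xAa, 1xaa: p = 0.625, Ho = 0.25, He = 0.46875
  Xu <- matrix(c(2, 2, 1, 0), 4)
  expect_equal(unname(fis_per_population(genotype_matrix(Xu),
                                         stats::setNames(rep("p", 4),
                                                         sprintf("S%03d", 1:4)))),
               1 - 0.25 / 0.46875, tolerance = 1e-12)
})
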