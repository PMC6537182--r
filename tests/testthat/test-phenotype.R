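# LS means and trait prediction from admixture proportions.

test_that("LS means equal plain means for balanced or single-block designs", {
  set.seed(1)
  raw <- data.frame(accession = rep(c("a", "b", "c"), each = 4),
                    block = rep(c("B1", "B2"), 6),
                    score = rnorm(12))
  lsm <- ls_means(raw)
  plain <- tapply(raw$score, raw$accession, mean)
  expect_equal(lsm$ls_mean, as.numeric(plain[lsm$accession]),
               tolerance = 1e-12)

  raw1 <- raw[raw$block == "B1", ]
  lsm1 <- ls_means(raw1)
  plain1 <- tapply(raw1$score, raw1$accession, mean)
  expect_equal(lsm1$ls_mean, as.numeric(plain1[lsm1$accession]))
})

test_that("LS means solve the unbalanced normal equations", {
  # 2-block toy, solvable by hand: mu + block2 + accession effects
  raw <- data.frame(accession = c("a", "a", "b", "b", "c", "c"),
                    block = c("B1", "B2", "B1", "B1", "B2", "B2"),
                    score = c(1, 3, 2, 2, 5, 7))
  lsm <- ls_means(raw)
  # oracle: explicit design-matrix OLS, then equal-weight block average
  Xd <- cbind(1, raw$block == "B2", raw$accession == "b", raw$accession == "c")
  cf <- solve(crossprod(Xd), crossprod(Xd, raw$score))
  oracle <- c(a = cf[1] + cf[2] / 2,
              b = cf[1] + cf[3] + cf[2] / 2,
              c = cf[1] + cf[4] + cf[2] / 2)
  expect_equal(lsm$ls_mean, as.numeric(oracle[lsm$accession]),
               tolerance = 1e-10)

  # 50 random unbalanced designs against the same oracle
  for (s in 1:50) {
    set.seed(s)
    n <- 30
    d <- data.frame(accession = sample(letters[1:5], n, TRUE),
                    block = sample(c("B1", "B2", "B3"), n, TRUE),
                    score = rnorm(n))
    d <- d[order(d$accession), ]
    if (length(unique(d$accession)) < 2) next
    fit <- stats::lm(score ~ block + accession, data = d)
    grid <- expand.grid(block = unique(d$block),
                        accession = unique(d$accession))
    ora <- tapply(stats::predict(fit, grid), grid$accession, mean)
    got <- ls_means(d)
    expect_equal(got$ls_mean, as.numeric(ora[got$accession]),
                 tolerance = 1e-8)
  }
})

test_that("disconnected designs error, absent accessions are absent", {
  raw <- data.frame(accession = c("a", "a", "b", "b"),
                    block = c("B1", "B1", "B2", "B2"),
                    score = 1:4)
  expect_error(ls_means(raw), "disconnected")
})

test_that("best-minimum-model search recovers the generating component", {
  set.seed(2)
  N <- 200
  Q <- t(apply(matrix(rgamma(N * 4, 1), N), 1, function(x) x / sum(x)))
  colnames(Q) <- paste0("K", 1:4)
  rownames(Q) <- sprintf("S%03d", 1:N)
  y <- 2 + 3 * Q[, 2] + rnorm(N, 0, 0.01)
  fit <- suppressWarnings(   # near-noiseless fit trips lm's perfect-fit note
    fit_admixture_lm(stats::setNames(y, rownames(Q)), Q))
  expect_identical(fit$terms, "K2")
  expect_lt(abs(coef(fit)[["K2"]] - 3), 0.1)
  expect_true(all(fit$coefficients[-1, 4] <= 0.05))

  # constant trait: intercept-only with r2 = 0 (the zero-residual fit also
  # trips lm's perfect-fit note, hence capture_warnings)
  w <- capture_warnings(
    fit0 <- fit_admixture_lm(stats::setNames(rep(1, N), rownames(Q)), Q))
  expect_true(any(grepl("intercept-only", w)))
  expect_length(fit0$terms, 0)
  expect_equal(fit0$r2, 0)
})

test_that("the selection is invariant to component relabeling", {
  set.seed(3)
  N <- 120
  Q <- t(apply(matrix(rgamma(N * 4, 1), N), 1, function(x) x / sum(x)))
  colnames(Q) <- paste0("K", 1:4); rownames(Q) <- sprintf("S%03d", 1:N)
  y <- stats::setNames(1 + 2 * Q[, 1] - 1.5 * Q[, 3] + rnorm(N, 0, 0.1),
                       rownames(Q))
  f1 <- fit_admixture_lm(y, Q)
  perm <- c(3, 1, 4, 2)
  Qp <- Q[, perm]
  f2 <- fit_admixture_lm(y, Qp)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
  expect_setequal(f1$terms, f2$terms)
})

test_that("predict_trait reproduces fitted values and simple arithmetic", {
  sim <- fix_sim3
  fit <- fit_admixture_lm(sim$traits, sim$q_true)
  pr <- predict_trait(fit, sim$q_true)
  expect_equal(pr$predicted, unname(stats::fitted(fit$fit)),
               tolerance = 1e-12)

  # hand arithmetic: beta0 = 2, betaK2 = 3, q2 = 0.5 -> 3.5
  manual <- fit
  manual$fit <- stats::lm(y ~ K2, data = data.frame(y = c(2, 5), K2 = c(0, 1)))
  manual$terms <- "K2"
  Qnew <- matrix(c(0.5, 0.5), 1, dimnames = list("x", c("K1", "K2")))
  expect_equal(predict_trait(manual, Qnew)$predicted, 3.5)
  expect_error(predict_trait(fit, Qnew[, 1, drop = FALSE]), "component")
})

test_that("fitted r2 approaches the trait's structural heritability", {
  set.seed(4)
  N <- 1000
  Q <- t(apply(matrix(rgamma(N * 3, 2), N), 1, function(x) x / sum(x)))
  colnames(Q) <- paste0("K", 1:3); rownames(Q) <- sprintf("S%04d", 1:N)
  beta <- c(0, 2, -1, 0)
  signal <- drop(Q %*% beta[-1])
  sigma <- stats::sd(signal)           # structural h2 = 0.5
  y <- stats::setNames(signal + rnorm(N, 0, sigma), rownames(Q))
  fit <- fit_admixture_lm(y, Q)
  expect_lt(abs(fit$r2 - 0.5), 0.05)
})
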