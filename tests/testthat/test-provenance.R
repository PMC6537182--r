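# Distances, Mantel test, calibration, placement, LOO, K selection.

test_that("admixture and geographic distances match hand arithmetic", {
  Q <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.2, 0.8), c(1, 0))
  D <- admixture_distance_matrix(Q)
  expect_equal(D[1, 5], 0)
  expect_equal(D[1, 2], sqrt(2))
  expect_equal(D[3, 4], sqrt(0.18))

  geo <- data.frame(sample_id = c("a", "b", "c"),
                    latitude = c(0, 0, 3), longitude = c(0, 1, 4))
  De <- geographic_distance_matrix(geo, "euclidean-degrees")
  expect_equal(De[1, 1], 0)
  expect_equal(De[1, 3], 5)                       # 3-4-5 triangle
  Dk <- geographic_distance_matrix(geo, "great-circle-km")
  expect_equal(Dk[1, 2], 111.19, tolerance = 1e-3)  # 1 deg on the equator
})

test_that("Mantel statistic matches an exhaustive permutation oracle", {
  set.seed(4)
  P <- matrix(runif(8), 4)
  D1 <- as.matrix(dist(P)); D2 <- as.matrix(dist(P + rnorm(8, 0, 0.3)))
  mt <- mantel_test(D1, D2, n_perm = 999, seed = 1)
  low <- lower.tri(D1)
  expect_equal(mt$r, cor(D1[low], D2[low]))

  # brute force over all 24 relabelings: exact exceedance fraction
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rs <- apply(perms, 1, function(p) {
    Dp <- D2[unlist(p), unlist(p)]
    cor(D1[low], Dp[low])
  })
  exact_frac <- mean(rs >= mt$r)
  expect_lt(abs(mt$p - exact_frac), 0.05)

  # identity: r = 1 with the smallest attainable p (on a matrix large
  # enough that a sampled permutation is essentially never an automorphism)
  set.seed(5)
  Db <- as.matrix(dist(matrix(runif(16), 8)))
  mt1 <- mantel_test(Db, Db, n_perm = 99, seed = 2)
  expect_equal(mt1$r, 1)
  expect_equal(mt1$p, 1 / 100)
  expect_error(mantel_test(matrix(0, 3, 3), D1[1:3, 1:3]), "zero variance")
})

test_that("Mantel agrees with the vegan implementation", {
  set.seed(11)
  P <- matrix(runif(20), 10)
  D1 <- as.matrix(dist(P))
  D2 <- as.matrix(dist(P + rnorm(20, 0, 0.5)))
  mt <- mantel_test(D1, D2, n_perm = 999, seed = 3)
  vg <- vegan::mantel(D1, D2, permutations = 999)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(mt$p - vg$signif), 0.05)
})

test_that("calibration recovers a noiseless linear relation", {
  set.seed(6)
  n <- 25
  pts <- matrix(runif(2 * n), n)
  genD <- as.matrix(dist(pts)) / 10
  geoD <- 5 * genD                      # geo = 5 * gen exactly
  cal <- suppressWarnings(   # "essentially perfect fit" is the point here
    calibrate(genD, geoD, cutoff = max(geoD) + 1, n_perm = 99, seed = 1))
  expect_equal(cal$slope, 5, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$adj_r2, 1, tolerance = 1e-9)
  expect_equal(cal$mantel_r_filtered, 1, tolerance = 1e-12)
  expect_error(calibrate(genD, geoD, cutoff = 1e-9), "fewer than 3")
})

test_that("the packaged calibration carries the published constants", {
  cal <- mtruncatula_calibration()
  expect_equal(cal$intercept, 0.204)
  expect_equal(cal$slope, 4.973)
  expect_equal(cal$cutoff * cal$km_per_degree, 950)
  expect_equal(cal$mantel_r_all, 0.294)
  expect_equal(cal$mantel_r_filtered, 0.78)
  expect_identical(cal$metric, "euclidean-degrees")
})

toy_panel <- function(theta, lat, lon, country = NULL) {
  if (is.null(country)) country <- sprintf("c%d", seq_along(lat))
  geo <- data.frame(sample_id = sprintf("u%d", seq_along(lat)),
                    latitude = lat, longitude = lon,
                    country = country,
                    population = sprintf("u%d", seq_along(lat)))
  rownames(theta) <- geo$sample_id
  reference_panel(theta, geo, level = "accession")
}

flat_cal <- function(a, b, cutoff = 100) {
  structure(list(intercept = a, slope = b, cutoff = cutoff,
                 adj_r2 = NA, mantel_r_all = NA, mantel_p_all = NA,
                 mantel_r_filtered = NA, mantel_p_filtered = NA,
                 n_pairs = NA, metric = "euclidean-degrees",
                 km_per_degree = 111.32),
            class = "provenance_calibration")
}

test_that("placement reproduces the hand-worked three-unit example", {
  # units at (0,0), (0,1), (1,0); Delta = (0.1, 0.2, 0.4); a=0, b=5, M=3
  # tie set = {unit1}, origin (0,0), r = 0.5, weights (1, 0.5, 0.25),
  # D = 0.5*(0,1) + 0.25*(1,0) = (0.25, 0.5), |D| = 0.559 > r
  # -> predicted = (0.5/0.559) * D = (0.2236, 0.4472)
  # panel crafted on the 3-simplex so the genetic deltas are exactly
  # 0.1, 0.2, 0.4 from the query
  q <- c(0.5, 0.5, 0)
  delta_target <- c(0.1, 0.2, 0.4)
  u <- c(1, -1, 0) / sqrt(2)               # unit vector within the simplex
  theta <- t(vapply(delta_target, function(d) q + d * u, numeric(3)))
  expect_equal(sqrt(rowSums(sweep(theta, 2, q)^2)), delta_target)
  panel <- toy_panel(theta, lat = c(0, 0, 1), lon = c(0, 1, 0))
  pl <- predict_location(q, panel, flat_cal(0, 5), M = 3)
  expect_equal(pl$delta_min, 0.1)
  expect_equal(pl$radius, 0.5)
  expect_equal(pl$used$weight, c(1, 0.5, 0.25))
  expect_equal(pl$latitude, 0.2236068, tolerance = 1e-6)
  expect_equal(pl$longitude, 0.4472136, tolerance = 1e-6)
})

test_that("placement handles exact matches and ties", {
  theta <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  panel <- toy_panel(theta, lat = c(3, 4, 5), lon = c(30, 40, 50))
  pl <- predict_location(c(0, 1), panel, flat_cal(0.1, 5), M = 3)
  expect_equal(c(pl$latitude, pl$longitude), c(4, 40))   # unique zero match

  # two exact matches at (0,0) and (0,2): predicted at the tie centroid
  panel2 <- toy_panel(rbind(c(1, 0), c(1, 0), c(0, 1)),
                      lat = c(0, 0, 5), lon = c(0, 2, 5))
  pl2 <- predict_location(c(1, 0), panel2, flat_cal(0.1, 5), M = 3)
  expect_equal(c(pl2$latitude, pl2$longitude), c(0, 1))
  expect_setequal(pl2$tie_set, c("u1", "u2"))
  expect_error(predict_location(c(1, 0, 0), panel2, flat_cal(0, 5)), "K")
})

test_that("placement invariants hold across random cases", {
  set.seed(12)
  cal <- flat_cal(0.05, 4, cutoff = 2)
  for (rep in 1:20) {
    K <- sample(3:5, 1); n <- sample(4:8, 1)
    theta <- t(apply(matrix(rgamma(n * K, 1), n), 1, function(x) x / sum(x)))
    panel <- toy_panel(theta, lat = runif(n, 0, 5), lon = runif(n, 0, 5))
    q <- rgamma(K, 1); q <- q / sum(q)
    pl <- predict_location(q, panel, cal, M = 5)
    expect_true(all(pl$used$weight > 0 & pl$used$weight <= 1))
    expect_true(all((pl$used$weight == 1) == (pl$used$unit %in% pl$tie_set)))
    d_origin <- sqrt((pl$latitude - pl$origin[1])^2 +
                       (pl$longitude - pl$origin[2])^2)
    expect_lte(d_origin, pl$radius + 1e-9)

    # invariance under permuting panel units and relabeling components
    pu <- sample(n); pk <- sample(K)
    panel_p <- toy_panel(theta[pu, pk], panel$lat[pu], panel$lon[pu])
    pl_p <- predict_location(q[pk], panel_p, cal, M = 5)
    expect_equal(c(pl_p$latitude, pl_p$longitude),
                 c(pl$latitude, pl$longitude), tolerance = 1e-9)
  }
})

test_that("leave-one-out is exact on degenerate panels and null on shuffles", {
  # every member of a population shares one Q vector and one location
  Q <- rbind(matrix(rep(c(1, 0, 0), 4), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0), 4), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE))
  rownames(Q) <- sprintf("s%02d", 1:12)
  geo <- data.frame(sample_id = rownames(Q),
                    latitude = rep(c(0, 10, 20), each = 4),
                    longitude = rep(c(0, 10, 20), each = 4),
                    country = rep(c("A", "B", "C"), each = 4),
                    population = rep(c("P1", "P2", "P3"), each = 4))
  loo <- loo_cross_validate(Q, geo, flat_cal(0.1, 5, cutoff = 50))
  expect_equal(loo$median_error, 0)
  expect_equal(max(loo$per_sample$error), 0)
  expect_equal(loo$country_accuracy, 1)

  # structure destroyed: accuracy compatible with the 1/4-country chance
  sim <- fix_sim3
  set.seed(33)
  Qs <- sim$q_true[sample(90), ]
  rownames(Qs) <- rownames(sim$q_true)
  genD <- admixture_distance_matrix(sim$q_true)
  geoD <- geographic_distance_matrix(sim$geo)
  cal <- calibrate(genD, geoD, cutoff = stats::quantile(geoD[lower.tri(geoD)], 0.5),
                   n_perm = 99, seed = 1)
  loo_null <- loo_cross_validate(Qs, sim$geo, cal)
  n_countries <- length(unique(sim$geo$country))
  # binomial 99.9% envelope around chance at n = 90
  expect_lt(loo_null$country_accuracy,
            1 / n_countries + 3.3 * sqrt((1 / n_countries) *
                                           (1 - 1 / n_countries) / 90))
  typical <- stats::median(geoD[lower.tri(geoD)])
  expect_gt(loo_null$median_error, 0.25 * typical)
})

test_that("select_k applies the parsimony rule", {
  mk <- function(med, acc) structure(list(median_error = med,
                                          country_accuracy = acc),
                                     class = "loo_summary")
  by_k <- list(`2` = mk(5, 0.5), `4` = mk(1, 0.9), `6` = mk(1.02, 0.88),
               `8` = mk(1.01, 0.89))
  sel <- select_k(by_k)
  expect_equal(sel$K, 4L)                # dominating K
  by_k2 <- list(`6` = mk(1.0, 0.9), `8` = mk(1.0, 0.9))
  expect_equal(select_k(by_k2)$K, 6L)    # tie -> smallest K
  by_k3 <- list(`2` = mk(1.0, 0.2), `4` = mk(2.0, 0.9))
  expect_warning(sel3 <- select_k(by_k3), "no K")
  expect_equal(sel3$K, 2L)
})
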