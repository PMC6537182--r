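# Provenance prediction: convert a sample's admixture vector into a map
# position via its genetic distances to a geo-referenced reference panel
# and an isolation-by-distance calibration line.

KM_PER_DEGREE <- 111.32   # reporting conversion for degree-based distances
EARTH_RADIUS_KM <- 6371

#' Pairwise Euclidean distances between admixture vectors
#'
#' @param Q N x K matrix with rows on the simplex.
#' @return Symmetric N x N matrix with zero diagonal; values lie in
#'   `[0, sqrt(2)]`.
#' @export
admixture_distance_matrix <- function(Q) {
  Q <- as.matrix(Q)
  check_simplex(Q)
  as.matrix(stats::dist(Q))
}

haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Pairwise geographic distances
#'
#' `euclidean-degrees` is the naive Euclidean distance on (latitude,
#' longitude) pairs, adequate at regional scale; `great-circle-km` is the
#' haversine distance on a 6371-km sphere.
#'
#' @param geo data.frame with `latitude` and `longitude` (degrees).
#' @param metric distance metric.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
geographic_distance_matrix <- function(geo,
                                       metric = c("euclidean-degrees",
                                                  "great-circle-km")) {
  metric <- match.arg(metric)
  if (metric == "euclidean-degrees")
    return(as.matrix(stats::dist(cbind(geo$latitude, geo$longitude))))
  n <- nrow(geo)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- haversine_km(geo$latitude[i], geo$longitude[i],
                      geo$latitude[j], geo$longitude[j])
    out[i, j] <- d; out[j, i] <- d
  }
  dimnames(out) <- list(geo$sample_id, geo$sample_id)
  out
}

#' Mantel test of association between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle entries;
#' significance comes from jointly permuting the rows and columns of `D2`,
#' one-sided for positive association:
#' `p = (1 + #permuted r >= observed r) / (n_perm + 1)`.
#'
#' @param D1,D2 conformable symmetric distance matrices (N >= 3).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `r` and `p`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  stopifnot(all(dim(D1) == dim(D2)), n >= 3)
  low <- lower.tri(D1)
  x <- D1[low]
  if (stats::sd(x) == 0 || stats::sd(D2[low]) == 0)
    stop("zero variance in a distance matrix; correlation undefined",
         call. = FALSE)
  r_obs <- stats::cor(x, D2[low])
  ge <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (stats::cor(x, D2[p, p][low]) >= r_obs) count <- count + 1L
    }
    count
  })
  list(r = r_obs, p = (1 + ge) / (n_perm + 1))
}

#' Calibrate the genetic-to-geographic distance conversion
#'
#' Isolation by distance makes geographic and admixture distances linearly
#' related at short range.  This fits `Geo = a + b * Gen` by ordinary
#' least squares over sample pairs closer (geographically) than `cutoff`,
#' and reports Mantel statistics for the full and the distance-restricted
#' matrices.
#'
#' @param genD admixture distance matrix ([admixture_distance_matrix()]).
#' @param geoD geographic distance matrix, same samples and order.
#' @param cutoff geographic distance below which the linear relation is
#'   fitted, in the units of `geoD`.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @param metric tag recording the geographic metric of `geoD`.
#' @param km_per_degree reporting conversion used when `metric` is
#'   `"euclidean-degrees"`.
#'
#' @return Object of class `provenance_calibration`: `intercept`, `slope`,
#'   `cutoff`, `adj_r2`, `mantel_r_all`, `mantel_p_all`,
#'   `mantel_r_filtered`, `mantel_p_filtered`, `n_pairs`, `metric`,
#'   `km_per_degree`.
#' @export
calibrate <- function(genD, geoD, cutoff, n_perm = 999, seed = 1,
                      metric = c("euclidean-degrees", "great-circle-km"),
                      km_per_degree = KM_PER_DEGREE) {
  metric <- match.arg(metric)
  genD <- as.matrix(genD); geoD <- as.matrix(geoD)
  stopifnot(all(dim(genD) == dim(geoD)))
  if (cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  low <- lower.tri(genD)
  keep <- low & geoD < cutoff
  if (sum(keep) < 3)
    stop("fewer than 3 sample pairs below the cutoff", call. = FALSE)

  mt <- mantel_test(geoD, genD, n_perm = n_perm, seed = seed)
  # filtered Mantel: same joint permutation of the genetic matrix, but the
  # correlation is evaluated only over the retained (close) pairs
  x <- geoD[keep]
  r_filt <- stats::cor(x, genD[keep])
  p_filt <- with_seed(child_seed(seed, 1), {
    n <- nrow(genD); count <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (stats::cor(x, genD[p, p][keep]) >= r_filt) count <- count + 1L
    }
    (1 + count) / (n_perm + 1)
  })

  fit <- stats::lm(geo ~ gen, data = data.frame(geo = geoD[keep],
                                                gen = genD[keep]))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 cutoff = cutoff,
                 adj_r2 = summary(fit)$adj.r.squared,
                 mantel_r_all = mt$r, mantel_p_all = mt$p,
                 mantel_r_filtered = r_filt, mantel_p_filtered = p_filt,
                 n_pairs = sum(keep), metric = metric,
                 km_per_degree = km_per_degree),
            class = "provenance_calibration")
}

#' @export
print.provenance_calibration <- function(x, ...) {
  cat(sprintf("Genetic-to-geographic calibration (%s)\n", x$metric))
  cat(sprintf("  Geo = %.4g + %.4g x Gen  (adj r2 = %.3g, %d pairs < %.4g)\n",
              x$intercept, x$slope, x$adj_r2, x$n_pairs, x$cutoff))
  cat(sprintf("  Mantel r (all pairs) = %.3g (p = %.3g); restricted r = %.3g (p = %.3g)\n",
              x$mantel_r_all, x$mantel_p_all,
              x$mantel_r_filtered, x$mantel_p_filtered))
  invisible(x)
}

#' Published Medicago truncatula calibration constants
#'
#' The calibration published for the 262-accession *M. truncatula* panel
#' at K = 8: `Geo = 0.204 + 4.973 x Gen` (adjusted r2 = 0.61), with the
#' linear range restricted to pairs closer than 950 km and Mantel
#' correlations of 0.294 (all pairs) and 0.78 (restricted), both at
#' p = 1e-4.  The regression units are not stated in the source; they are
#' consistent with Euclidean distances on decimal degrees, so the object
#' is tagged `euclidean-degrees` with a 111.32 km/degree reporting factor
#' and the cutoff stored as 950 km converted to degrees.  Treat the unit
#' assignment as inferred.
#'
#' @return A `provenance_calibration` object.
#' @export
mtruncatula_calibration <- function() {
  structure(list(intercept = 0.204, slope = 4.973,
                 cutoff = 950 / KM_PER_DEGREE,
                 adj_r2 = 0.61,
                 mantel_r_all = 0.294, mantel_p_all = 1e-4,
                 mantel_r_filtered = 0.78, mantel_p_filtered = 1e-4,
                 n_pairs = NA_integer_, metric = "euclidean-degrees",
                 km_per_degree = KM_PER_DEGREE),
            class = "provenance_calibration")
}

#' Build a reference panel
#'
#' A panel is the geo-referenced reference set a query is placed against.
#' Units are either individual accessions (one row per sample) or
#' population summaries (mean admixture vector, geographic centroid,
#' majority country, member count).
#'
#' @param Q N x K admixture matrix (rownames = sample ids).
#' @param geo geo table matching `Q`'s samples.
#' @param labels population labels (named vector or two-column
#'   data.frame); defaults to `geo$population`.
#' @param level `"accession"` or `"population"`.
#' @return Object of class `reference_panel`: `theta` (units x K),
#'   `lat`, `lon`, `country`, `population`, `n` (members per unit),
#'   `level`.
#' @export
reference_panel <- function(Q, geo, labels = NULL,
                            level = c("accession", "population")) {
  level <- match.arg(level)
  Q <- as.matrix(Q)
  ids <- rownames(Q) %||% geo$sample_id
  geo <- geo[match(ids, geo$sample_id), , drop = FALSE]
  if (anyNA(geo$latitude)) stop("samples missing from the geo table",
                                call. = FALSE)
  if (level == "accession") {
    panel <- list(theta = Q, lat = geo$latitude, lon = geo$longitude,
                  country = geo$country %||% rep(NA_character_, nrow(Q)),
                  population = geo$population %||% ids,
                  n = rep(1L, nrow(Q)), level = level, unit_ids = ids)
  } else {
    lab <- if (is.null(labels)) {
      stats::setNames(geo$population, ids)
    } else normalize_labels(labels, ids)
    lab <- lab[ids]
    pops <- sort(unique(lab))
    theta <- t(vapply(pops, function(pp) colMeans(Q[lab == pp, , drop = FALSE]),
                      numeric(ncol(Q))))
    majority <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
    panel <- list(theta = theta,
                  lat = unname(vapply(pops, function(pp) mean(geo$latitude[lab == pp]), numeric(1))),
                  lon = unname(vapply(pops, function(pp) mean(geo$longitude[lab == pp]), numeric(1))),
                  country = unname(vapply(pops, function(pp) majority(geo$country[lab == pp]), character(1))),
                  population = pops,
                  n = as.integer(table(lab)[pops]), level = level,
                  unit_ids = pops)
  }
  if (length(panel$unit_ids) < 2) stop("a panel needs >= 2 units", call. = FALSE)
  structure(panel, class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d %s-level units, K = %d\n",
              length(x$unit_ids), x$level, ncol(x$theta)))
  invisible(x)
}

# Geographic displacement coordinates around an origin, in the units of
# the calibration metric (degrees, or km in the local tangent plane).
geo_to_plane <- function(lat, lon, origin, metric) {
  if (metric == "euclidean-degrees")
    return(cbind(x = lat - origin[1], y = lon - origin[2]))
  kmdeg <- EARTH_RADIUS_KM * pi / 180
  cbind(x = (lat - origin[1]) * kmdeg,
        y = (lon - origin[2]) * kmdeg * cos(origin[1] * pi / 180))
}

plane_to_geo <- function(xy, origin, metric) {
  if (metric == "euclidean-degrees")
    return(c(latitude = origin[1] + xy[1], longitude = origin[2] + xy[2]))
  kmdeg <- EARTH_RADIUS_KM * pi / 180
  c(latitude = origin[1] + xy[1] / kmdeg,
    longitude = origin[2] + xy[2] / (kmdeg * cos(origin[1] * pi / 180)))
}

point_distance <- function(lat1, lon1, lat2, lon2, metric) {
  if (metric == "euclidean-degrees")
    sqrt((lat1 - lat2)^2 + (lon1 - lon2)^2)
  else haversine_km(lat1, lon1, lat2, lon2)
}

#' Predict the geographic origin of a sample from its admixture vector
#'
#' The genetic distance from the query to every panel unit is the
#' Euclidean distance between admixture vectors.  All units within a
#' relative tolerance of the smallest distance form the tie set; the
#' placement origin is the geographic centroid of the tie set.  The
#' smallest genetic distance is converted to a geographic radius through
#' the calibration line, and the weighted displacement towards the `M`
#' nearest units (weights `w_m = delta_min / delta_m`, 1 within the tie
#' set) is confined to that radius.
#'
#' @param q admixture vector on the simplex (length K of the panel).
#' @param panel a [reference_panel()].
#' @param cal a `provenance_calibration`.
#' @param M number of nearest units contributing to the displacement
#'   (capped at the panel size).
#' @param tie_tol relative tolerance defining ties; also the absolute
#'   threshold below which the query is placed directly at the tie-set
#'   centroid.
#' @param scale_rule `"clip"` (default) shrinks the displacement only when
#'   it exceeds the radius; `"project"` always rescales it onto the circle.
#'
#' @return Object of class `placement`: predicted `latitude`/`longitude`,
#'   `delta_min`, `tie_set`, `used` (unit, delta, weight), `radius`,
#'   `origin`, `flag` (`"within-calibration-range"` or `"extrapolated"`).
#' @export
predict_location <- function(q, panel, cal, M = 10, tie_tol = 1e-9,
                             scale_rule = c("clip", "project")) {
  scale_rule <- match.arg(scale_rule)
  stopifnot(inherits(panel, "reference_panel"),
            inherits(cal, "provenance_calibration"))
  q <- as.numeric(q)
  if (length(q) != ncol(panel$theta))
    stop("query K does not match the panel", call. = FALSE)
  check_simplex(matrix(q, 1))

  delta <- sqrt(colSums((t(panel$theta) - q)^2))
  dmin <- min(delta)
  tie <- which(delta <= dmin * (1 + tie_tol))
  origin <- c(mean(panel$lat[tie]), mean(panel$lon[tie]))
  radius <- cal$intercept + cal$slope * dmin
  flag <- if (radius > cal$cutoff) "extrapolated" else "within-calibration-range"

  if (dmin <= tie_tol) {
    pred <- c(latitude = origin[1], longitude = origin[2])
    used <- data.frame(unit = panel$unit_ids[tie], delta = delta[tie],
                       weight = 1, stringsAsFactors = FALSE)
  } else {
    Mp <- min(M, length(delta))
    nearest <- order(delta)[seq_len(Mp)]
    w <- dmin / delta
    w[tie] <- 1
    used <- data.frame(unit = panel$unit_ids[nearest], delta = delta[nearest],
                       weight = w[nearest], stringsAsFactors = FALSE)
    contrib <- setdiff(nearest, tie)
    if (length(contrib)) {
      xy <- geo_to_plane(panel$lat[contrib], panel$lon[contrib], origin,
                         cal$metric)
      D <- colSums(w[contrib] * xy)
    } else D <- c(0, 0)
    nD <- sqrt(sum(D^2))
    if (nD == 0) {
      pred <- c(latitude = origin[1], longitude = origin[2])
    } else {
      fac <- if (scale_rule == "clip") min(1, radius / nD) else radius / nD
      pred <- plane_to_geo(fac * D, origin, cal$metric)
    }
  }
  stopifnot(point_distance(pred[1], pred[2], origin[1], origin[2],
                           cal$metric) <= radius + 1e-9)
  structure(list(latitude = unname(pred[1]), longitude = unname(pred[2]),
                 delta_min = dmin, tie_set = panel$unit_ids[tie],
                 used = used, radius = radius, origin = origin,
                 flag = flag),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("Predicted location: (%.4f, %.4f)  [%s]\n",
              x$latitude, x$longitude, x$flag))
  cat(sprintf("  delta_min = %.4g, radius = %.4g, best match: %s\n",
              x$delta_min, x$radius, paste(x$tie_set, collapse = ", ")))
  invisible(x)
}

#' Leave-one-out validation of provenance prediction
#'
#' Each sample is removed in turn and placed against the remaining
#' references.  At `population` level the panel holds population mean
#' admixture vectors and geographic centroids, and the focal sample's own
#' population is replaced by its adjusted mean over the other `n_i - 1`
#' members; singleton populations are skipped with a warning.  At
#' `accession` level the panel is simply all other samples.  A placement
#' counts as the correct country when the country label of the panel unit
#' nearest (great-circle) to the predicted point equals the sample's
#' reported country.
#'
#' @param Q N x K admixture matrix.
#' @param geo matching geo table (needs `country`).
#' @param cal a `provenance_calibration`.
#' @param labels population labels; defaults to `geo$population`.
#' @param level `"population"` (default) or `"accession"`.
#' @param M nearest units used by [predict_location()].
#'
#' @return Object of class `loo_summary`: `per_sample` data.frame
#'   (sample_id, error, correct_country, population), `median_error`,
#'   `country_accuracy`, `per_population` accuracy table, `metric`.
#' @export
loo_cross_validate <- function(Q, geo, cal, labels = NULL,
                               level = c("population", "accession"),
                               M = 10) {
  level <- match.arg(level)
  Q <- as.matrix(Q)
  ids <- rownames(Q) %||% geo$sample_id
  rownames(Q) <- ids
  geo <- geo[match(ids, geo$sample_id), , drop = FALSE]
  lab <- if (is.null(labels)) stats::setNames(geo$population, ids) else
    normalize_labels(labels, ids)[ids]

  if (level == "population") {
    sizes <- table(lab)
    if (all(sizes < 2)) stop("all populations are singletons", call. = FALSE)
    if (any(sizes < 2))
      warning("skipping singleton population(s): ",
              paste(names(sizes)[sizes < 2], collapse = ", "))
    eligible <- ids[lab %in% names(sizes)[sizes >= 2]]
  } else eligible <- ids

  res <- lapply(eligible, function(j) {
    if (level == "population") {
      keep <- setdiff(ids, j)
      panel <- reference_panel(Q[keep, , drop = FALSE],
                               geo[geo$sample_id %in% keep, , drop = FALSE],
                               labels = lab[keep], level = "population")
    } else {
      keep <- setdiff(ids, j)
      panel <- reference_panel(Q[keep, , drop = FALSE],
                               geo[geo$sample_id %in% keep, , drop = FALSE],
                               level = "accession")
    }
    pl <- predict_location(Q[j, ], panel, cal, M = M)
    gj <- geo[geo$sample_id == j, ]
    err <- point_distance(pl$latitude, pl$longitude, gj$latitude,
                          gj$longitude, cal$metric)
    nearest <- which.min(haversine_km(pl$latitude, pl$longitude,
                                      panel$lat, panel$lon))
    data.frame(sample_id = j, error = err,
               correct_country = identical(panel$country[nearest],
                                           gj$country),
               population = unname(lab[j]), stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, res)
  per_pop <- stats::aggregate(correct_country ~ population, per_sample, mean)
  structure(list(per_sample = per_sample,
                 median_error = stats::median(per_sample$error),
                 country_accuracy = mean(per_sample$correct_country),
                 per_population = per_pop, metric = cal$metric,
                 level = level),
            class = "loo_summary")
}

#' @export
print.loo_summary <- function(x, ...) {
  unit <- if (x$metric == "euclidean-degrees") "degrees" else "km"
  cat(sprintf("Leave-one-out provenance validation (%s level, %d samples)\n",
              x$level, nrow(x$per_sample)))
  cat(sprintf("  median error: %.3g %s; correct country: %.1f%%\n",
              x$median_error, unit, 100 * x$country_accuracy))
  invisible(x)
}

#' Select the number of admixture components from geolocation accuracy
#'
#' The most parsimonious optimum: the smallest K whose median
#' leave-one-out error is within `tol` of the global minimum and whose
#' country accuracy is within `tol` of the global maximum.  When no K
#' satisfies both, the argmin of the median error is returned with a
#' warning.
#'
#' @param loo_by_K named list mapping K to [loo_cross_validate()] results.
#' @param tol relative slack on both criteria.
#' @return List with `K` (the selection) and `table` (per-K criteria,
#'   with the pass/fail of each rule).
#' @export
select_k <- function(loo_by_K, tol = 0.05) {
  if (length(loo_by_K) < 2) stop("need >= 2 K values", call. = FALSE)
  Ks <- as.integer(names(loo_by_K))
  med <- vapply(loo_by_K, function(s) s$median_error, numeric(1))
  acc <- vapply(loo_by_K, function(s) s$country_accuracy, numeric(1))
  ok <- med <= (1 + tol) * min(med) & acc >= (1 - tol) * max(acc)
  tab <- data.frame(K = Ks, median_error = med, country_accuracy = acc,
                    admissible = ok)
  if (any(ok)) {
    K_star <- min(Ks[ok])
  } else {
    warning("no K meets both criteria; returning the distance argmin")
    K_star <- Ks[which.min(med)]
  }
  list(K = K_star, table = tab[order(tab$K), ])
}

#' Multi-criteria choice of the number of admixture components
#'
#' The three-step K-determination pipeline: (1) the admixture
#' cross-validation error curve proposes a candidate region (Ks within one
#' standard error of the minimum); (2) a k-means/BIC scan on PCA scores
#' proposes its own region (Ks within one `log(N)` unit of the minimum
#' BIC); (3) for the intersection (falling back to the union if empty)
#' leave-one-out geolocation is run and [select_k()] picks the most
#' parsimonious K that is nearly optimal on both median error and country
#' accuracy.
#'
#' @param G a [genotype_matrix()].
#' @param geo matching geo table with `country` labels.
#' @param K_range candidate K values.
#' @param seed integer seed.
#' @param cutoff calibration cutoff as a quantile of the geographic
#'   distances (default the median).
#' @param n_folds,mask_fraction,max_iter controls passed to
#'   [admixture_cv_error()] and the EM.
#' @param n_perm Mantel permutations inside each per-K calibration.
#' @param M nearest units for placement.
#'
#' @return List with `K` (selection), `cv_curve`, `bic_curve`,
#'   `candidates`, `loo_table`.
#' @export
choose_k <- function(G, geo, K_range, seed = 1, cutoff = 0.5,
                     n_folds = 3, mask_fraction = 0.1, max_iter = 200,
                     n_perm = 99, M = 10) {
  cv <- admixture_cv_error(G, K_range, n_folds = n_folds,
                           mask_fraction = mask_fraction,
                           seed = child_seed(seed, 11), max_iter = max_iter)
  fe <- attr(cv, "fold_errors")
  se_min <- stats::sd(fe[which.min(cv$mean_error), ]) / sqrt(ncol(fe))
  region_cv <- cv$K[cv$mean_error <= min(cv$mean_error) + se_min]

  pcs <- pca_scores(G, n_components = min(20L, nrow(G$dosage) - 1L))
  bic <- suppressWarnings(bic_scan(pcs, K_range, seed = child_seed(seed, 12)))
  region_bic <- bic$K[bic$BIC <= min(bic$BIC) + log(nrow(G$dosage))]

  cand <- intersect(region_cv, region_bic)
  if (!length(cand)) cand <- sort(union(region_cv, region_bic))
  if (length(cand) == 1L)
    return(list(K = cand, cv_curve = cv, bic_curve = bic,
                candidates = cand, loo_table = NULL))

  geoD <- geographic_distance_matrix(geo)
  loo_by_K <- lapply(cand, function(K) {
    fit <- estimate_admixture_unsupervised(G, K, seed = child_seed(seed, K),
                                           max_iter = max_iter)
    lab <- cluster_by_admixture(fit$Q, K)
    genD <- admixture_distance_matrix(fit$Q)
    cal <- calibrate(genD, geoD, cutoff = stats::quantile(geoD[lower.tri(geoD)],
                                                          cutoff),
                     n_perm = n_perm, seed = child_seed(seed, 100 + K))
    loo_cross_validate(fit$Q, geo, cal, labels = lab, M = M)
  })
  names(loo_by_K) <- cand
  sel <- select_k(loo_by_K)
  list(K = sel$K, cv_curve = cv, bic_curve = bic, candidates = cand,
       loo_table = sel$table)
}
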