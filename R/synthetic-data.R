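#' Configuration for a synthetic landscape-genetics dataset
#'
#' Describes a map with `K` ancestral populations anchored at spatially
#' separated centroids.  Samples scatter around their population centroid;
#' their true admixture proportions decay with distance to every centroid,
#' so the landscape shows isolation by distance — the precondition for
#' admixture-based geolocation.  Allele frequencies of the ancestral
#' populations follow the Balding-Nichols model around a common ancestral
#' frequency, with differentiation controlled by `fst_f`.
#'
#' @param K number of ancestral populations (>= 1).
#' @param n_per_pop samples per population.
#' @param lat_range,lon_range map bounds in decimal degrees.  Defaults span
#'   a Mediterranean-basin-sized box.
#' @param decay_rho admixture distance-decay scale in degrees: the true
#'   proportion of component k in a sample at distance d from centroid k is
#'   proportional to `exp(-d / decay_rho)`.  Small values give nearly pure
#'   populations.
#' @param dirichlet_conc concentration of the per-sample Dirichlet noise
#'   around the distance-decay proportions; larger is less noisy.
#' @param fst_f Balding-Nichols differentiation parameter, in (0, 1).
#' @param n_loci number of independent loci to simulate.
#' @param pop_sd standard deviation, in degrees, of the Gaussian scatter of
#'   sample locations around their population centroid.  Defaults to
#'   `decay_rho` so geographic and genetic scales match.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#'
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(K = 4, n_per_pop = 50,
                             lat_range = c(30, 45), lon_range = c(-10, 25),
                             decay_rho = 2, dirichlet_conc = 100,
                             fst_f = 0.15, n_loci = 1000,
                             pop_sd = decay_rho, seed = 1) {
  K <- check_count(K, "K")
  n_per_pop <- check_count(n_per_pop, "n_per_pop")
  n_loci <- check_count(n_loci, "n_loci")
  check_fraction(fst_f, "fst_f", open = TRUE)
  if (!is.numeric(decay_rho) || decay_rho <= 0)
    stop("`decay_rho` must be > 0", call. = FALSE)
  if (!is.numeric(pop_sd) || pop_sd < 0)
    stop("`pop_sd` must be >= 0", call. = FALSE)
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0)
    stop("map ranges must be increasing (min, max) pairs", call. = FALSE)
  structure(list(K = K, n_per_pop = n_per_pop, lat_range = lat_range,
                 lon_range = lon_range, decay_rho = decay_rho,
                 dirichlet_conc = dirichlet_conc, fst_f = fst_f,
                 n_loci = n_loci, pop_sd = pop_sd, seed = seed),
            class = "landscape_config")
}

# One Dirichlet draw; zero shapes give exact zeros (gamma(0) point mass),
# so in the decay_rho -> 0 limit samples become purebred.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {            # all shapes ~ 0: fall back to the dominant class
    out <- numeric(length(alpha))
    out[which.max(alpha)] <- 1
    return(out)
  }
  g / s
}

#' Place ancestral populations on a map and draw sample locations and
#' true admixture proportions
#'
#' @param config a [landscape_config()].
#' @param max_tries redraws allowed before a landscape with centroids
#'   closer than 5\% of the map diagonal is declared degenerate.
#'
#' @return A list with `geo` (data.frame: sample_id, latitude, longitude,
#'   country, population), `q_true` (N x K matrix, rows on the simplex),
#'   and `centroids` (K x 2 matrix of latitude/longitude).  Country labels
#'   are the Voronoi cell (nearest centroid) of each sample's location, so
#'   "correct country" is well defined on the synthetic map.
#' @export
make_landscape <- function(config, max_tries = 200) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    K <- config$K
    diag_len <- sqrt(diff(config$lat_range)^2 + diff(config$lon_range)^2)
    min_sep <- 0.05 * diag_len
    cent <- NULL
    for (try in seq_len(max_tries)) {
      cand <- cbind(lat = stats::runif(K, config$lat_range[1], config$lat_range[2]),
                    lon = stats::runif(K, config$lon_range[1], config$lon_range[2]))
      if (K == 1L || min(stats::dist(cand)) > min_sep) { cent <- cand; break }
    }
    if (is.null(cent))
      stop("degenerate landscape: could not place ", K,
           " centroids separated by ", signif(min_sep, 3), " degrees",
           call. = FALSE)

    N <- K * config$n_per_pop
    pop <- rep(seq_len(K), each = config$n_per_pop)
    lat <- cent[pop, 1] + stats::rnorm(N, 0, config$pop_sd)
    lon <- cent[pop, 2] + stats::rnorm(N, 0, config$pop_sd)

    # distance-decay admixture + Dirichlet sampling noise
    d <- sqrt(outer(lat, cent[, 1], "-")^2 + outer(lon, cent[, 2], "-")^2)
    q_raw <- exp(-d / config$decay_rho)
    q_raw <- q_raw / rowSums(q_raw)
    q_true <- t(apply(q_raw, 1L, function(w) rdirichlet1(config$dirichlet_conc * w)))
    if (K == 1L) q_true <- matrix(1, N, 1)

    ids <- sprintf("S%03d", seq_len(N))
    rownames(q_true) <- ids
    colnames(q_true) <- sprintf("K%d", seq_len(K))
    nearest <- apply(sqrt(outer(lat, cent[, 1], "-")^2 +
                            outer(lon, cent[, 2], "-")^2), 1L, which.min)
    geo <- data.frame(sample_id = ids, latitude = lat, longitude = lon,
                      country = sprintf("C%d", nearest),
                      population = sprintf("P%d", pop),
                      stringsAsFactors = FALSE)
    list(geo = geo, q_true = q_true, centroids = cent)
  })
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Each locus has a common ancestral frequency `p_j ~ Uniform(0.05, 0.95)`;
#' each ancestral population draws its own frequency
#' `f_kj ~ Beta(p_j (1 - F) / F, (1 - p_j)(1 - F) / F)` with differentiation
#' parameter `F = fst_f`; each sample's dosage at locus j is
#' `Binomial(2, sum_k q_ik f_kj)`.
#'
#' @param q_true N x K matrix of true admixture proportions (rows on the
#'   simplex).
#' @param n_loci number of independent loci.
#' @param fst_f differentiation parameter in (0, 1).
#' @param seed integer seed.
#'
#' @return A list with `genotypes` (a [genotype_matrix()] of 0/1/2 dosages)
#'   and `freqs_true` (K x M matrix of ancestral allele frequencies).
#' @export
simulate_genotypes <- function(q_true, n_loci, fst_f, seed = 1) {
  check_fraction(fst_f, "fst_f", open = TRUE)
  n_loci <- check_count(n_loci, "n_loci")
  q_true <- as.matrix(q_true)
  check_simplex(q_true)
  with_seed(seed, {
    K <- ncol(q_true); N <- nrow(q_true)
    p <- stats::runif(n_loci, 0.05, 0.95)
    a <- p * (1 - fst_f) / fst_f
    b <- (1 - p) * (1 - fst_f) / fst_f
    F <- matrix(stats::rbeta(K * n_loci, rep(a, each = K), rep(b, each = K)),
                nrow = K)
    P <- q_true %*% F
    G <- matrix(stats::rbinom(N * n_loci, 2L, pmin(pmax(P, 0), 1)), nrow = N)
    ids <- rownames(q_true) %||% sprintf("S%03d", seq_len(N))
    vids <- sprintf("snp%05d", seq_len(n_loci))
    rownames(F) <- colnames(q_true) %||% sprintf("K%d", seq_len(K))
    colnames(F) <- vids
    list(genotypes = genotype_matrix(G, sample_ids = ids, variant_ids = vids),
         freqs_true = F)
  })
}

#' Simulate a trait linear in the true admixture proportions
#'
#' `y_i = beta[1] + sum_k beta[k + 1] * q_ik + Normal(0, sigma^2)`.
#'
#' @param q_true N x K admixture matrix.
#' @param beta coefficient vector of length K + 1, intercept first.
#' @param sigma residual standard deviation (>= 0).
#' @param seed integer seed.
#' @param trait name for the trait column.
#'
#' @return A data.frame with columns `sample_id` and the trait.
#' @export
simulate_trait <- function(q_true, beta, sigma = 0.5, seed = 1,
                           trait = "trait") {
  q_true <- as.matrix(q_true)
  if (length(beta) != ncol(q_true) + 1L)
    stop("`beta` must have length K + 1 (intercept first)", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be >= 0", call. = FALSE)
  with_seed(seed, {
    y <- beta[1] + drop(q_true %*% beta[-1]) +
      stats::rnorm(nrow(q_true), 0, sigma)
    out <- data.frame(sample_id = rownames(q_true) %||%
                        sprintf("S%03d", seq_len(nrow(q_true))),
                      y, stringsAsFactors = FALSE)
    names(out)[2] <- trait
    out
  })
}

#' Simulate spatially structured environmental variables
#'
#' Each variable is an affine function of latitude and longitude plus a
#' smooth low-order interaction term and Gaussian noise, emulating
#' bioclimatic layers extracted at the sample locations.  The final column,
#' `env_null`, is pure noise and serves as a negative control for
#' association tests.
#'
#' @param geo a geo table (needs `sample_id`, `latitude`, `longitude`).
#' @param n_vars number of variables to produce (including the null
#'   control), default 19 as in typical bioclim panels.
#' @param seed integer seed.
#' @param noise_sd residual noise standard deviation (on the scale of the
#'   standardized coordinates).
#' @param degree 2 (default) includes the smooth lat x lon interaction
#'   term; 1 keeps the variables exactly affine in (lat, lon) apart from
#'   the noise.
#'
#' @return A data.frame: `sample_id`, `env1` ... and `env_null`.
#' @export
simulate_environment <- function(geo, n_vars = 19, seed = 1,
                                 noise_sd = 0.3, degree = 2) {
  if (nrow(geo) == 0) stop("`geo` is empty", call. = FALSE)
  n_vars <- check_count(n_vars, "n_vars")
  with_seed(seed, {
    la <- scale(geo$latitude)[, 1]
    lo <- scale(geo$longitude)[, 1]
    n <- nrow(geo)
    out <- matrix(NA_real_, n, n_vars)
    for (v in seq_len(n_vars)) {
      if (v == n_vars) {                       # null control: pure noise
        out[, v] <- stats::rnorm(n)
      } else {
        a <- stats::rnorm(1); b <- stats::rnorm(1)
        cc <- if (degree >= 2) stats::rnorm(1, 0, 0.5) else 0
        out[, v] <- a * la + b * lo + cc * la * lo + stats::rnorm(n, 0, noise_sd)
      }
    }
    colnames(out) <- c(sprintf("env%d", seq_len(n_vars - 1L)), "env_null")
    data.frame(sample_id = geo$sample_id, out, stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_landscape()], [simulate_genotypes()], [simulate_trait()] and
#' [simulate_environment()] with seeds derived from `config$seed`, so one
#' integer determines the whole dataset.
#'
#' @param config a [landscape_config()].
#' @param beta trait coefficients (length K + 1); default gives the trait a
#'   strong dependence on the first two components.
#' @param sigma trait noise standard deviation.
#' @param n_env number of environmental variables.
#'
#' @return A list of class `whogem_sim` with elements `genotypes`,
#'   `q_true`, `freqs_true`, `geo`, `traits`, `env`, `centroids`, `config`.
#' @export
simulate_dataset <- function(config = landscape_config(), beta = NULL,
                             sigma = 0.5, n_env = 19) {
  land <- make_landscape(config)
  gen <- simulate_genotypes(land$q_true, config$n_loci, config$fst_f,
                            seed = child_seed(config$seed, 1))
  if (is.null(beta)) beta <- c(2, 3, -2, rep(0, config$K - 2L))
  traits <- simulate_trait(land$q_true, beta, sigma,
                           seed = child_seed(config$seed, 2))
  env <- simulate_environment(land$geo, n_env,
                              seed = child_seed(config$seed, 3))
  structure(list(genotypes = gen$genotypes, q_true = land$q_true,
                 freqs_true = gen$freqs_true, geo = land$geo,
                 traits = traits, env = env, centroids = land$centroids,
                 config = config),
            class = "whogem_sim")
}

#' @export
print.whogem_sim <- function(x, ...) {
  cat(sprintf("Synthetic landscape dataset: %d samples, %d populations, %d loci\n",
              nrow(x$q_true), x$config$K, ncol(x$genotypes$dosage)))
  cat(sprintf("  fst_f = %.3g, decay_rho = %.3g deg, seed = %s\n",
              x$config$fst_f, x$config$decay_rho, format(x$config$seed)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Genotypes go to a dosage TSV, the true Q matrix to ADMIXTURE-style
#' `.Q` / `.id` files, and the geo/trait/environment tables to CSV.
#'
#' @param sim a `whogem_sim` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "whogem_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genotypes = file.path(dir, "genotypes.tsv"),
             q = file.path(dir, "q_true.Q"),
             geo = file.path(dir, "geo.csv"),
             traits = file.path(dir, "traits.csv"),
             env = file.path(dir, "env.csv"))
  write_genotypes(sim$genotypes, files["genotypes"])
  write_q_matrix(sim$q_true, files["q"])
  utils::write.csv(sim$geo, files["geo"], row.names = FALSE)
  utils::write.csv(sim$traits, files["traits"], row.names = FALSE)
  utils::write.csv(sim$env, files["env"], row.names = FALSE)
  invisible(files)
}
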