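# Shared fixtures (built once per run) and independent oracles used to
# freeze expected values.

# a small, well-differentiated 3-population landscape reused across files
fix_sim3 <- simulate_dataset(
  landscape_config(K = 3, n_per_pop = 30, n_loci = 300, fst_f = 0.25,
                   decay_rho = 1, seed = 5),
  beta = c(2, 3, -1, 0), sigma = 0.2)

fix_labels3 <- stats::setNames(fix_sim3$geo$population, fix_sim3$geo$sample_id)

# minimal biallelic VCF text for parser tests
make_vcf_text <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB\tsampC",
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t./.\t1|1\t0/0",
    "chr2\t50\tv3\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/1")
}

# brute-force UPGMA (average linkage) oracle: returns sorted merge heights
upgma_heights_oracle <- function(X) {
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# rank-formula Kruskal-Wallis oracle with tie correction
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# direct VIF of column j of X regressed on the others
vif_oracle <- function(X, j) {
  fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
  1 / (1 - summary(fit)$r.squared)
}
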