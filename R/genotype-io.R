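#' Construct a genotype matrix of allelic dosages
#'
#' @param dosage N x M numeric matrix with entries in \{0, 1, 2, NA\}
#'   counting copies of the alternate allele.
#' @param sample_ids,variant_ids unique identifiers; taken from dimnames
#'   when omitted.
#' @param chrom,pos optional per-variant metadata (1-based positions).
#'
#' @return An object of class `genotype_matrix`: a list with `dosage`
#'   (dimnamed matrix), `chrom`, `pos`.
#' @export
genotype_matrix <- function(dosage, sample_ids = NULL, variant_ids = NULL,
                            chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  sample_ids <- sample_ids %||% rownames(dosage) %||%
    sprintf("S%03d", seq_len(nrow(dosage)))
  variant_ids <- variant_ids %||% colnames(dosage) %||%
    sprintf("snp%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids", call. = FALSE)
  if (length(sample_ids) != nrow(dosage) || length(variant_ids) != ncol(dosage))
    stop("id lengths do not match the dosage matrix", call. = FALSE)
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or missing", call. = FALSE)
  dimnames(dosage) <- list(sample_ids, variant_ids)
  structure(list(dosage = dosage, chrom = chrom, pos = pos),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from a VCF or a dosage TSV
#'
#' VCF input (v4.x, biallelic SNP records, diploid GT) is converted to
#' alternate-allele dosage: `0/0` -> 0, `0/1` -> 1, `1/1` -> 2, missing
#' (`./.`) -> NA.  A dosage TSV has a header of variant ids, then one row
#' per sample with the sample id in the first column.
#'
#' @param path path to a `.vcf` file or a tab-separated dosage file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) read_vcf_dosage(path)
  else read_dosage_tsv(path)
}

read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  # gt: variants x samples character matrix
  clean <- gsub("\\|", "/", gt)
  bad <- !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    ploidy_bad <- !grepl("^[.0-9]+(/[.0-9]+)?$", clean) |
      lengths(regmatches(clean, gregexpr("/", clean))) != 1L
    if (any(ploidy_bad))
      stop("non-diploid GT for sample ", colnames(gt)[idx[2L]],
           " at record ", rownames(gt)[idx[1L]], call. = FALSE)
    stop("unsupported (non-biallelic?) GT '", gt[idx[1L], idx[2L]],
         "' for sample ", colnames(gt)[idx[2L]], call. = FALSE)
  }
  dose <- matrix(NA_real_, nrow(gt), ncol(gt))
  dose[clean == "0/0"] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean == "1/1"] <- 2
  rr <- SummarizedExperiment::rowRanges(vcf)
  genotype_matrix(t(dose), sample_ids = colnames(gt),
                  variant_ids = rownames(gt),
                  chrom = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr))
}

read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "."))
  ids <- as.character(dt[[1L]])
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.na(mat) & !(mat %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed dosage at line %d (sample %s): value %s",
                 bad[1L, 1L] + 1L, ids[bad[1L, 1L]],
                 format(mat[bad[1L, , drop = FALSE]])), call. = FALSE)
  genotype_matrix(mat, sample_ids = ids, variant_ids = colnames(mat))
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  dt <- data.table::data.table(sample_id = rownames(G$dosage))
  dt <- cbind(dt, data.table::as.data.table(G$dosage))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Remove variants with too much missingness or too low frequency
#'
#' Mirrors the conventional `--geno 0.05 --maf 0.01` quality filters:
#' variants whose missing-call fraction exceeds `max_missing` or whose
#' minor-allele frequency (computed from non-missing dosages) falls below
#' `min_maf` are dropped; variant order is preserved.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing maximum tolerated missing-call fraction.
#' @param min_maf minimum minor-allele frequency.
#' @return The filtered [genotype_matrix()].
#' @export
quality_filter <- function(G, max_missing = 0.05, min_maf = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"))
  check_fraction(max_missing, "max_missing")
  check_fraction(min_maf, "min_maf")
  X <- G$dosage
  miss <- colMeans(is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  p[!is.finite(p)] <- 0
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep)) warning("no variants pass the quality filters")
  subset_variants(G, which(keep))
}

subset_variants <- function(G, idx) {
  genotype_matrix(G$dosage[, idx, drop = FALSE],
                  sample_ids = rownames(G$dosage),
                  variant_ids = colnames(G$dosage)[idx],
                  chrom = G$chrom[idx], pos = G$pos[idx])
}

# Variance inflation factors of the columns of a (mean-imputed) dosage
# block: VIF_j = 1 / (1 - R^2 of column j on the others) = diag(inv(R))
# for the correlation matrix R.  Exactly collinear columns get +Inf.
block_vif <- function(X) {
  keep <- apply(X, 2L, stats::sd) > 0
  vif <- rep(1, ncol(X))
  if (sum(keep) < 2L) return(vif)
  R <- stats::cor(X[, keep, drop = FALSE])
  inv <- tryCatch(chol2inv(chol(R)), error = function(e) NULL)
  if (is.null(inv)) {
    # singular: flag members of perfectly correlated pairs as infinite
    v <- rep(1, sum(keep))
    perfect <- which(abs(R) > 1 - 1e-10 & upper.tri(R), arr.ind = TRUE)
    v[unique(c(perfect))] <- Inf
    if (!length(perfect)) {
      inv <- solve(R + diag(1e-8, nrow(R)))
      v <- diag(inv)
    }
    vif[keep] <- v
  } else {
    vif[keep] <- diag(inv)
  }
  vif
}

#' Prune variants in linkage disequilibrium by variance inflation factor
#'
#' Greedy VIF-based pruning in sliding windows, in the spirit of the
#' `--indep <window> <step> <vif>` approach: within each window of
#' `window` surviving variants, the variant with the largest VIF (computed
#' from mean-imputed dosages) is removed, worst first, until all VIFs fall
#' below `vif_threshold`; windows advance by `step` variants and removals
#' are global.  Passes repeat until a full sweep removes nothing, which
#' guarantees the post-condition that every window of the surviving set has
#' maximum VIF below the threshold.  Exactly duplicated columns have
#' infinite VIF; the lowest-index copy is kept.
#'
#' @param G a [genotype_matrix()].
#' @param window window size in variants (>= 2).
#' @param step window step in variants.
#' @param vif_threshold VIF above which a variant is removed (> 1).
#' @return The pruned [genotype_matrix()].
#' @export
ld_prune <- function(G, window = 300, step = 60, vif_threshold = 1.3) {
  stopifnot(inherits(G, "genotype_matrix"))
  window <- check_count(window, "window", min = 2)
  step <- check_count(step, "step", min = 1)
  if (step > window) stop("`step` must be <= `window`", call. = FALSE)
  if (vif_threshold <= 1) stop("`vif_threshold` must be > 1", call. = FALSE)

  X <- impute_mean(G$dosage)$X
  alive <- seq_len(ncol(X))
  repeat {
    removed_this_pass <- FALSE
    start <- 1L
    while (start <= length(alive)) {
      win <- alive[start:min(start + window - 1L, length(alive))]
      if (length(win) >= 2L) {
        repeat {
          vif <- block_vif(X[, win, drop = FALSE])
          worst <- max(vif)
          if (worst < vif_threshold) break
          # ties / duplicates: drop the highest-index worst column so the
          # lowest-index copy survives
          drop_local <- max(which(vif == worst))
          drop_global <- win[drop_local]
          win <- setdiff(win, drop_global)
          alive <- setdiff(alive, drop_global)
          removed_this_pass <- TRUE
          if (length(win) < 2L) break
        }
      }
      start <- start + step
    }
    if (!removed_this_pass) break
  }
  subset_variants(G, alive)
}

#' Read / write ADMIXTURE-style Q matrices
#'
#' `.Q` files are whitespace-separated proportions, one row per individual,
#' no header; sample ids come from a companion `.id` file (same basename)
#' when present, or can be passed explicitly.  Rows must sum to 1 within
#' `1e-6` and are renormalized exactly on read.
#'
#' @param path path to the `.Q` file.
#' @param ids optional character vector of sample ids, overriding the
#'   companion `.id` file.
#' @return A numeric matrix with sample ids as rownames and components
#'   `K1..Kk` as colnames.
#' @export
read_q_matrix <- function(path, ids = NULL) {
  Q <- as.matrix(utils::read.table(path, header = FALSE))
  storage.mode(Q) <- "double"
  if (any(Q < 0 | Q > 1))
    stop("Q entries must lie in [0, 1]", call. = FALSE)
  dev <- abs(rowSums(Q) - 1)
  if (any(dev > 1e-6))
    stop(sprintf("Q row %d sums to %.8f, not 1", which.max(dev),
                 rowSums(Q)[which.max(dev)]), call. = FALSE)
  Q <- Q / rowSums(Q)
  idfile <- sub("\\.Q$", ".id", path)
  if (is.null(ids) && idfile != path && file.exists(idfile))
    ids <- readLines(idfile)
  rownames(Q) <- ids %||% sprintf("S%03d", seq_len(nrow(Q)))
  colnames(Q) <- sprintf("K%d", seq_len(ncol(Q)))
  Q
}

#' @rdname read_q_matrix
#' @param Q N x K matrix of proportions, rows on the simplex.
#' @param digits decimal places written.
#' @export
write_q_matrix <- function(Q, path, digits = 6) {
  check_simplex(as.matrix(Q))
  utils::write.table(format(round(as.matrix(Q), digits), nsmall = digits),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  idfile <- sub("\\.Q$", ".id", path)
  if (idfile != path)
    writeLines(rownames(Q) %||% sprintf("S%03d", seq_len(nrow(Q))), idfile)
  invisible(path)
}

#' Read a per-sample geographic table
#'
#' CSV with header `sample_id,latitude,longitude[,country][,population]`.
#' Coordinates are validated against the usual degree ranges.
#'
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_geo_table <- function(path) {
  geo <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "latitude", "longitude")
  if (!all(req %in% names(geo)))
    stop("geo table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(geo$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (any(abs(geo$latitude) > 90) || any(abs(geo$longitude) > 180))
    stop("coordinates out of range", call. = FALSE)
  geo
}
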