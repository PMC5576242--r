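#' Compute a genomic relationship matrix
#'
#' `G[j, k] = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the `m` polymorphic SNPs. Missing genotypes are mean-imputed to
#' `2 p_i` before standardization. Monomorphic SNPs (under the frequencies in
#' use) are skipped and `m` adjusted. With in-sample frequencies every row of
#' `G` sums to zero by the centering identity.
#'
#' @param dataset A [genotype_dataset()].
#' @param freqs Optional per-SNP A1 frequencies (e.g. from a training fold);
#'   defaults to in-sample frequencies.
#' @return A list of class `grm_matrix`: `values` (n x n), `ids`, `m_used`,
#'   `freq_source` ("in-sample" or "supplied").
#' @export
compute_grm <- function(dataset, freqs = NULL) {
  supplied <- !is.null(freqs)
  p <- if (supplied) freqs else allele_freq(dataset)
  if (length(p) != n_snps(dataset)) stop("freqs length must match SNP count")
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM undefined")
  Z <- standardize_dosage(dataset$dosage[, poly, drop = FALSE], p[poly])
  m <- sum(poly)
  G <- tcrossprod(Z) / m
  structure(list(values = G, ids = sample_ids(dataset), m_used = m,
                 freq_source = if (supplied) "supplied" else "in-sample"),
            class = "grm_matrix")
}

#' @export
print.grm_matrix <- function(x, ...) {
  cat("grm_matrix:", length(x$ids), "samples,", x$m_used,
      "SNPs,", x$freq_source, "frequencies\n")
  invisible(x)
}

#' Effective number of independent markers
#'
#' `Me = 1 / Var(G[j, k], j < k)`: the reciprocal of the unbiased sample
#' variance of the off-diagonal genomic relationships. For an unrelated,
#' homogeneous sample this estimates the number of quasi-linkage-equilibrium
#' markers; it is invariant to duplicating SNP columns. Invalid for samples
#' containing relatives or strong structure (the off-diagonal variance is
#' then dominated by kinship, not marker sampling).
#'
#' @param grm A [compute_grm()] result.
#' @return The effective marker count (positive real).
#' @export
effective_marker_count <- function(grm) {
  off <- grm$values[upper.tri(grm$values)]
  if (length(off) < 2) stop("need at least 3 samples")
  v <- stats::var(off)
  if (v <= 0) stop("off-diagonal variance is zero; Me undefined")
  1 / v
}

#' Principal components of a reference panel
#'
#' Standardizes the reference by its own allele frequencies and extracts the
#' top-`k` right singular vectors as SNP loadings. Reference PC scores are
#' defined as `Z %*% loadings` so that projecting the panel onto itself
#' reproduces them exactly.
#'
#' @param reference A [genotype_dataset()] (the reference panel).
#' @param k Number of components (default 10).
#' @return A list of class `eigen_projection`: `k`, `snp_ids`, `loadings`
#'   (m x k), `freqs` (reference A1 frequencies), `d` (singular values),
#'   `eigenvalues`, `scores` (reference coordinates, n x k).
#' @export
reference_pca <- function(reference, k = 10) {
  p <- allele_freq(reference)
  poly <- !is.na(p) & p > 0 & p < 1
  Z <- standardize_dosage(reference$dosage[, poly, drop = FALSE], p[poly])
  r <- min(dim(Z))
  if (k > r) stop("k = ", k, " exceeds the rank bound ", r, " of the reference")
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- sample_ids(reference)
  structure(list(k = k, snp_ids = reference$snps$id[poly],
                 loadings = sv$v, freqs = p[poly], d = sv$d[seq_len(k)],
                 eigenvalues = sv$d[seq_len(k)]^2 / (nrow(Z) - 1),
                 scores = scores),
            class = "eigen_projection")
}

#' Project study samples onto reference principal components
#'
#' Standardizes the study genotypes with the reference allele frequencies and
#' multiplies by the reference SNP loadings. Samples from the reference panel
#' itself project onto their own PCA scores.
#'
#' @param proj An [reference_pca()] result.
#' @param dataset Study [genotype_dataset()].
#' @param min_overlap Minimum fraction of loading SNPs that must be present
#'   in the study dataset (default 0.8).
#' @return Numeric matrix of projected coordinates (samples x k), rownames
#'   are sample ids.
#' @export
project_samples <- function(proj, dataset, min_overlap = 0.8) {
  idx <- match(proj$snp_ids, dataset$snps$id)
  frac <- mean(!is.na(idx))
  if (frac < min_overlap) {
    stop(sprintf("only %.1f%% of projection SNPs found in dataset (need %.0f%%)",
                 100 * frac, 100 * min_overlap))
  }
  keep <- !is.na(idx)
  Z <- standardize_dosage(dataset$dosage[, idx[keep], drop = FALSE],
                          proj$freqs[keep])
  coords <- Z %*% proj$loadings[keep, , drop = FALSE]
  rownames(coords) <- sample_ids(dataset)
  colnames(coords) <- paste0("PC", seq_len(proj$k))
  coords
}

#' Ancestry-adjust a phenotype by regression on projected eigenvectors
#'
#' Regresses the 0/1 disease status (ordinary least squares, intercept
#' included) on the top-`k` projected coordinates and stores the residual in
#' the `adjusted` column; downstream linear predictors (GBLUP, BayesR,
#' linear association) can then be trained on the residual scale.
#' Collinear coordinates are dropped with a warning. Residuals are orthogonal
#' to every retained coordinate; re-adjusting is a no-op.
#'
#' @param y A `phenotype_table` with a `status` column.
#' @param coords Coordinate matrix from [project_samples()], rownames
#'   `fid:iid`.
#' @param k Number of leading coordinates to use (default all supplied, up
#'   to 10).
#' @return The phenotype table with `adjusted` filled in.
#' @export
adjust_phenotype <- function(y, coords, k = min(10, ncol(coords))) {
  if (k > ncol(coords)) stop("k exceeds available components")
  key <- paste(y$fid, y$iid, sep = ":")
  idx <- match(key, rownames(coords))
  if (anyNA(idx)) stop("coordinates missing for some phenotype samples")
  X <- coords[idx, seq_len(k), drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    warning("dropping ", ncol(X) + 1 - qrX$rank, " collinear coordinate(s)")
  }
  y$adjusted <- qr.resid(qrX, y$status)
  y
}
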