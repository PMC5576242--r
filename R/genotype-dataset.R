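#' Construct a genotype dataset
#'
#' The central genotype container: an n x m dosage matrix (counts of the A1
#' effect allele, 0/1/2, `NA` for missing) with per-SNP metadata and
#' per-sample identifiers. All pipeline stages consume and return this class.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns. Entries
#'   must be 0, 1, 2 or `NA`.
#' @param snps `data.frame` with one row per SNP: columns `id`, `chr`, `pos`,
#'   `a1` (effect allele, the counted one), `a2`, and optionally `info`
#'   (imputation quality in (0, 1]).
#' @param samples `data.frame` with columns `fid` and `iid`; `fid:iid` pairs
#'   must be unique. Optional extra columns (e.g. `subpop`) are carried along.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(is.numeric(dosage))
  if (ncol(dosage) != nrow(snps)) {
    stop("dosage has ", ncol(dosage), " columns but snps has ", nrow(snps), " rows")
  }
  if (nrow(dosage) != nrow(samples)) {
    stop("dosage has ", nrow(dosage), " rows but samples has ", nrow(samples), " rows")
  }
  need <- c("id", "chr", "pos", "a1", "a2")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("snps lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(c("fid", "iid") %in% names(samples))) stop("samples needs fid and iid columns")
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids")
  key <- paste(samples$fid, samples$iid, sep = ":")
  if (anyDuplicated(key)) stop("duplicate sample ids (fid:iid)")
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(key, snps$id)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", n_samples(x), "samples x", n_snps(x), "SNPs\n")
  nmiss <- sum(is.na(x$dosage))
  cat("  missing genotypes:", nmiss,
      sprintf("(%.3f%%)", 100 * nmiss / length(x$dosage)), "\n")
  if (!is.null(x$snps$info)) cat("  INFO scores present\n")
  invisible(x)
}

#' Number of samples / SNPs in a genotype dataset
#' @param x A `genotype_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$dosage)

#' Sample identifiers (`fid:iid`) of a genotype dataset
#' @param x A `genotype_dataset`.
#' @return Character vector.
#' @export
sample_ids <- function(x) paste(x$samples$fid, x$samples$iid, sep = ":")

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param samples Optional sample selector: logical/integer index into rows,
#'   or character `fid:iid` keys.
#' @param snps Optional SNP selector: logical/integer index or SNP ids.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, snps = NULL) {
  si <- seq_len(n_samples(x))
  vi <- seq_len(n_snps(x))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, sample_ids(x)) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s) in subset")
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, x$snps$id) else vi[snps]
    if (anyNA(vi)) stop("unknown SNP id(s) in subset")
  }
  genotype_dataset(x$dosage[si, vi, drop = FALSE],
                   x$snps[vi, , drop = FALSE],
                   x$samples[si, , drop = FALSE])
}

#' Per-SNP A1 allele frequency
#'
#' Computed on non-missing genotypes of the current sample set.
#'
#' @param x A `genotype_dataset`.
#' @return Numeric vector, one frequency per SNP (of the counted A1 allele).
#' @export
allele_freq <- function(x) {
  colMeans(x$dosage, na.rm = TRUE) / 2
}

#' Standardize a dosage matrix
#'
#' Centers each SNP at twice the allele frequency and scales by
#' `sqrt(2 p (1 - p))`; missing dosages are mean-imputed (to `2p`) before
#' standardization, so missing entries become exact zeros. SNPs with
#' `p(1 - p) = 0` under the supplied frequencies yield all-zero columns.
#'
#' @param dosage Numeric dosage matrix (0/1/2/NA).
#' @param p Per-SNP A1 allele frequencies used for centering and scaling
#'   (training-fold or reference frequencies to avoid leakage).
#' @return Numeric matrix of the same shape.
#' @keywords internal
standardize_dosage <- function(dosage, p) {
  stopifnot(length(p) == ncol(dosage))
  sd <- sqrt(2 * p * (1 - p))
  Z <- sweep(dosage, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  ok <- sd > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sd[ok], "/")
  Z[, !ok] <- 0
  Z
}
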