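#' Quality-control thresholds
#'
#' Defaults follow common GWAS practice for imputed array data: drop SNPs
#' with imputation INFO below 0.6 or minor allele frequency below 0.01,
#' Hardy-Weinberg exact p below 1e-6, palindromic (A/T, G/C) allele pairs,
#' samples with more than 2% missing genotypes, and one member of each pair
#' related above 0.2 on the genomic relationship scale. For dense custom
#' arrays a lower MAF floor (0.001) is conventional; set `min_maf`
#' accordingly.
#'
#' @param min_info INFO-score floor (filter skipped with a warning when the
#'   dataset carries no INFO metadata).
#' @param min_maf Minor-allele-frequency floor.
#' @param hwe_p_floor Hardy-Weinberg exact-test p-value floor.
#' @param max_sample_missing Maximum tolerated per-sample missing fraction
#'   (strictly greater is removed).
#' @param relatedness_cutoff Off-diagonal GRM value above which a pair is
#'   considered related.
#' @param drop_palindromic Drop A/T and G/C SNPs?
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_info = 0.6, min_maf = 0.01, hwe_p_floor = 1e-6,
                          max_sample_missing = 0.02, relatedness_cutoff = 0.2,
                          drop_palindromic = TRUE) {
  for (v in c(min_info, min_maf, hwe_p_floor, max_sample_missing)) {
    if (v < 0 || v >= 1) stop("thresholds must lie in [0, 1)")
  }
  structure(list(min_info = min_info, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor,
                 max_sample_missing = max_sample_missing,
                 relatedness_cutoff = relatedness_cutoff,
                 drop_palindromic = isTRUE(drop_palindromic)),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test on genotype counts: conditional on the observed
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. Probabilities follow the classical exact distribution of
#' heterozygote counts in a sample drawn from a population in equilibrium.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, not all zero).
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa                # minor/major roles are symmetric
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2) # feasible heterozygote counts
  # log P(n_Aa = h | allele counts) up to a shared constant:
  # n! / (nAA! nAa! naa!) * 2^nAa / [ (2n)! / (nA! na!) ]
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    AA <- n - aa - h
    h * log(2) - lgamma(h + 1) - lgamma(aa + 1) - lgamma(AA + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- min(n_Aa, rare)               # n_Aa given roles; equals n_Aa
  if (!n_Aa %in% hets) stop("inconsistent genotype counts")
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP genotype counts and summary statistics
#' @param dataset A [genotype_dataset()].
#' @return `data.frame` with counts of the three genotypes, call rate, MAF
#'   and HWE exact p per SNP.
#' @export
snp_stats <- function(dataset) {
  d <- dataset$dosage
  n2 <- colSums(d == 2, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n0 <- colSums(d == 0, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe <- rep(NA_real_, length(n))
  ok <- n > 0
  hwe[ok] <- mapply(hwe_exact_p, n2[ok], n1[ok], n0[ok])
  data.frame(id = dataset$snps$id, n_called = n,
             call_rate = n / n_samples(dataset),
             freq_a1 = p, maf = maf, hwe_p = hwe,
             stringsAsFactors = FALSE)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Apply SNP-level quality-control filters
#'
#' Filters are applied in a fixed, reported order — INFO, then MAF, then
#' Hardy-Weinberg, then palindromic alleles — each on the SNPs surviving the
#' previous step. MAF and HWE are computed from non-missing genotypes of the
#' current sample set. Set a threshold to 0 (or `drop_palindromic = FALSE`)
#' to disable a filter.
#'
#' @param dataset A [genotype_dataset()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `dataset` (filtered) and `report`, a `qc_report`
#'   carrying per-filter removal counts and surviving ids.
#' @export
apply_snp_filters <- function(dataset, thresholds = qc_thresholds()) {
  removed <- c(info = 0L, maf = 0L, hwe = 0L, palindromic = 0L)
  keep <- dataset
  if (thresholds$min_info > 0) {
    if (is.null(keep$snps$info)) {
      warning("dataset carries no INFO scores; INFO filter skipped")
    } else {
      drop <- keep$snps$info < thresholds$min_info
      removed["info"] <- sum(drop)
      if (any(drop)) keep <- subset_dataset(keep, snps = !drop)
    }
  }
  if (thresholds$min_maf > 0 && n_snps(keep) > 0) {
    st <- snp_stats(keep)
    drop <- is.na(st$maf) | st$maf < thresholds$min_maf
    removed["maf"] <- sum(drop)
    if (any(drop)) keep <- subset_dataset(keep, snps = !drop)
  }
  if (thresholds$hwe_p_floor > 0 && n_snps(keep) > 0) {
    st <- snp_stats(keep)
    drop <- is.na(st$hwe_p) | st$hwe_p < thresholds$hwe_p_floor
    removed["hwe"] <- sum(drop)
    if (any(drop)) keep <- subset_dataset(keep, snps = !drop)
  }
  if (thresholds$drop_palindromic && n_snps(keep) > 0) {
    drop <- is_palindromic(keep$snps$a1, keep$snps$a2)
    removed["palindromic"] <- sum(drop)
    if (any(drop)) keep <- subset_dataset(keep, snps = !drop)
  }
  if (n_snps(keep) == 0) stop("no SNPs survive quality control")
  report <- structure(list(axis = "snp", removed = removed,
                           n_in = n_snps(dataset), n_out = n_snps(keep),
                           surviving = keep$snps$id),
                      class = "qc_report")
  list(dataset = keep, report = report)
}

#' Apply sample-level quality-control filters
#'
#' Removes samples whose missing-genotype fraction strictly exceeds
#' `max_sample_missing`.
#'
#' @inheritParams apply_snp_filters
#' @return List with `dataset` and a `qc_report`.
#' @export
apply_sample_filters <- function(dataset, thresholds = qc_thresholds()) {
  missfrac <- rowMeans(is.na(dataset$dosage))
  drop <- missfrac > thresholds$max_sample_missing
  keep <- if (any(drop)) subset_dataset(dataset, samples = !drop) else dataset
  report <- structure(list(axis = "sample",
                           removed = c(missingness = sum(drop)),
                           n_in = n_samples(dataset), n_out = n_samples(keep),
                           surviving = sample_ids(keep)),
                      class = "qc_report")
  list(dataset = keep, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report (", x$axis, " axis): ", x$n_in, " -> ", x$n_out, "\n", sep = "")
  for (nm in names(x$removed)) cat("  removed by ", nm, ": ", x$removed[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write a QC report as tab-separated text
#' @param report A `qc_report`.
#' @param path Output file path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(filter = names(report$removed),
                   removed = as.integer(report$removed))
  df <- rbind(df, data.frame(filter = c("input", "surviving"),
                             removed = c(report$n_in, report$n_out)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prune related samples from a genomic relationship matrix
#'
#' Scans off-diagonal GRM entries in ascending (row, column) index order; for
#' every pair still intact whose relatedness exceeds `cutoff`, one member is
#' removed uniformly at random. The returned sample set contains no pair
#' above the cutoff.
#'
#' @param grm A [compute_grm()] result.
#' @param cutoff Relatedness threshold (> 0).
#' @param seed Optional integer seed for the random member choice.
#' @return Character vector of surviving sample ids.
#' @export
prune_related <- function(grm, cutoff = 0.2, seed = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.null(seed)) set.seed(seed)
  G <- grm$values
  n <- nrow(G)
  alive <- rep(TRUE, n)
  for (i in seq_len(n - 1)) {
    if (!alive[i]) next
    for (j in seq(i + 1, n)) {
      if (alive[i] && alive[j] && G[i, j] > cutoff) {
        drop <- if (stats::runif(1) < 0.5) i else j
        alive[drop] <- FALSE
      }
    }
  }
  grm$ids[alive]
}
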