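# Small in-code fixtures shared across test files.

toy_dataset <- function(dosage, a1 = NULL, a2 = NULL, info = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  n <- nrow(dosage)
  snps <- data.frame(id = sprintf("s%03d", seq_len(m)), chr = 1L,
                     pos = seq_len(m) * 100L,
                     a1 = if (is.null(a1)) rep("A", m) else a1,
                     a2 = if (is.null(a2)) rep("G", m) else a2,
                     stringsAsFactors = FALSE)
  if (!is.null(info)) snps$info <- info
  samples <- data.frame(fid = sprintf("F%04d", seq_len(n)),
                        iid = sprintf("I%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
  genotype_dataset(dosage, snps, samples)
}

toy_phenotypes <- function(dataset, status, adjusted = NA_real_) {
  out <- data.frame(fid = dataset$samples$fid, iid = dataset$samples$iid,
                    status = status, adjusted = adjusted,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

make_io_fixture <- function(seed = 80, n = 15, m = 12) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, 0.4), n, m)
  d[2, 3] <- NA
  d[d[, 1] == 2, 1] <- 1                  # make sure no column is constant
  toy_dataset(d, a1 = rep(c("A", "C", "T"), length.out = m),
              a2 = rep(c("G", "T", "C"), length.out = m),
              info = runif(m, 0.5, 1))
}

# Independent enumeration oracle for the exact Hardy-Weinberg test, built on
# the classical probability recurrence over heterozygote counts (a different
# route than the package's direct log-gamma evaluation).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    aa <- (rare - h) / 2
    AA <- n - aa - h
    # P(h+2) = P(h) * 4 * AA * aa / ((h+2)(h+1))
    pr[k] <- pr[k - 1] * 4 * AA * aa / ((h + 2) * (h + 1))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# Brute-force AUC by explicit pair counting.
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]
  ks <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ks) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ks))
}
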