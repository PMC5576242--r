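make_assoc_cohort <- function(n = 300, m = 60, h2 = 0.4, seed = 1,
                              K = 0.2, pi = c(0.6, 0.2, 0.1, 0.1)) {
  cfg <- simulation_config(n_pool = max(4 * n, 800), m = m, h2 = h2,
                           prevalence_K = K, n_cases = n / 2,
                           n_controls = n / 2, seed = seed, pi = pi)
  simulate_cohort(cfg)
}

test_that("single-SNP association controls type-I error and flags degeneracy", {
  set.seed(50)
  n <- 400; m <- 1000
  ds <- toy_dataset(matrix(rbinom(n * m, 2, 0.3), n, m))
  y <- toy_phenotypes(ds, rbinom(n, 1, 0.5), adjusted = rnorm(n))
  res <- single_snp_assoc(ds, y, "adjusted")
  rej <- mean(res$p < 0.05, na.rm = TRUE)
  ci <- qbinom(c(0.005, 0.995), m, 0.05) / m
  expect_gt(rej, ci[1]); expect_lt(rej, ci[2])

  # constant-dosage SNP yields an NA record on both scales
  d2 <- ds$dosage; d2[, 1] <- 1
  ds2 <- toy_dataset(d2)
  expect_true(is.na(single_snp_assoc(ds2, y, "adjusted")$beta[1]))
  res_l <- single_snp_assoc(subset_dataset(ds2, snps = 1:20), y, "status")
  expect_true(is.na(res_l$beta[1]))
  expect_false(anyNA(res_l$beta[-1]))
})

test_that("a strong causal SNP tops the association scan", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 600
    d <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
    lin <- 1.2 * scale(d[, 17]) + rnorm(n)
    ds <- toy_dataset(d)
    y <- toy_phenotypes(ds, as.numeric(lin > quantile(lin, 0.6)))
    res <- single_snp_assoc(ds, y, "status")
    hits <- hits + (which.min(res$p) == 17)
  }
  expect_gte(hits, 4)
})

test_that("GPRS thresholding follows the order statistics of p-values", {
  set.seed(51)
  sim <- make_assoc_cohort(seed = 51)
  y <- sim$phenotypes
  assoc <- single_snp_assoc(sim$dataset, y, "status")
  full <- fit_gprs(assoc, 1)
  expect_equal(sum(full$table$effect != 0), sum(is.finite(assoc$beta)))
  ps <- sort(assoc$p)
  cut <- mean(ps[3:4])
  three <- fit_gprs(assoc, cut)
  expect_equal(sum(three$table$effect != 0), 3)
  expect_error(fit_gprs(assoc, 0), "no SNP")
  grid <- fit_gprs_grid(assoc, c(cut, 1))
  expect_length(grid, 2)
  expect_equal(grid[[1]]$meta$n_selected, 3)
})

test_that("GBLUP equals ridge SNP-BLUP and respects the zero boundary", {
  sim <- make_assoc_cohort(n = 200, m = 50, seed = 52)
  y <- sim$phenotypes
  ids <- paste(y$fid, y$iid, sep = ":")
  tr <- 1:150; te <- 151:200
  p <- allele_freq(sim$dataset)
  grm <- compute_grm(sim$dataset, p)
  fit <- fit_gblup(grm, y[tr, ], ids[te])
  expect_gt(fit$sigma_g2, 0)
  expect_true(fit$h2_hat >= 0 && fit$h2_hat <= 1)

  Z <- grsbench:::standardize_dosage(sim$dataset$dosage, p)
  lam <- 50 * fit$sigma_e2 / fit$sigma_g2
  u <- solve(crossprod(Z[tr, ]) + lam * diag(50),
             crossprod(Z[tr, ], y$status[tr] - fit$mu))
  pred <- drop(Z[te, ] %*% u) + fit$mu
  expect_lt(max(abs(pred - fit$scores)) / max(abs(fit$scores - fit$mu)), 1e-6)

  # SNP-effect back-solve reproduces the GRM predictions through the scorer
  eff <- gblup_snp_effects(fit, subset_dataset(sim$dataset, samples = ids[tr]),
                           freqs = p)
  sc <- score_genotypes(eff, subset_dataset(sim$dataset, samples = ids[te]))
  expect_lt(max(abs(sc - fit$scores)), 1e-8)

  fit0 <- fit_gblup(grm, y[tr, ], ids[te], h2_fixed = 0)
  expect_true(all(fit0$scores == fit0$mu))
  expect_error(fit_gblup(grm, y, ids[tr][1]), "overlap")
})

test_that("elastic net selects by p-value and shrinks fully at huge lambda", {
  sim <- make_assoc_cohort(n = 200, m = 10, seed = 53)
  y <- sim$phenotypes
  assoc <- single_snp_assoc(sim$dataset, y, "status")
  en <- fit_elastic_net(sim$dataset, y, assoc, top_m = 5, seed = 2)
  expect_setequal(en$table$id, assoc$id[order(assoc$p)][1:5])
  expect_equal(en$meta$top_m, 5)

  big <- fit_elastic_net(sim$dataset, y, assoc, top_m = 10, lambda = 1e6,
                         seed = 2)
  expect_true(all(big$table$effect == 0))
  expect_equal(big$intercept, qlogis(mean(y$status)), tolerance = 1e-6)
})

test_that("scoring is exact, order-invariant and flip-invariant", {
  ds <- toy_dataset(matrix(c(2, 1), 1, 2, byrow = TRUE),
                    a1 = c("A", "C"), a2 = c("G", "T"))
  eff <- snp_effects("GPRS",
                     data.frame(id = c("s001", "s002"),
                                effect_allele = c("A", "C"),
                                other_allele = c("G", "T"),
                                effect = c(0.5, -1), freq = c(0.5, 0.25)))
  expect_equal(as.numeric(score_genotypes(eff, ds)), 0)

  zero <- snp_effects("GPRS", transform(eff$table, effect = 0),
                      intercept = 1.5)
  expect_equal(as.numeric(score_genotypes(zero, ds)), 1.5)

  set.seed(54)
  d <- matrix(rbinom(40 * 12, 2, 0.4), 40, 12)
  ds2 <- toy_dataset(d, a1 = rep(c("A", "C"), 6), a2 = rep(c("G", "T"), 6))
  effs <- snp_effects("EN",
                      data.frame(id = ds2$snps$id,
                                 effect_allele = ds2$snps$a1,
                                 other_allele = ds2$snps$a2,
                                 effect = rnorm(12),
                                 freq = allele_freq(ds2)),
                      intercept = 0.3)
  base <- score_genotypes(effs, ds2)
  # flip allele labels and dosages of half the SNPs
  flip <- seq(1, 12, by = 2)
  d2 <- d; d2[, flip] <- 2 - d2[, flip]
  snps2 <- ds2$snps
  tmp <- snps2$a1[flip]; snps2$a1[flip] <- snps2$a2[flip]; snps2$a2[flip] <- tmp
  ds_flip <- genotype_dataset(d2, snps2, ds2$samples)
  expect_equal(score_genotypes(effs, ds_flip), base, ignore_attr = TRUE)
  # SNP order permutation
  perm <- sample(12)
  ds_perm <- subset_dataset(ds2, snps = perm)
  expect_equal(score_genotypes(effs, ds_perm), base, ignore_attr = TRUE)
  # missing dosage imputed to 2 * training freq
  dm <- d; dm[1, 2] <- NA
  ds_na <- genotype_dataset(dm, ds2$snps, ds2$samples)
  sna <- score_genotypes(effs, ds_na)
  manual <- base[1] + effs$table$effect[2] * (2 * effs$table$freq[2] - d[1, 2])
  expect_equal(unname(sna[1]), unname(manual))
  # unresolvable majority errors
  bad <- effs; bad$table$effect_allele <- "T"; bad$table$other_allele <- "A"
  expect_error(score_genotypes(bad, ds2), "scorable")
})
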