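test_that("GRM matches the standardized cross-product formula", {
  # two individuals, one SNP, dosages (0, 2), in-sample p = 0.5
  ds <- toy_dataset(matrix(c(0, 2), 2, 1))
  g <- compute_grm(ds)
  expect_equal(g$values[1, 2], -2)
  expect_equal(g$values[1, 1], 2)
  expect_equal(g$values[2, 2], 2)

  set.seed(5)
  d <- matrix(rbinom(30 * 50, 2, 0.3), 30, 50)
  d[3, ] <- d[7, ]                         # duplicated individual
  ds2 <- toy_dataset(d)
  g2 <- compute_grm(ds2)
  expect_equal(g2$values[3, 7], g2$values[3, 3])
  expect_lt(max(abs(rowSums(g2$values))), 1e-8)
  expect_lt(max(abs(g2$values - t(g2$values))), 1e-10)
  expect_error(compute_grm(toy_dataset(matrix(2, 5, 3))), "monomorphic")

  # monomorphic SNPs skipped with m adjusted
  d3 <- cbind(d, 2)
  g3 <- compute_grm(toy_dataset(d3))
  expect_equal(g3$m_used, 50)
  expect_equal(g3$values, g2$values)
})

test_that("missing genotypes are mean-imputed in the GRM", {
  set.seed(6)
  d <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30)
  dm <- d; dm[1, 5] <- NA
  p <- colMeans(d) / 2
  g <- compute_grm(genotype_dataset(dm, toy_dataset(d)$snps,
                                    toy_dataset(d)$samples), freqs = p)
  # manual reference: standardize, then zero out the imputed cell
  Z <- sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  Z[1, 5] <- 0
  expect_equal(g$values, tcrossprod(Z) / ncol(d), ignore_attr = TRUE)
})

test_that("effective marker count recovers the independent SNP number", {
  for (s in 1:2) {
    set.seed(s)
    d <- matrix(rbinom(2000 * 500, 2, rep(runif(500, 0.1, 0.5), each = 2000)),
                2000, 500)
    ds <- toy_dataset(d)
    me <- effective_marker_count(compute_grm(ds))
    expect_gt(me, 450); expect_lt(me, 550)
    # invariant to duplicating every SNP column
    dup <- toy_dataset(cbind(d, d))
    me2 <- effective_marker_count(compute_grm(dup))
    expect_equal(me2, me, tolerance = 1e-6)
  }
})

test_that("reference PCA separates subpopulations and projects consistently", {
  cfg <- simulation_config(n_pool = 300, m = 1000, n_subpops = 2, fst = 0.2,
                           prevalence_K = 0.2, n_cases = 20, n_controls = 20,
                           seed = 41)
  ref <- simulate_genotypes(cfg)
  pr <- reference_pca(ref, k = 5)
  s <- sign(pr$scores[, 1])
  lab <- ref$samples$subpop
  conc <- max(mean((s > 0) == (lab == 2)), mean((s > 0) == (lab == 1)))
  expect_gte(conc, 0.99)
  # self-projection reproduces the reference scores
  co <- project_samples(pr, ref)
  expect_lt(max(abs(co - pr$scores)) / max(abs(pr$scores)), 1e-8)
  # duplicated reference individuals share coordinates
  dup <- genotype_dataset(ref$dosage[c(1, 1, 2), ], ref$snps,
                          data.frame(fid = "D", iid = paste0("d", 1:3),
                                     stringsAsFactors = FALSE))
  cd <- project_samples(pr, dup)
  expect_equal(unname(cd[1, ]), unname(cd[2, ]))

  # structureless data: no eigengap (top eigenvalue near the noise bulk)
  cfg0 <- simulation_config(n_pool = 150, m = 3000, prevalence_K = 0.2,
                            n_cases = 20, n_controls = 20, seed = 42)
  flat <- simulate_genotypes(cfg0)
  pr0 <- reference_pca(flat, k = 1)
  p <- allele_freq(flat)
  Z <- grsbench:::standardize_dosage(flat$dosage, p)
  bulk <- sum(svd(Z, nu = 0, nv = 0)$d^2) / min(dim(Z))
  expect_lt(pr0$d[1]^2 / bulk, 2)

  expect_error(reference_pca(subset_dataset(ref, samples = 1:4), k = 10),
               "rank")
  expect_error(project_samples(pr, subset_dataset(ref, snps = 1:100)),
               "projection SNPs")
})

test_that("phenotype adjustment is an orthogonal projection", {
  set.seed(43)
  n <- 100
  ds <- toy_dataset(matrix(rbinom(n * 20, 2, 0.4), n, 20))
  y <- toy_phenotypes(ds, rbinom(n, 1, 0.4))
  key <- sample_ids(ds)

  zero <- matrix(0, n, 3, dimnames = list(key, NULL))
  expect_warning(y0 <- adjust_phenotype(y, zero, 3), "collinear")
  expect_equal(y0$adjusted, y$status - mean(y$status))

  pc1 <- matrix(rnorm(n), n, 1, dimnames = list(key, NULL))
  ylin <- y; ylin$status <- 2 + 3 * pc1[, 1]
  expect_equal(adjust_phenotype(ylin, pc1, 1)$adjusted, rep(0, n),
               tolerance = 1e-10)

  co <- matrix(rnorm(n * 4), n, 4, dimnames = list(key, NULL))
  ya <- adjust_phenotype(y, co, 4)
  expect_lt(max(abs(crossprod(co, ya$adjusted))), 1e-8 * n)
  # idempotent: re-adjusting the residual changes nothing
  yb <- ya; yb$status <- ya$adjusted
  yc <- adjust_phenotype(yb, co, 4)
  expect_equal(yc$adjusted, ya$adjusted, tolerance = 1e-10)
})
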