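test_that("identical configs give byte-identical cohorts", {
  cfg <- simulation_config(n_pool = 600, m = 150, h2 = 0.4,
                           prevalence_K = 0.15, n_cases = 80, n_controls = 80,
                           missing_rate = 0.01, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("genotype generator honors frequencies, missingness and alleles", {
  cfg <- simulation_config(n_pool = 2000, m = 300, maf_range = c(0.1, 0.5),
                           prevalence_K = 0.2, n_cases = 50, n_controls = 50,
                           palindromic_fraction = 0.2, seed = 3)
  ds <- simulate_genotypes(cfg)
  phat <- allele_freq(ds)
  se <- sqrt(ds$snps$freq_anc * (1 - ds$snps$freq_anc) / (2 * cfg$n_pool))
  # 5-sigma envelope on 300 binomial frequencies
  expect_lt(max(abs(phat - ds$snps$freq_anc) / se), 5)
  expect_equal(sum(grsbench:::is_palindromic(ds$snps$a1, ds$snps$a2)), 60)
  expect_true(all(ds$snps$info > 0 & ds$snps$info <= 1))

  cfg2 <- simulation_config(n_pool = 100, m = 100, missing_rate = 0.5,
                            prevalence_K = 0.2, n_cases = 10,
                            n_controls = 10, seed = 4)
  ds2 <- simulate_genotypes(cfg2)
  miss <- mean(is.na(ds2$dosage))
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5) / 10000
  expect_gt(miss, ci[1])
  expect_lt(miss, ci[2])
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(fst = 0.2, n_subpops = 1), "n_subpops")
  expect_error(simulation_config(h2 = 1), "h2")
  expect_error(simulation_config(pi = c(0.5, 0.5, 0.5, 0.5)), "pi")
  expect_error(simulation_config(n_pool = 100, n_cases = 80,
                                 n_controls = 80), "exceeds")
})

test_that("mixture effects realize the target heritability exactly", {
  set.seed(10)
  ds <- toy_dataset(matrix(rbinom(200 * 100, 2, 0.3), 200, 100))
  null_model <- simulate_effect_sizes(ds, pi = c(1, 0, 0, 0), h2 = 0)
  expect_true(all(null_model$effects == 0))
  expect_error(simulate_effect_sizes(ds, pi = c(1, 0, 0, 0), h2 = 0.5),
               "null")

  m4 <- simulate_effect_sizes(ds, pi = c(0, 0, 0, 1), h2 = 0.5, seed = 2)
  p <- allele_freq(ds)
  Z <- grsbench:::standardize_dosage(ds$dosage, p)
  expect_equal(var(drop(Z %*% m4$effects)), 0.5, tolerance = 1e-12)
  expect_equal(var(m4$genetic_score), 0.5, tolerance = 1e-12)

  set.seed(11)
  big <- toy_dataset(matrix(rbinom(50 * 10000, 2, 0.4), 50, 10000))
  mod <- simulate_effect_sizes(big, pi = c(0.95, 0.03, 0.015, 0.005),
                               h2 = 0.3, seed = 5)
  nn <- sum(mod$component_labels > 1)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gt(nn, ci[1])
  expect_lt(nn, ci[2])
})

test_that("liability-threshold ascertainment behaves like the model", {
  cfg <- simulation_config(n_pool = 5000, m = 100, h2 = 0, prevalence_K = 0.1,
                           n_cases = 200, n_controls = 200, seed = 7)
  set.seed(7)
  pool <- simulate_genotypes(cfg, seed = NA)
  mod <- simulate_effect_sizes(pool, cfg$pi, cfg$gamma, h2 = 0)
  phen <- simulate_case_control(pool, mod, cfg)
  prev <- attr(phen, "pool_prevalence")
  ci <- qbinom(c(0.005, 0.995), 5000, 0.1) / 5000
  expect_gt(prev, ci[1])
  expect_lt(prev, ci[2])
  expect_equal(sum(phen$status == 1), 200)
  expect_equal(sum(phen$status == 0), 200)

  cfg6 <- simulation_config(n_pool = 5000, m = 200, h2 = 0.6,
                            prevalence_K = 0.1, n_cases = 200,
                            n_controls = 200, seed = 8,
                            pi = c(0.8, 0.1, 0.06, 0.04))
  sim <- simulate_cohort(cfg6)
  t <- attr(sim$phenotypes, "threshold")
  case <- sim$model$liabilities > t
  expect_gt(mean(sim$model$genetic_score[case]),
            mean(sim$model$genetic_score[!case]))
  # too-small pool errors with guidance
  cfg_bad <- simulation_config(n_pool = 300, m = 50, h2 = 0,
                               prevalence_K = 0.05, n_cases = 100,
                               n_controls = 100, seed = 9)
  expect_error(simulate_cohort(cfg_bad), "n_pool")
})

test_that("clinical covariates carry (only) the requested signal", {
  cfg <- simulation_config(n_pool = 4000, m = 150, h2 = 0.6,
                           prevalence_K = 0.2, n_cases = 450,
                           n_controls = 100, seed = 12,
                           pi = c(0.8, 0.1, 0.06, 0.04))
  sim <- simulate_cohort(cfg)
  key <- paste(sim$phenotypes$fid, sim$phenotypes$iid, sep = ":")
  g <- sim$model$genetic_score[key]

  n_sig_null <- 0; n_sig_strong <- 0; reps <- 40
  for (r in seq_len(reps)) {
    y0 <- attach_clinical_covariates(sim$phenotypes, sim$model,
                                     effect_per_sd = 0, seed = 1000 + r)
    cases <- y0$status == 1
    p0 <- score_factor_association(g[cases], y0$onset_group[cases])$p_value
    n_sig_null <- n_sig_null + (p0 < 0.01)
    y2 <- attach_clinical_covariates(sim$phenotypes, sim$model,
                                     effect_per_sd = 2, seed = 2000 + r)
    p2 <- score_factor_association(g[cases], y2$onset_group[cases])$p_value
    n_sig_strong <- n_sig_strong + (p2 < 0.01)
  }
  expect_lte(n_sig_null, qbinom(0.999, reps, 0.01) + 1)
  expect_gte(n_sig_strong, ceiling(0.95 * reps))
  y0 <- attach_clinical_covariates(sim$phenotypes, sim$model, 0, seed = 1)
  expect_true(all(is.na(y0$onset_group[y0$status == 0])))
  expect_true(all(is.na(y0$surgery[y0$status == 0])))
})

test_that("batch re-rendering flips genotypes at the requested rate", {
  set.seed(20)
  ds <- toy_dataset(matrix(rbinom(200 * 200, 2, 0.3), 200, 200))
  b <- batch_copy(ds, 0.1, seed = 21)
  frac <- mean(ds$dosage != b$dosage)
  ci <- qbinom(c(0.005, 0.995), 40000, 0.1) / 40000
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  expect_identical(batch_copy(ds, 0.1, seed = 21)$dosage, b$dosage)
  expect_identical(batch_copy(ds, 0, seed = 1)$dosage, ds$dosage)
})
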