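test_that("fold plans partition samples and stratify case fractions", {
  ds <- toy_dataset(matrix(rbinom(100 * 5, 2, 0.4), 100, 5))
  y10 <- toy_phenotypes(subset_dataset(ds, samples = 1:10),
                        rep(c(0, 1), 5))
  plan <- make_folds(y10, 5, seed = 1)
  expect_equal(unname(table(plan$fold)), rep(2L, 5), ignore_attr = TRUE)

  y <- toy_phenotypes(ds, rep(c(1, 0, 0, 0, 0), c(40, 15, 15, 15, 15)))
  plan2 <- make_folds(y, 5, stratified = TRUE, seed = 2)
  case_per_fold <- tapply(y$status, plan2$fold, sum)
  expect_true(all(case_per_fold == 8))
  expect_setequal(names(plan2$fold), paste(y$fid, y$iid, sep = ":"))
  expect_error(make_folds(y10, 11), "fewer")
  expect_identical(make_folds(y, 5, seed = 3)$fold,
                   make_folds(y, 5, seed = 3)$fold)
})

test_that("AUC equals brute-force pair counting, with exact tie handling", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "control")
  set.seed(70)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    s <- sample(1:8, n, replace = TRUE)   # plenty of ties
    l <- rbinom(n, 1, 0.5)
    if (sum(l) %in% c(0, n)) next
    expect_equal(auc(s, l), auc_bruteforce(s, l))
    expect_equal(auc(s, l) + auc(-s, l), 1)
  }
})

test_that("relative AUC gain matches the printed worked examples", {
  expect_identical(relative_auc_gain(0.779, 0.715), 9.0)
  expect_identical(relative_auc_gain(0.741, 0.690), 7.4)
  expect_identical(relative_auc_gain(0.7, 0.7), 0)
  expect_error(relative_auc_gain(0.7, 0), "positive")
})

test_that("decile odds ratios follow 2x2 table arithmetic", {
  # 100 samples engineered: decile 1 has 2 cases/8 controls, decile 10 has 8/2
  scores <- seq_len(100)
  labels <- rbinom(100, 1, 0.5)
  labels[1:10] <- rep(c(1, 0), c(2, 8))
  labels[91:100] <- rep(c(0, 1), c(2, 8))
  tab <- decile_or(scores, labels)
  expect_equal(tab$or[1], 1)
  expect_equal(tab$or[10], 16)
  expect_equal(sum(tab$n_cases) + sum(tab$n_controls), 100)

  # constant case fraction across deciles gives OR 1 everywhere
  flat <- decile_or(seq_len(100), rep(rep(c(1, 0), c(3, 7)), 10))
  expect_true(all(flat$or == 1))

  # uneven n: decile sizes differ by at most one, remainders at the top
  t2 <- decile_or(seq_len(103), rep(c(0, 1), length.out = 103))
  sizes <- t2$n_cases + t2$n_controls
  expect_true(all(sizes %in% c(10, 11)))
  expect_equal(sum(sizes), 103)
  expect_true(all(diff(sizes) >= 0))

  # multi-model mode: mean and 1.96 SD/sqrt(K) interval
  multi <- decile_or(list(scores, scores + rnorm(100, 0, 1e-9)), labels)
  expect_true(all(c("or_lo", "or_hi") %in% names(multi)))
  expect_equal(multi$or[10], 16, tolerance = 1e-6)
  expect_error(decile_or(1:10, rep(c(0, 1), 5)), "20")
})

test_that("liability-threshold conversions are consistent and monotone", {
  s <- liability_spec(0.005)
  expect_equal(s$t, qnorm(0.995))
  expect_equal(s$i, dnorm(s$t) / 0.005, tolerance = 1e-12)
  expect_equal(s$i2, -dnorm(s$t) / 0.995, tolerance = 1e-12)
  expect_equal(auc_to_liability_v(0.5, 0.01)$v, 0)
  expect_equal(expected_decile_or(0.5, 0.1), 1)
  # round trip auc -> v -> auc
  for (a in c(0.6, 0.7, 0.75)) {
    v <- auc_to_liability_v(a, 0.005)$v
    expect_equal(liability_auc(v, 0.005), a, tolerance = 1e-9)
  }
  # strictly increasing in AUC at fixed prevalence
  grid <- sapply(seq(0.55, 0.85, by = 0.05), expected_decile_or, K = 0.005)
  expect_true(all(diff(grid) > 0))
  expect_error(auc_to_liability_v(0.4, 0.05), "orientation")
})

test_that("quadrature agrees with Monte-Carlo cross-checks", {
  for (a in c(0.6, 0.7, 0.75)) {
    for (K in c(0.002, 0.005, 0.01)) {
      q <- expected_decile_or(a, K)
      mc <- expected_decile_or(a, K, method = "mc", n_mc = 2e6, seed = 17)
      expect_lt(abs(mc / q - 1), 0.02)
    }
  }
  # fully generative check at a prevalence that populates all deciles
  q <- expected_decile_or(0.7, 0.05)
  sim <- expected_decile_or(0.7, 0.05, method = "liability_sim", n_mc = 2e6,
                            seed = 18)
  expect_lt(abs(sim / q - 1), 0.05)
})

test_that("calibration slope and factor association behave as designed", {
  set.seed(71)
  y <- rbinom(500, 1, 0.5)
  expect_equal(calibration_slope(y, y), 1)
  expect_equal(calibration_slope(y / 2, y), 2)
  slopes <- replicate(50, calibration_slope(rnorm(5000), rbinom(5000, 1, 0.5)))
  expect_gte(mean(abs(slopes) < 0.05), 0.9)

  # type-I error of the F-test on null groups
  rej <- 0; reps <- 100
  for (r in 1:reps) {
    s <- rnorm(150)
    f <- sample(rep(c("a", "b", "c"), 50))
    rej <- rej + (score_factor_association(s, f)$p_value < 0.05)
  }
  ci <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
  # power with one level shifted a full SD
  pow <- 0
  for (r in 1:20) {
    f <- rep(c("a", "b", "c"), each = 300)
    s <- rnorm(900) + (f == "c")
    pow <- pow + (score_factor_association(s, f)$p_value < 0.01)
  }
  expect_gte(pow, 19)
  expect_error(score_factor_association(rnorm(10), rep("a", 10)), "levels")
})

test_that("the CV harness trains per fold and reports coherent AUCs", {
  cfg <- simulation_config(n_pool = 2500, m = 150, h2 = 0.5,
                           prevalence_K = 0.1, n_cases = 200,
                           n_controls = 200, seed = 72,
                           pi = c(0.8, 0.1, 0.06, 0.04))
  sim <- simulate_cohort(cfg)
  rep1 <- run_benchmark(sim$dataset, sim$phenotypes,
                        methods = c("gprs", "gblup"), folds = 5, seed = 5)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1), 2)
  expect_true(all(rep1$mean_auc > 0.55))      # heritable signal is learnable
  expect_equal(lengths(rep1$fold_auc), c(5L, 5L))
  # deterministic rerun
  rep2 <- run_benchmark(sim$dataset, sim$phenotypes,
                        methods = c("gprs", "gblup"), folds = 5, seed = 5)
  expect_identical(rep1$mean_auc, rep2$mean_auc)

  # nested scenarios: error on unknown ids
  expect_error(run_benchmark(sim$dataset, sim$phenotypes,
                             scenarios = list(list(name = "bad",
                                                   snp_ids = "nope"))),
               "absent")

  # learning curve: larger training sets do not hurt (within noise)
  ids <- paste(sim$phenotypes$fid, sim$phenotypes$iid, sep = ":")
  small <- run_benchmark(sim$dataset, sim$phenotypes, methods = "gblup",
                         scenarios = list(list(name = "half",
                                               sample_ids = ids[c(1:100, 201:300)]),
                                          list(name = "all")),
                         folds = 5, seed = 6)
  expect_gt(small$mean_auc[small$scenario == "all"],
            small$mean_auc[small$scenario == "half"] - 0.05)
})
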