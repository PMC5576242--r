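#' Simulation configuration for synthetic case-control genotype data
#'
#' Bundles and validates all parameters of the generative model used
#' throughout the package's tests and benchmarks: a pool of unrelated (or
#' two-subpopulation) individuals genotyped at independent biallelic SNPs,
#' SNP effects from a four-component normal mixture on the
#' standardized-genotype scale, a latent liability equal to genetic score
#' plus normal noise, disease status by thresholding the liability at the
#' quantile implied by the prevalence, and case-control ascertainment by
#' sampling from the pool.
#'
#' @param n_pool Individuals in the simulated source population.
#' @param m Number of SNPs.
#' @param maf_range Length-2 numeric, ancestral allele frequency range in
#'   (0, 0.5].
#' @param pi Length-4 mixture proportions (null, small, medium, large
#'   component); must be non-negative and sum to 1.
#' @param gamma Length-4 per-component variance multipliers of the genetic
#'   variance; `gamma[1]` must be 0 (the null point mass). Default
#'   `c(0, 1e-4, 1e-3, 1e-2)`.
#' @param h2 Liability-scale heritability target in `[0, 1)`; realized
#'   exactly by rescaling.
#' @param prevalence_K Disease prevalence in (0, 0.5) defining the liability
#'   threshold.
#' @param n_cases,n_controls Ascertained sample sizes drawn from the pool.
#' @param n_subpops 1 or 2 subpopulations.
#' @param fst Differentiation between subpopulations in `[0, 0.5)`
#'   (Balding-Nichols allele-frequency model).
#' @param confounding_delta Difference in the fraction of ascertained cases
#'   drawn from subpopulation 2 versus balanced sampling; positive values
#'   confound case status with ancestry.
#' @param batch_error_rate Per-genotype error probability used by
#'   [batch_copy()].
#' @param missing_rate Per-genotype missingness probability.
#' @param palindromic_fraction Fraction of SNPs assigned A/T or G/C alleles
#'   (for exercising the palindromic QC filter).
#' @param seed Integer random seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_pool = 10000, m = 1000,
                              maf_range = c(0.05, 0.5),
                              pi = c(0.95, 0.03, 0.015, 0.005),
                              gamma = c(0, 1e-4, 1e-3, 1e-2),
                              h2 = 0.5, prevalence_K = 0.05,
                              n_cases = 500, n_controls = 500,
                              n_subpops = 1, fst = 0,
                              confounding_delta = 0,
                              batch_error_rate = 0, missing_rate = 0,
                              palindromic_fraction = 0.1, seed = 1) {
  cfg <- list(n_pool = as.integer(n_pool), m = as.integer(m),
              maf_range = as.numeric(maf_range), pi = as.numeric(pi),
              gamma = as.numeric(gamma), h2 = h2,
              prevalence_K = prevalence_K,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_subpops = as.integer(n_subpops), fst = fst,
              confounding_delta = confounding_delta,
              batch_error_rate = batch_error_rate, missing_rate = missing_rate,
              palindromic_fraction = palindromic_fraction,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_pool < 2 || m < 1) stop("n_pool and m must be positive")
    if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2]) {
      stop("maf_range must be an increasing pair of frequencies in (0, 0.5]")
    }
    if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
      stop("pi must be 4 non-negative proportions summing to 1")
    }
    if (length(gamma) != 4 || gamma[1] != 0 || any(gamma < 0)) {
      stop("gamma must be a 4-vector with gamma[1] = 0")
    }
    if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
    if (prevalence_K <= 0 || prevalence_K >= 0.5) {
      stop("prevalence_K must lie in (0, 0.5)")
    }
    if (n_cases + n_controls > n_pool) {
      stop("n_cases + n_controls exceeds n_pool")
    }
    if (!n_subpops %in% c(1L, 2L)) stop("n_subpops must be 1 or 2")
    if (fst < 0 || fst >= 0.5) stop("fst must lie in [0, 0.5)")
    if (fst > 0 && n_subpops == 1) stop("fst > 0 requires n_subpops = 2")
    for (r in c(cfg$batch_error_rate, cfg$missing_rate,
                cfg$palindromic_fraction)) {
      if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
    }
    if (abs(confounding_delta) > 1) stop("confounding_delta must lie in [-1, 1]")
  })
  invisible(cfg)
}

#' Simulate a genotype dataset
#'
#' Draws ancestral A1 allele frequencies uniformly over `maf_range`, derives
#' subpopulation frequencies from a Balding-Nichols Beta distribution with
#' parameter `fst` when two subpopulations are requested, and samples
#' independent binomial(2) dosages. A configurable fraction of SNPs receives
#' palindromic (A/T or G/C) allele labels and each SNP an imputation INFO
#' score in (0, 1]. Missing genotypes are injected at `missing_rate`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`; pass `NA` to use the
#'   current RNG state (used internally for sub-stream sequencing).
#' @return A [genotype_dataset()] whose `samples` table carries a `subpop`
#'   column.
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  validate_simulation_config(config)
  s <- if (is.null(seed)) config$seed else seed
  if (!is.na(s)) set.seed(s)
  m <- config$m
  n <- config$n_pool
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  subpop <- rep(1L, n)
  if (config$n_subpops == 2L) {
    subpop <- rep(c(1L, 2L), length.out = n)
    if (config$fst > 0) {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      p_sub <- cbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b))
      # keep SNPs segregating: clamp away from fixation
      p_sub <- pmin(pmax(p_sub, 1e-4), 1 - 1e-4)
    } else {
      p_sub <- cbind(p_anc, p_anc)
    }
  } else {
    p_sub <- cbind(p_anc)
  }
  dosage <- matrix(0, n, m)
  for (k in seq_len(ncol(p_sub))) {
    idx <- which(subpop == k)
    dosage[idx, ] <- matrix(stats::rbinom(length(idx) * m, 2L,
                                          rep(p_sub[, k], each = length(idx))),
                            length(idx), m)
  }
  if (config$missing_rate > 0) {
    dosage[stats::runif(n * m) < config$missing_rate] <- NA
  }
  n_pal <- round(config$palindromic_fraction * m)
  pal <- sample.int(m, n_pal)
  alleles <- matrix("", m, 2)
  nonpal_pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  alleles[, ] <- nonpal_pairs[sample.int(4, m, replace = TRUE), ]
  pal_pairs <- rbind(c("A", "T"), c("G", "C"))
  if (n_pal > 0) alleles[pal, ] <- pal_pairs[sample.int(2, n_pal, replace = TRUE), ]
  chr <- rep(seq_len(22L), length.out = m)[order(rep(seq_len(22L), length.out = m))]
  pos <- stats::ave(seq_len(m), chr, FUN = seq_along) * 1000L
  snps <- data.frame(id = sprintf("snp%06d", seq_len(m)), chr = chr, pos = pos,
                     a1 = alleles[, 1], a2 = alleles[, 2],
                     info = stats::runif(m, 0.2, 1),
                     freq_anc = p_anc, stringsAsFactors = FALSE)
  samples <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                        iid = sprintf("I%05d", seq_len(n)),
                        subpop = subpop, stringsAsFactors = FALSE)
  genotype_dataset(dosage, snps, samples)
}

#' Simulate SNP effect sizes under a normal-mixture architecture
#'
#' Each SNP is assigned a mixture component with probabilities `pi`; non-null
#' components draw effects from `N(0, gamma_k)` on the standardized-genotype
#' scale, and the whole effect vector is then rescaled so the realized
#' variance of the genetic score over the supplied genotypes equals `h2`
#' exactly. Liabilities are completed with independent `N(0, 1 - h2)`
#' environmental noise.
#'
#' @param dataset A [genotype_dataset()] (the simulation pool).
#' @param pi,gamma,h2 Architecture parameters, see [simulation_config()].
#' @param seed Optional integer seed (`NULL` keeps the current RNG state).
#' @return A list of class `true_model` with elements `effects` (per-SNP
#'   standardized-scale liability effects), `component_labels` (1-4),
#'   `sigma_g2` (realized genetic variance, equals `h2`), `h2`,
#'   `liability_threshold_t` slot left `NA` until a prevalence is chosen,
#'   `genetic_score` and `liabilities` (named by sample id).
#' @export
simulate_effect_sizes <- function(dataset, pi = c(0.95, 0.03, 0.015, 0.005),
                                  gamma = c(0, 1e-4, 1e-3, 1e-2), h2 = 0.5,
                                  seed = NULL) {
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be 4 non-negative proportions summing to 1")
  }
  if (gamma[1] != 0) stop("gamma[1] must be 0 (null component)")
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- n_snps(dataset)
  comp <- sample.int(4L, m, replace = TRUE, prob = pi)
  beta <- stats::rnorm(m, 0, sqrt(gamma[comp]))
  beta[comp == 1L] <- 0
  p <- allele_freq(dataset)
  Z <- standardize_dosage(dataset$dosage, p)
  g <- drop(Z %*% beta)
  vg <- stats::var(g)
  if (h2 > 0) {
    if (vg <= 0) stop("all effects are null; cannot rescale to h2 > 0 ",
                      "(increase non-null mixture proportions)")
    sc <- sqrt(h2 / vg)
    beta <- beta * sc
    g <- g * sc
  } else {
    beta[] <- 0
    g[] <- 0
  }
  e <- stats::rnorm(n_samples(dataset), 0, sqrt(1 - h2))
  liab <- g + e
  names(g) <- names(liab) <- sample_ids(dataset)
  structure(list(effects = beta, component_labels = comp,
                 sigma_g2 = if (h2 > 0) stats::var(g) else 0, h2 = h2,
                 liability_threshold_t = NA_real_,
                 genetic_score = g, liabilities = liab),
            class = "true_model")
}

#' Ascertain a case-control sample under the liability-threshold model
#'
#' Individuals whose latent liability exceeds `t = qnorm(1 - K)` are pool
#' cases; `n_cases` cases and `n_controls` controls are then sampled from the
#' pool. With `confounding_delta > 0` (two subpopulations) ascertained cases
#' are drawn preferentially from subpopulation 2, inducing case/ancestry
#' confounding; controls are always sampled without regard to ancestry.
#'
#' @param dataset The pool [genotype_dataset()].
#' @param model A `true_model` from [simulate_effect_sizes()].
#' @param config A [simulation_config()] supplying `prevalence_K`, `n_cases`,
#'   `n_controls` and `confounding_delta`.
#' @param seed Optional integer seed.
#' @return A `data.frame` (class `phenotype_table`) with columns `fid`,
#'   `iid`, `status` (0/1), `adjusted` (`NA` until [adjust_phenotype()]) and
#'   `subpop`; attribute `pool_prevalence` records the pool case fraction and
#'   attribute `threshold` the liability threshold used.
#' @export
simulate_case_control <- function(dataset, model, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- config$prevalence_K
  t <- stats::qnorm(1 - K)
  ids <- sample_ids(dataset)
  is_case <- model$liabilities[ids] > t
  pool_cases <- which(is_case)
  pool_controls <- which(!is_case)
  if (length(pool_cases) < config$n_cases) {
    stop("pool yields only ", length(pool_cases), " cases but n_cases = ",
         config$n_cases, "; increase n_pool or prevalence_K")
  }
  if (length(pool_controls) < config$n_controls) {
    stop("pool yields too few controls; increase n_pool")
  }
  subpop <- dataset$samples$subpop
  if (is.null(subpop)) subpop <- rep(1L, length(ids))
  delta <- config$confounding_delta
  if (delta != 0 && config$n_subpops == 2L) {
    frac2 <- min(max(0.5 + delta / 2, 0), 1)
    want2 <- round(config$n_cases * frac2)
    c2 <- pool_cases[subpop[pool_cases] == 2L]
    c1 <- pool_cases[subpop[pool_cases] == 1L]
    take2 <- min(want2, length(c2))
    take1 <- config$n_cases - take2
    if (take1 > length(c1)) stop("not enough subpopulation-1 cases in pool")
    cases <- c(sample(c2, take2), sample(c1, take1))
  } else {
    cases <- sample(pool_cases, config$n_cases)
  }
  controls <- sample(pool_controls, config$n_controls)
  sel <- c(cases, controls)
  out <- data.frame(fid = dataset$samples$fid[sel],
                    iid = dataset$samples$iid[sel],
                    status = rep(c(1, 0), c(length(cases), length(controls))),
                    adjusted = NA_real_,
                    subpop = subpop[sel],
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "pool_prevalence") <- mean(is_case)
  attr(out, "threshold") <- t
  out
}

#' Attach clinical covariates correlated with the true genetic score
#'
#' Generates, for cases only, three categorical clinical covariates (age at
#' onset group, bowel-surgery indicator, disease location) whose category
#' probabilities are tilted by `effect_per_sd` times the case's standardized
#' true genetic score: higher scores shift mass towards earlier onset,
#' surgery and ileal location. `effect_per_sd = 0` yields covariates
#' independent of the score. Controls receive `NA`.
#'
#' @param phenotypes A `phenotype_table` from [simulate_case_control()].
#' @param model The `true_model` carrying genetic scores.
#' @param effect_per_sd Log-odds tilt per standard deviation of the genetic
#'   score.
#' @param seed Optional integer seed.
#' @return The phenotype table with `onset_group`, `surgery` and `location`
#'   factor columns added.
#' @export
attach_clinical_covariates <- function(phenotypes, model, effect_per_sd = 0,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- paste(phenotypes$fid, phenotypes$iid, sep = ":")
  g <- model$genetic_score[key]
  if (anyNA(g)) stop("phenotype samples missing from the true model")
  z <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  specs <- list(
    onset_group = list(levels = c("1-19", "20-39", ">40"),
                       base = c(0.30, 0.45, 0.25), w = c(1, 0, -1)),
    surgery = list(levels = c("no", "yes"), base = c(0.6, 0.4), w = c(0, 1)),
    location = list(levels = c("ileal", "colonic", "ileocolonic"),
                    base = c(0.35, 0.30, 0.35), w = c(1, -1, 0))
  )
  n <- nrow(phenotypes)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    col <- factor(rep(NA_character_, n), levels = sp$levels)
    for (i in which(phenotypes$status == 1)) {
      pr <- sp$base * exp(effect_per_sd * z[i] * sp$w)
      col[i] <- sample(sp$levels, 1, prob = pr / sum(pr))
    }
    phenotypes[[nm]] <- col
  }
  phenotypes
}

#' Re-render a genotype dataset with batch errors
#'
#' Produces a second genotyping of the same samples in which each non-missing
#' genotype is, with probability `error_rate`, replaced by one of the other
#' two dosage values chosen uniformly — a symmetric per-genotype error model
#' emulating cross-platform batch artifacts.
#'
#' @param dataset A [genotype_dataset()].
#' @param error_rate Per-genotype error probability.
#' @param seed Optional integer seed.
#' @return A [genotype_dataset()] with identical metadata.
#' @export
batch_copy <- function(dataset, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- dataset$dosage
  flip <- !is.na(d) & stats::runif(length(d)) < error_rate
  if (any(flip)) {
    cur <- d[flip]
    # uniformly pick one of the two other dosage values
    shift <- sample(1:2, sum(flip), replace = TRUE)
    d[flip] <- (cur + shift) %% 3
  }
  genotype_dataset(d, dataset$snps, dataset$samples)
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_effect_sizes()] and [simulate_case_control()] off one seeded
#' stream, returning the ascertained dataset aligned with its phenotypes.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (ascertained samples only), `phenotypes`,
#'   `model` (true generative model) and `pool` (the full pool dataset).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  pool <- simulate_genotypes(config, seed = NA)
  model <- simulate_effect_sizes(pool, config$pi, config$gamma, config$h2,
                                 seed = NULL)
  phen <- simulate_case_control(pool, model, config, seed = NULL)
  ds <- subset_dataset(pool, samples = paste(phen$fid, phen$iid, sep = ":"))
  list(dataset = ds, phenotypes = phen, model = model, pool = pool)
}
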