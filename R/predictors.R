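#' Extract the phenotype vector on a chosen scale
#' @param y A `phenotype_table`.
#' @param scale `"status"` (0/1 disease status) or `"adjusted"`
#'   (ancestry-adjusted residual, see [adjust_phenotype()]).
#' @return Named numeric vector (`fid:iid` names).
#' @keywords internal
pheno_vector <- function(y, scale = c("status", "adjusted")) {
  scale <- match.arg(scale)
  v <- y[[scale]]
  if (scale == "adjusted" && all(is.na(v))) {
    stop("adjusted phenotype not available; run adjust_phenotype() first")
  }
  names(v) <- paste(y$fid, y$iid, sep = ":")
  v
}

#' Construct a SNP effect set
#'
#' The common currency of all four predictors: per-SNP allele effects plus an
#' intercept, with training-fold allele frequencies retained for
#' missing-dosage imputation at scoring time.
#'
#' @param method One of `"GPRS"`, `"EN"`, `"GBLUP"`, `"BAYESR"`.
#' @param table `data.frame` with columns `id`, `effect_allele`,
#'   `other_allele`, `effect`, `freq` (training frequency of the effect
#'   allele).
#' @param intercept Numeric intercept.
#' @param meta List of training metadata (cutoffs, tuning values, MCMC
#'   settings).
#' @return An object of class `snp_effects`.
#' @export
snp_effects <- function(method, table, intercept = 0, meta = list()) {
  stopifnot(all(c("id", "effect_allele", "other_allele", "effect", "freq")
                %in% names(table)))
  if (any(!is.finite(table$effect))) stop("effects must be finite")
  structure(list(method = method, table = table, intercept = intercept,
                 meta = meta),
            class = "snp_effects")
}

#' @export
print.snp_effects <- function(x, ...) {
  cat("snp_effects [", x$method, "]: ", nrow(x$table), " SNPs, ",
      sum(x$table$effect != 0), " non-zero, intercept ",
      signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' Write SNP effects as tab-separated text
#'
#' Columns `SNP`, `effect_allele`, `other_allele`, `effect`, `freq`,
#' `method` — usable in spirit as PLINK `--score` input. The intercept is
#' recorded on a `#intercept` header line.
#'
#' @param effects A [snp_effects()] object.
#' @param path Output path.
#' @export
write_snp_effects <- function(effects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#intercept\t%.10g\t%s", effects$intercept,
                     effects$method), con)
  df <- data.frame(SNP = effects$table$id,
                   effect_allele = effects$table$effect_allele,
                   other_allele = effects$table$other_allele,
                   effect = effects$table$effect,
                   freq = effects$table$freq,
                   method = effects$method)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single-SNP association scan
#'
#' Per-SNP univariate regression of the phenotype on dosage with an
#' intercept: logistic (Wald test) on the 0/1 status scale, ordinary linear
#' regression on the adjusted scale. Missing dosages are dropped per SNP.
#' Monomorphic SNPs and fits with degenerate standard errors (e.g. perfect
#' separation) yield `NA` records.
#'
#' @param dataset Training-fold [genotype_dataset()].
#' @param y `phenotype_table` for the training samples (subset of the
#'   dataset's samples).
#' @param scale `"status"` or `"adjusted"`.
#' @return `data.frame`: `id`, `a1`, `a2`, `freq_a1`, `beta`, `se`, `p`, `n`.
#' @export
single_snp_assoc <- function(dataset, y, scale = c("status", "adjusted")) {
  scale <- match.arg(scale)
  yv <- pheno_vector(y, scale)
  idx <- match(names(yv), sample_ids(dataset))
  if (anyNA(idx)) stop("phenotype samples missing from dataset")
  X <- dataset$dosage[idx, , drop = FALSE]
  if (length(unique(yv[!is.na(yv)])) < 2) stop("phenotype is constant")
  m <- ncol(X)
  out <- data.frame(id = dataset$snps$id, a1 = dataset$snps$a1,
                    a2 = dataset$snps$a2,
                    freq_a1 = colMeans(X, na.rm = TRUE) / 2,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = colSums(!is.na(X)), stringsAsFactors = FALSE)
  if (scale == "adjusted") {
    # vectorized per-SNP OLS on complete observations
    obs <- !is.na(X)
    X0 <- X; X0[!obs] <- 0
    nv <- colSums(obs)
    sy <- as.vector(crossprod(obs, yv))
    sy2 <- as.vector(crossprod(obs, yv^2))
    sx <- colSums(X0)
    sx2 <- colSums(X0^2)
    sxy <- as.vector(crossprod(X0, yv))
    sxx <- sx2 - sx^2 / nv
    syy <- sy2 - sy^2 / nv
    sxy <- sxy - sx * sy / nv
    ok <- nv > 2 & sxx > 0
    beta <- ifelse(ok, sxy / sxx, NA_real_)
    rss <- pmax(syy - beta * sxy, 0)
    s2 <- rss / (nv - 2)
    se <- sqrt(s2 / sxx)
    tval <- beta / se
    out$beta <- beta
    out$se <- se
    out$p <- ifelse(ok, 2 * stats::pt(-abs(tval), nv - 2), NA_real_)
  } else {
    for (i in seq_len(m)) {
      x <- X[, i]
      keep <- !is.na(x)
      if (sum(keep) < 3 || stats::var(x[keep]) == 0) next
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, x[keep]), yv[keep],
                       family = stats::binomial()))
      cf <- fit$coefficients[2]
      # Wald SE from the unscaled covariance of the IRLS solve
      w <- fit$weights
      XtWX <- crossprod(cbind(1, x[keep]) * sqrt(w))
      cov2 <- tryCatch(solve(XtWX)[2, 2], error = function(e) Inf)
      se <- sqrt(cov2)
      if (!is.finite(cf) || !is.finite(se) || se > 100) {
        warning("SNP ", dataset$snps$id[i],
                " gave a degenerate logistic fit (possible separation); ",
                "recorded as NA")
        next
      }
      out$beta[i] <- cf
      out$se[i] <- se
      out$p[i] <- 2 * stats::pnorm(-abs(cf / se))
    }
  }
  out
}

#' Genetic profile risk score from association results
#'
#' Keeps the per-SNP association effect for SNPs with `p < p_cutoff` and sets
#' all other effects to zero. `p_cutoff = 1` retains every SNP with a finite
#' effect (the default whole-genome profile score). SNPs with `NA` effects
#' (degenerate fits) are excluded.
#'
#' @param assoc Result of [single_snp_assoc()] on the training fold.
#' @param p_cutoff P-value inclusion threshold in (0, 1].
#' @return A [snp_effects()] with method `"GPRS"` and intercept 0.
#' @export
fit_gprs <- function(assoc, p_cutoff = 1) {
  ok <- is.finite(assoc$beta) & is.finite(assoc$p)
  eff <- ifelse(ok & assoc$p < p_cutoff, assoc$beta, 0)
  if (!any(eff != 0)) stop("no SNP passes p_cutoff = ", p_cutoff)
  snp_effects("GPRS",
              data.frame(id = assoc$id, effect_allele = assoc$a1,
                         other_allele = assoc$a2, effect = eff,
                         freq = assoc$freq_a1, stringsAsFactors = FALSE),
              intercept = 0,
              meta = list(p_cutoff = p_cutoff, n_selected = sum(eff != 0)))
}

#' GPRS over a grid of p-value cutoffs
#' @param assoc Association results (training fold).
#' @param cutoffs Numeric vector of p-value cutoffs.
#' @return Named list of [snp_effects()], one per cutoff.
#' @export
fit_gprs_grid <- function(assoc, cutoffs) {
  stats::setNames(lapply(cutoffs, function(cc) fit_gprs(assoc, cc)),
                  paste0("p<", format(cutoffs)))
}

# Profiled REML for y = mu + g + e, g ~ N(0, sigma_g2 G), via the
# eigendecomposition of G: 1-D optimization over delta = sigma_e2/sigma_g2.
reml_grm <- function(G, yv) {
  n <- length(yv)
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  ys <- drop(crossprod(U, yv))
  xs <- drop(crossprod(U, rep(1, n)))
  prof <- function(logdelta) {
    delta <- exp(logdelta)
    v <- d + delta
    w <- 1 / v
    xwx <- sum(xs^2 * w)
    mu <- sum(xs * ys * w) / xwx
    rss <- sum(w * (ys - xs * mu)^2)
    sg2 <- rss / (n - 1)
    # REML log-likelihood up to a constant
    ll <- -0.5 * ((n - 1) * log(sg2) + sum(log(v)) + log(xwx) + (n - 1))
    list(ll = ll, mu = mu, sg2 = sg2, delta = delta)
  }
  opt <- stats::optimize(function(l) -prof(l)$ll, interval = c(-12, 12),
                         tol = 1e-8)
  est <- prof(opt$minimum)
  sigma_g2 <- est$sg2
  sigma_e2 <- est$sg2 * est$delta
  list(mu = est$mu, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
       h2_hat = sigma_g2 / (sigma_g2 + sigma_e2),
       U = U, d = d, delta = est$delta, logl = est$ll)
}

#' Fit GBLUP and predict test individuals
#'
#' Estimates the variance components of `y = mu + g + e`, `g ~ N(0,
#' sigma_g2 G)`, by restricted maximum likelihood on the training block of
#' the GRM (profiled over the variance ratio on the eigenbasis of `G`, which
#' is exact for this single-component model), then predicts test genetic
#' values through the mixed-model equations:
#' `g_test = G_ts (G_tt + delta I)^-1 (y_t - mu)`, `delta = sigma_e2 /
#' sigma_g2`. The 0/1 status (or the adjusted residual) is treated as a
#' linear trait.
#'
#' @param grm [compute_grm()] covering training and test samples.
#' @param y `phenotype_table` for the training samples only.
#' @param test_ids Character vector of test sample ids (`fid:iid`); may be
#'   empty.
#' @param scale `"status"` or `"adjusted"`.
#' @param h2_fixed Optionally bypass REML and fix the heritability (0 gives
#'   constant predictions equal to the GLS intercept).
#' @return List of class `gblup_fit`: `mu`, `sigma_g2`, `sigma_e2`,
#'   `h2_hat`, `train_ids`, `alpha` (the mixed-model solution
#'   `(G_tt + delta I)^-1 (y_t - mu)` used for prediction and SNP-effect
#'   back-solving), `ghat_train`, and `scores` (named predictions
#'   `mu + g_test` for `test_ids`).
#' @export
fit_gblup <- function(grm, y, test_ids = character(),
                      scale = c("status", "adjusted"), h2_fixed = NULL) {
  scale <- match.arg(scale)
  yv <- pheno_vector(y, scale)
  train_ids <- names(yv)
  ti <- match(train_ids, grm$ids)
  si <- match(test_ids, grm$ids)
  if (anyNA(ti) || anyNA(si)) stop("GRM does not cover all train/test samples")
  if (length(intersect(train_ids, test_ids))) {
    stop("test samples overlap the training phenotypes")
  }
  Gtt <- grm$values[ti, ti, drop = FALSE]
  n <- length(yv)
  if (!is.null(h2_fixed) && h2_fixed == 0) {
    mu <- mean(yv)
    scores <- stats::setNames(rep(mu, length(si)), test_ids)
    fit <- list(mu = mu, sigma_g2 = 0, sigma_e2 = stats::var(yv), h2_hat = 0,
                train_ids = train_ids, alpha = stats::setNames(rep(0, n), train_ids),
                ghat_train = stats::setNames(rep(0, n), train_ids),
                scores = scores, m = grm$m_used, boundary = TRUE)
    class(fit) <- "gblup_fit"
    return(fit)
  }
  if (!is.null(h2_fixed)) {
    eg <- eigen(Gtt, symmetric = TRUE)
    delta <- (1 - h2_fixed) / h2_fixed
    w <- 1 / (pmax(eg$values, 0) + delta)
    ys <- drop(crossprod(eg$vectors, yv))
    xs <- drop(crossprod(eg$vectors, rep(1, n)))
    mu <- sum(xs * ys * w) / sum(xs^2 * w)
    sg2 <- sum(w * (ys - xs * mu)^2) / (n - 1)
    r <- list(mu = mu, sigma_g2 = sg2, sigma_e2 = sg2 * delta,
              h2_hat = h2_fixed, U = eg$vectors, d = pmax(eg$values, 0),
              delta = delta)
  } else {
    r <- reml_grm(Gtt, yv)
  }
  # alpha = (G_tt + delta I)^-1 (y - mu) on the eigenbasis
  resid_rot <- drop(crossprod(r$U, yv - r$mu))
  alpha <- drop(r$U %*% (resid_rot / (r$d + r$delta)))
  names(alpha) <- train_ids
  ghat_train <- drop(Gtt %*% alpha)
  names(ghat_train) <- train_ids
  boundary <- r$h2_hat < 1e-6
  if (boundary) warning("sigma_g2 at the zero boundary; predictions are constant")
  scores <- if (length(si)) {
    drop(grm$values[si, ti, drop = FALSE] %*% alpha) + r$mu
  } else numeric(0)
  names(scores) <- test_ids
  fit <- list(mu = r$mu, sigma_g2 = r$sigma_g2, sigma_e2 = r$sigma_e2,
              h2_hat = r$h2_hat, train_ids = train_ids, alpha = alpha,
              ghat_train = ghat_train, scores = scores, m = grm$m_used,
              boundary = boundary)
  class(fit) <- "gblup_fit"
  fit
}

#' Back-solve GBLUP into per-SNP effects
#'
#' Converts a GBLUP fit into its equivalent SNP-BLUP effect set:
#' `u = Z_t' alpha / m` on the standardized scale (with `alpha =
#' (G_tt + delta I)^-1 (y_t - mu)`), divided by
#' `sqrt(2 p (1-p))` to obtain dosage-scale effects (scoring any dataset with
#' these reproduces the GRM-based predictions). The training dataset must
#' hold exactly the SNPs the GRM was built from.
#'
#' @param fit A [fit_gblup()] result.
#' @param dataset Training-fold [genotype_dataset()] restricted to the GRM's
#'   SNPs.
#' @param freqs Optional frequencies used when the GRM was computed
#'   (defaults to training in-sample).
#' @return A [snp_effects()] with method `"GBLUP"`.
#' @export
gblup_snp_effects <- function(fit, dataset, freqs = NULL) {
  p <- if (is.null(freqs)) allele_freq(dataset) else freqs
  idx <- match(fit$train_ids, sample_ids(dataset))
  if (anyNA(idx)) stop("dataset lacks training samples")
  poly <- !is.na(p) & p > 0 & p < 1
  Z <- standardize_dosage(dataset$dosage[idx, poly, drop = FALSE], p[poly])
  m <- sum(poly)
  u <- drop(crossprod(Z, fit$alpha[fit$train_ids])) / m
  sd <- sqrt(2 * p[poly] * (1 - p[poly]))
  b <- u / sd
  intercept <- fit$mu - sum(b * 2 * p[poly])
  snp_effects("GBLUP",
              data.frame(id = dataset$snps$id[poly],
                         effect_allele = dataset$snps$a1[poly],
                         other_allele = dataset$snps$a2[poly],
                         effect = b, freq = p[poly], stringsAsFactors = FALSE),
              intercept = intercept,
              meta = list(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                          h2_hat = fit$h2_hat))
}

#' Elastic-net risk prediction with SNP pre-selection
#'
#' Restricts the model space to the `top_m` SNPs with the smallest
#' association p-values on the training fold, then fits an elastic-net
#' penalized regression (logit link on the 0/1 status scale, identity link
#' on the adjusted scale) with the penalty weight chosen by inner
#' cross-validated deviance over a decreasing lambda path at fixed mixing
#' parameter `alpha`.
#'
#' @param dataset Training-fold [genotype_dataset()].
#' @param y Training `phenotype_table`.
#' @param assoc [single_snp_assoc()] results from the same training fold.
#' @param top_m Candidate-set size (default 8000; capped at the available
#'   SNP count).
#' @param inner_folds Inner CV folds for lambda selection (default 10).
#' @param scale `"status"` or `"adjusted"`.
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge; default
#'   0.5).
#' @param lambda Optional fixed penalty weight, bypassing the inner CV
#'   (useful for limit checks; a very large value shrinks all effects to
#'   zero, leaving the intercept at the null model value).
#' @param seed Optional seed for the inner fold assignment.
#' @return A [snp_effects()] with method `"EN"`; `meta` records the chosen
#'   lambda and candidate-set size.
#' @export
fit_elastic_net <- function(dataset, y, assoc, top_m = 8000, inner_folds = 10,
                            scale = c("status", "adjusted"), alpha = 0.5,
                            lambda = NULL, seed = NULL) {
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  yv <- pheno_vector(y, scale)
  idx <- match(names(yv), sample_ids(dataset))
  if (anyNA(idx)) stop("phenotype samples missing from dataset")
  ok <- which(is.finite(assoc$p))
  if (length(ok) < 2) stop("degenerate candidate set (fewer than 2 usable SNPs)")
  sel <- ok[order(assoc$p[ok])][seq_len(min(top_m, length(ok)))]
  sel_ids <- assoc$id[sel]
  vi <- match(sel_ids, dataset$snps$id)
  X <- dataset$dosage[idx, vi, drop = FALSE]
  p_train <- colMeans(X, na.rm = TRUE) / 2
  for (j in seq_along(vi)) {          # mean-impute missing dosages
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- 2 * p_train[j]
  }
  fam <- if (scale == "status") "binomial" else "gaussian"
  if (is.null(lambda)) {
    foldid <- sample(rep(seq_len(inner_folds), length.out = nrow(X)))
    cv <- glmnet::cv.glmnet(X, yv, family = fam, alpha = alpha,
                            foldid = foldid)
    lambda <- cv$lambda.min
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  } else {
    fit <- glmnet::glmnet(X, yv, family = fam, alpha = alpha)
    cf <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  }
  snp_effects("EN",
              data.frame(id = sel_ids,
                         effect_allele = dataset$snps$a1[vi],
                         other_allele = dataset$snps$a2[vi],
                         effect = cf[-1], freq = p_train,
                         stringsAsFactors = FALSE),
              intercept = cf[1],
              meta = list(alpha = alpha, lambda = lambda,
                          top_m = length(sel), inner_folds = inner_folds,
                          scale = scale))
}

#' Score samples with a SNP effect set
#'
#' `score_j = intercept + sum_i beta_i * dosage_ij`, reconciling allele
#' orientation by SNP id and allele match: SNPs whose dataset A1 equals the
#' effect allele are used as-is; SNPs with swapped allele labels
#' contribute through the flipped dosage `2 - x`; SNPs absent or with
#' irreconcilable alleles are dropped and counted. Missing dosages are
#' imputed to twice the training-fold effect-allele frequency.
#'
#' @param effects A [snp_effects()].
#' @param dataset A [genotype_dataset()] to score.
#' @return Named numeric vector of risk scores; attribute `n_dropped` counts
#'   unresolvable effect SNPs.
#' @export
score_genotypes <- function(effects, dataset) {
  tab <- effects$table
  idx <- match(tab$id, dataset$snps$id)
  found <- !is.na(idx)
  direct <- found & dataset$snps$a1[idx] == tab$effect_allele &
    dataset$snps$a2[idx] == tab$other_allele
  flipped <- found & !direct & dataset$snps$a1[idx] == tab$other_allele &
    dataset$snps$a2[idx] == tab$effect_allele
  usable <- direct | flipped
  n_drop <- sum(!usable)
  if (sum(usable) < 0.5 * nrow(tab)) {
    stop("only ", sum(usable), " of ", nrow(tab), " effect SNPs are scorable")
  }
  n <- n_samples(dataset)
  score <- rep(effects$intercept, n)
  use <- which(usable)
  D <- dataset$dosage[, idx[use], drop = FALSE]
  pf <- tab$freq[use]
  for (j in seq_along(use)) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- 2 * pf[j]
  }
  flip <- flipped[use]
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  score <- score + drop(D %*% tab$effect[use])
  names(score) <- sample_ids(dataset)
  attr(score, "n_dropped") <- n_drop
  score
}
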