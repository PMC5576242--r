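#' Cross-validation fold plan
#'
#' Deterministic given the seed; stratified by case status by default so
#' per-fold case fractions match the overall fraction to within one sample.
#'
#' @param y A `phenotype_table`.
#' @param K Number of folds (default 5).
#' @param stratified Stratify fold assignment by case status?
#' @param seed Optional integer seed.
#' @return List of class `fold_plan`: `K`, `fold` (named integer vector of
#'   fold labels per sample), `stratified`, `seed`.
#' @export
make_folds <- function(y, K = 5, stratified = TRUE, seed = NULL) {
  n <- nrow(y)
  if (n < K) stop("fewer samples than folds")
  if (!is.null(seed)) set.seed(seed)
  key <- paste(y$fid, y$iid, sep = ":")
  fold <- integer(n)
  if (stratified) {
    for (s in unique(y$status)) {
      idx <- which(y$status == s)
      fold[idx] <- sample(rep(seq_len(K), length.out = length(idx)))
    }
  } else {
    fold <- sample(rep(seq_len(K), length.out = n))
  }
  structure(list(K = K, fold = stats::setNames(fold, key),
                 stratified = stratified, seed = seed),
            class = "fold_plan")
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The fraction of (case, control) pairs in which the case outscores the
#' control, ties counted one half — identical to the trapezoidal ROC area.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 status vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative gain in AUC, in percent
#'
#' `100 * (auc1/auc0 - 1)`, reported to one decimal place.
#'
#' @param auc1,auc0 The two AUC values (`auc0 > 0` is the baseline).
#' @return Percent gain, rounded to one decimal.
#' @export
relative_auc_gain <- function(auc1, auc0) {
  if (auc0 <= 0) stop("baseline AUC must be positive")
  round(100 * (auc1 / auc0 - 1), 1)
}

#' Decile odds-ratio risk stratification
#'
#' Ranks samples by score (ties broken by stable sample order), cuts them
#' into 10 near-equal groups (remainders to the top deciles), and contrasts
#' each decile's case-control odds against the lowest decile. When a list of
#' score vectors is supplied (e.g. the K models of a cross-validation), the
#' per-model ORs are averaged and a 95% interval `mean +/- 1.96 * SD /
#' sqrt(K)` is attached.
#'
#' @param scores Numeric score vector, or a list of score vectors over the
#'   same samples.
#' @param labels 0/1 status vector.
#' @return `data.frame` with columns `decile`, `n_cases`, `n_controls`,
#'   `or` (and `or_lo`, `or_hi` with multiple score sets). The lowest decile
#'   has OR 1 by construction; deciles without controls get `NA` with a
#'   warning.
#' @export
decile_or <- function(scores, labels) {
  if (is.list(scores)) {
    tabs <- lapply(scores, decile_or, labels = labels)
    ors <- sapply(tabs, `[[`, "or")
    k <- length(scores)
    out <- tabs[[1]][c("decile", "n_cases", "n_controls")]
    out$n_cases <- round(rowMeans(sapply(tabs, `[[`, "n_cases")))
    out$n_controls <- round(rowMeans(sapply(tabs, `[[`, "n_controls")))
    out$or <- rowMeans(ors)
    sd <- apply(ors, 1, stats::sd)
    out$or_lo <- out$or - 1.96 * sd / sqrt(k)
    out$or_hi <- out$or + 1.96 * sd / sqrt(k)
    return(out)
  }
  n <- length(scores)
  if (n < 20) stop("need at least 20 samples for decile stratification")
  ord <- order(scores)                   # stable: ties by sample order
  base <- n %/% 10; rem <- n %% 10
  sizes <- rep(base, 10) + c(rep(0, 10 - rem), rep(1, rem))
  dec <- rep(seq_len(10), sizes)[order(ord)]
  nc <- tapply(labels == 1, dec, sum)
  nk <- tapply(labels == 0, dec, sum)
  odds <- ifelse(nk > 0, nc / nk, NA_real_)
  if (any(nk == 0)) warning("decile(s) without controls; OR undefined there")
  data.frame(decile = 1:10, n_cases = as.integer(nc),
             n_controls = as.integer(nk), or = odds / odds[1])
}

#' Calibration slope of predicted scores
#'
#' Slope of the ordinary regression of observed phenotype on predicted
#' score; 1 indicates a calibrated predictor.
#'
#' @param scores Predicted scores.
#' @param y Observed phenotype (numeric, or a `phenotype_table` whose
#'   `status` is used).
#' @return The regression slope.
#' @export
calibration_slope <- function(scores, y) {
  obs <- if (inherits(y, "phenotype_table") || is.data.frame(y)) y$status else y
  if (length(obs) < 3) stop("need at least 3 samples")
  stats::coef(stats::lm(obs ~ scores))[["scores"]]
}

#' Association between risk score and a categorical clinical factor
#'
#' Linear regression of the (internally standardized) score on factor
#' dummies with an overall F-test, mirroring the clinical risk-factor
#' analyses run on case cohorts (onset age group, surgery, disease
#' location).
#'
#' @param scores Numeric risk scores.
#' @param factor_values Categorical covariate (factor or character); `NA`
#'   levels are dropped.
#' @return List: `p_value` (overall F-test), `level_means` (per-level mean
#'   standardized score), `n` per level.
#' @export
score_factor_association <- function(scores, factor_values) {
  f <- factor(factor_values)
  ok <- !is.na(f) & !is.na(scores)
  f <- droplevels(f[ok]); s <- scores[ok]
  if (nlevels(f) < 2) stop("factor needs at least 2 non-empty levels")
  s <- (s - mean(s)) / stats::sd(s)
  fit <- stats::lm(s ~ f)
  an <- stats::anova(fit)
  list(p_value = an[["Pr(>F)"]][1],
       level_means = tapply(s, f, mean),
       n = as.integer(table(f)))
}

#' Train one predictor on a training fold
#'
#' Shared dispatcher used by [run_benchmark()]: performs all SNP selection
#' and tuning strictly inside the given training samples and returns a
#' [snp_effects()] usable on any dataset.
#'
#' @param method `"gprs"`, `"en"`, `"gblup"` or `"bayesr"`.
#' @param dataset Full [genotype_dataset()] (training + test samples).
#' @param y_train `phenotype_table` for the training samples only.
#' @param scale `"status"` or `"adjusted"`.
#' @param control List of method options: `p_cutoff` (GPRS), `top_m`,
#'   `inner_folds`, `alpha` (EN), `mcmc` (a [bayesr_settings()] for BayesR).
#' @return A [snp_effects()].
#' @export
train_predictor <- function(method, dataset, y_train,
                            scale = c("status", "adjusted"),
                            control = list()) {
  method <- match.arg(tolower(method), c("gprs", "en", "gblup", "bayesr"))
  scale <- match.arg(scale)
  train_ids <- paste(y_train$fid, y_train$iid, sep = ":")
  ds_train <- subset_dataset(dataset, samples = train_ids)
  if (method %in% c("gprs", "en")) {
    assoc <- single_snp_assoc(ds_train, y_train, scale)
    if (method == "gprs") {
      return(fit_gprs(assoc, control$p_cutoff %||% 1))
    }
    return(fit_elastic_net(ds_train, y_train, assoc,
                           top_m = control$top_m %||% 8000,
                           inner_folds = control$inner_folds %||% 10,
                           scale = scale, alpha = control$alpha %||% 0.5))
  }
  if (method == "gblup") {
    freqs <- allele_freq(ds_train)
    grm_t <- compute_grm(ds_train, freqs)
    fit <- fit_gblup(grm_t, y_train, character(), scale)
    return(gblup_snp_effects(fit, ds_train, freqs))
  }
  mcmc <- control$mcmc %||% bayesr_settings()
  fit_bayesr(ds_train, y_train, mcmc, scale)$effects
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated benchmark of risk-prediction methods
#'
#' For each scenario (a named subset of samples/SNPs and a phenotype scale)
#' and each method: K-fold cross-validation in which every model is trained
#' — including SNP selection and tuning — on the training folds only, the
#' held-out fold is scored, and the per-fold AUCs are averaged. Optionally,
#' each of the K fold models also scores an external validation cohort and
#' the mean external AUC is reported.
#'
#' @param dataset A [genotype_dataset()].
#' @param y Matching `phenotype_table`.
#' @param methods Character vector among `"gprs"`, `"en"`, `"gblup"`,
#'   `"bayesr"`.
#' @param scenarios List of scenario lists: `name`, optional `sample_ids`,
#'   optional `snp_ids`, `scale` (default `"status"`). `NULL` runs one
#'   default scenario on everything.
#' @param folds Fold count (default 5).
#' @param seed Seed for the fold plans.
#' @param control Per-method options, see [train_predictor()].
#' @param external Optional list `list(dataset=, y=)`: an external cohort
#'   scored by every fold model.
#' @return `data.frame` of class `evaluation_report`: one row per scenario x
#'   method with mean CV AUC, per-fold AUCs (list column `fold_auc`),
#'   calibration slope on pooled out-of-fold scores, and mean external AUC
#'   when requested. Attribute `scores` holds per-fold out-of-sample scores.
#' @export
run_benchmark <- function(dataset, y, methods = c("gprs", "gblup"),
                          scenarios = NULL, folds = 5, seed = 1,
                          control = list(), external = NULL) {
  if (is.null(scenarios)) {
    scenarios <- list(list(name = "all", scale = "status"))
  }
  rows <- list()
  score_store <- list()
  for (sc in scenarios) {
    scale <- sc$scale %||% "status"
    ids <- sc$sample_ids %||% paste(y$fid, y$iid, sep = ":")
    if (!all(ids %in% sample_ids(dataset))) {
      stop("scenario '", sc$name, "' requests samples absent from the dataset")
    }
    ds <- subset_dataset(dataset, samples = ids)
    if (!is.null(sc$snp_ids)) {
      if (!all(sc$snp_ids %in% dataset$snps$id)) {
        stop("scenario '", sc$name, "' requests SNPs absent from the dataset")
      }
      ds <- subset_dataset(ds, snps = sc$snp_ids)
    }
    ysub <- y[match(ids, paste(y$fid, y$iid, sep = ":")), , drop = FALSE]
    plan <- make_folds(ysub, K = folds, seed = seed)
    for (method in methods) {
      fold_auc <- numeric(folds)
      ext_auc <- rep(NA_real_, folds)
      oof_scores <- rep(NA_real_, nrow(ysub))
      for (k in seq_len(folds)) {
        test <- plan$fold == k
        y_train <- ysub[!test, , drop = FALSE]
        eff <- train_predictor(method, ds, y_train, scale,
                               control[[method]] %||% list())
        ds_test <- subset_dataset(ds, samples = names(plan$fold)[test])
        sc_test <- score_genotypes(eff, ds_test)
        fold_auc[k] <- auc(sc_test, ysub$status[test])
        oof_scores[test] <- sc_test
        if (!is.null(external)) {
          se <- score_genotypes(eff, external$dataset)
          key <- paste(external$y$fid, external$y$iid, sep = ":")
          ext_auc[k] <- auc(se[key], external$y$status)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc$name, method = method, scale = scale,
        n = nrow(ysub), m = n_snps(ds),
        mean_auc = mean(fold_auc),
        sd_auc = stats::sd(fold_auc),
        calibration = calibration_slope(oof_scores, ysub$status),
        mean_external_auc = if (is.null(external)) NA_real_ else mean(ext_auc),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$fold_auc <- I(list(fold_auc))
      score_store[[paste(sc$name, method, scale, sep = "|")]] <-
        stats::setNames(oof_scores, paste(ysub$fid, ysub$iid, sep = ":"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scores") <- score_store
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Write an evaluation report
#'
#' Tab-separated table plus a JSON rendering side by side.
#'
#' @param report An `evaluation_report`.
#' @param path Output path (``.tsv``; a ``.json`` twin is written next to
#'   it).
#' @export
write_evaluation_report <- function(report, path) {
  flat <- report[setdiff(names(report), "fold_auc")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- lapply(seq_len(nrow(report)), function(i) {
    c(as.list(flat[i, ]), list(fold_auc = report$fold_auc[[i]]))
  })
  jsonlite::write_json(js, sub("\\.tsv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
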