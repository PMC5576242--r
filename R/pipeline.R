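#' Pipeline configuration
#'
#' Validates paths and settings for [run_pipeline()]. Supply either a
#' [simulation_config()] (synthetic input) or genotype/phenotype file paths.
#'
#' @param out_dir Output directory (created if absent).
#' @param simulate Optional [simulation_config()].
#' @param genotype_prefix Optional PLINK prefix (binary `.bed` triple or
#'   text `.ped`/`.map` pair, autodetected).
#' @param phenotype_path Optional phenotype TSV (required with
#'   `genotype_prefix`).
#' @param snp_metadata_path Optional INFO-score sidecar TSV.
#' @param qc A [qc_thresholds()].
#' @param methods Methods to benchmark.
#' @param folds CV fold count.
#' @param adjust_pcs Number of principal components for phenotype
#'   adjustment (0 disables; components are computed on the study sample
#'   when no reference panel is given).
#' @param reference Optional reference [genotype_dataset()] for PCA
#'   projection.
#' @param control Per-method options, see [train_predictor()].
#' @param seed Global seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, genotype_prefix = NULL,
                            phenotype_path = NULL, snp_metadata_path = NULL,
                            qc = qc_thresholds(), methods = c("gprs", "gblup"),
                            folds = 5, adjust_pcs = 0, reference = NULL,
                            control = list(), seed = 1) {
  if (is.null(simulate)) {
    if (is.null(genotype_prefix) || is.null(phenotype_path)) {
      stop("supply either a simulation config or genotype + phenotype paths")
    }
    has_bed <- file.exists(paste0(genotype_prefix, ".bed"))
    has_ped <- file.exists(paste0(genotype_prefix, ".ped"))
    if (!has_bed && !has_ped) {
      stop("no .bed or .ped found at prefix ", genotype_prefix)
    }
    if (!file.exists(phenotype_path)) {
      stop("phenotype file not found: ", phenotype_path)
    }
    if (!is.null(snp_metadata_path) && !file.exists(snp_metadata_path)) {
      stop("SNP metadata file not found: ", snp_metadata_path)
    }
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 genotype_prefix = genotype_prefix,
                 phenotype_path = phenotype_path,
                 snp_metadata_path = snp_metadata_path, qc = qc,
                 methods = methods, folds = folds, adjust_pcs = adjust_pcs,
                 reference = reference, control = control,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) genotypes and phenotypes, apply SNP- and sample-level
#' QC, prune relatives, optionally ancestry-adjust the phenotype on
#' projected principal components, benchmark the requested predictors by
#' cross-validation, and write all artifacts (QC reports, GRM, effect sets
#' of the final full-data models, evaluation report, and a run manifest with
#' seed and package version) into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The `evaluation_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_cohort(config$simulate))
    dataset <- sim$dataset
    phen <- sim$phenotypes
  } else {
    dataset <- stage("load", {
      if (file.exists(paste0(config$genotype_prefix, ".bed"))) {
        read_plink_binary(paste0(config$genotype_prefix, ".bed"))
      } else {
        read_plink_text(paste0(config$genotype_prefix, ".ped"),
                        paste0(config$genotype_prefix, ".map"))
      }
    })
    if (!is.null(config$snp_metadata_path)) {
      dataset <- read_snp_metadata(dataset, config$snp_metadata_path)
    }
    phen <- stage("load", read_phenotypes(config$phenotype_path, dataset))
  }
  qc_snp <- stage("qc", apply_snp_filters(dataset, config$qc))
  write_qc_report(qc_snp$report, file.path(config$out_dir, "qc_snps.tsv"))
  qc_sam <- stage("qc", apply_sample_filters(qc_snp$dataset, config$qc))
  write_qc_report(qc_sam$report, file.path(config$out_dir, "qc_samples.tsv"))
  dataset <- qc_sam$dataset
  phen <- phen[paste(phen$fid, phen$iid, sep = ":") %in% sample_ids(dataset), ]

  grm <- stage("grm", compute_grm(dataset))
  write_grm_binary(grm, file.path(config$out_dir, "study"))
  keep <- stage("relatedness",
                prune_related(grm, config$qc$relatedness_cutoff))
  if (length(keep) < length(grm$ids)) {
    message("removed ", length(grm$ids) - length(keep), " related sample(s)")
    dataset <- subset_dataset(dataset, samples = keep)
    phen <- phen[paste(phen$fid, phen$iid, sep = ":") %in% keep, ]
  }

  scale <- "status"
  if (config$adjust_pcs > 0) {
    proj <- stage("pca", {
      ref <- config$reference %||% dataset
      reference_pca(ref, k = config$adjust_pcs)
    })
    coords <- stage("pca", project_samples(proj, dataset))
    utils::write.table(data.frame(id = rownames(coords), coords),
                       file.path(config$out_dir, "projected_pcs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    phen <- stage("adjust", adjust_phenotype(phen, coords, config$adjust_pcs))
    scale <- "adjusted"
  }
  write_phenotypes(phen, file.path(config$out_dir, "phenotypes.tsv"))

  report <- stage("evaluate",
                  run_benchmark(dataset, phen, methods = config$methods,
                                scenarios = list(list(name = "all",
                                                      scale = scale)),
                                folds = config$folds, seed = config$seed,
                                control = config$control))
  write_evaluation_report(report, file.path(config$out_dir, "evaluation.tsv"))
  for (method in config$methods) {
    eff <- stage("train", train_predictor(method, dataset, phen, scale,
                                          config$control[[method]] %||%
                                            list()))
    write_snp_effects(eff, file.path(config$out_dir,
                                     paste0("effects_", method, ".tsv")))
  }
  manifest <- list(package = "grsbench",
                   version = as.character(utils::packageVersion("grsbench")),
                   seed = config$seed, methods = config$methods,
                   folds = config$folds, n = n_samples(dataset),
                   m = n_snps(dataset), scale = scale,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(report)
}
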