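#' Write a GRM in GCTA-style binary triple
#'
#' `<prefix>.grm.bin` holds the lower triangle (diagonal included) as
#' little-endian float32 in row order, `<prefix>.grm.N.bin` the SNP count
#' per element, `<prefix>.grm.id` the FID/IID pairs.
#'
#' @param grm A [compute_grm()] result.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_grm_binary <- function(grm, prefix) {
  n <- length(grm$ids)
  lower <- grm$values[upper.tri(grm$values, diag = TRUE)]
  # upper.tri in column order == lower triangle in row order for symmetric G
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m_used), length(lower)), con, size = 4,
           endian = "little")
  close(con)
  ids <- do.call(rbind, strsplit(grm$ids, ":", fixed = TRUE))
  utils::write.table(ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA-style binary GRM
#' @param prefix Path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triple.
#' @return A `grm_matrix`.
#' @export
read_grm_binary <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(ids)
  len <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = len, size = 4,
                  endian = "little")
  if (length(vals) != len) stop("grm.bin truncated")
  Nv <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = len, size = 4,
                endian = "little")
  G <- matrix(0, n, n)
  G[upper.tri(G, diag = TRUE)] <- vals
  G <- G + t(G) - diag(diag(G))
  key <- paste(ids[, 1], ids[, 2], sep = ":")
  dimnames(G) <- list(key, key)
  structure(list(values = G, ids = key, m_used = round(Nv[1]),
                 freq_source = "supplied"),
            class = "grm_matrix")
}

#' Write a GRM as plain text
#'
#' Long format `id1 id2 n_snps grm`, one row per pair (diagonal included).
#'
#' @param grm A `grm_matrix`.
#' @param path Output TSV path.
#' @export
write_grm_text <- function(grm, path) {
  n <- length(grm$ids)
  ut <- which(upper.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = grm$ids[ut[, 1]], id2 = grm$ids[ut[, 2]],
                   n_snps = grm$m_used, grm = grm$values[ut])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header containing at least `FID`, `IID` and
#' `status`; optional `adjusted` and covariate columns are carried along.
#' Status accepts the 0/1 coding or the PLINK 1/2 case-control dialect
#' (autodetected and mapped to 0/1 with a message); `-9` and `NA` denote
#' missing.
#'
#' @param path Input path.
#' @param dataset Optional [genotype_dataset()] to align against (by
#'   FID/IID); samples absent from the dataset are dropped, and zero overlap
#'   is an error.
#' @return A `phenotype_table` (`fid`, `iid`, `status`, `adjusted`, ...).
#' @export
read_phenotypes <- function(path, dataset = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "FID"] <- "fid"
  names(df)[names(df) == "IID"] <- "iid"
  need <- c("fid", "iid", "status")
  if (!all(need %in% names(df))) {
    stop("phenotype file needs columns FID, IID, status")
  }
  if (anyDuplicated(paste(df$fid, df$iid))) stop("duplicate sample ids")
  st <- df$status
  st[st == -9] <- NA
  vals <- unique(st[!is.na(st)])
  if (length(vals) == 0) stop("all status values are missing")
  if (all(vals %in% c(1, 2)) && length(vals) == 2) {
    message("status coded 1/2 (PLINK dialect); remapping to 0/1")
    st <- st - 1
  } else if (!all(vals %in% c(0, 1))) {
    stop("status must be coded 0/1 or 1/2 (missing: -9 or NA)")
  }
  df$status <- st
  if (is.null(df$adjusted)) df$adjusted <- NA_real_
  if (!is.null(dataset)) {
    keep <- paste(df$fid, df$iid, sep = ":") %in% sample_ids(dataset)
    if (!any(keep)) stop("no overlap between phenotype and genotype samples")
    df <- df[keep, , drop = FALSE]
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype/covariate table
#'
#' Tab-separated with columns `FID`, `IID`, `status`, `adjusted` and any
#' covariates present (`onset_group`, `surgery`, `location`, ...).
#'
#' @param y A `phenotype_table`.
#' @param path Output path.
#' @export
write_phenotypes <- function(y, path) {
  out <- as.data.frame(y)
  names(out)[names(out) == "fid"] <- "FID"
  names(out)[names(out) == "iid"] <- "IID"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
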