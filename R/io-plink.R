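#' Write a genotype dataset as PLINK text (ped/map)
#'
#' Dosages are counts of the A1 allele: 2 writes `a1 a1`, 1 `a1 a2`,
#' 0 `a2 a2`, missing `0 0`. Positions are 1-based as in the format.
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Path prefix; `<prefix>.ped` and `<prefix>.map` are written.
#' @return The prefix, invisibly.
#' @export
write_plink_text <- function(dataset, prefix) {
  snps <- dataset$snps
  utils::write.table(data.frame(snps$chr, snps$id, 0, snps$pos),
                     paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(dataset)
  m <- n_snps(dataset)
  al <- matrix("0", n, 2 * m)
  d <- dataset$dosage
  for (j in seq_len(m)) {
    a1 <- snps$a1[j]; a2 <- snps$a2[j]
    g1 <- c("0", a2, a1, a1)[match(d[, j], c(NA, 0, 1, 2), nomatch = 1)]
    g2 <- c("0", a2, a2, a1)[match(d[, j], c(NA, 0, 1, 2), nomatch = 1)]
    al[, 2 * j - 1] <- g1
    al[, 2 * j] <- g2
  }
  lines <- paste(dataset$samples$fid, dataset$samples$iid, 0, 0, 0, -9,
                 apply(al, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK text genotypes (ped/map)
#'
#' Dosages count the first allele listed per SNP in the first sample with a
#' called genotype, declared as A1; `0 0` is missing. Malformed lines raise
#' an error naming the line number.
#'
#' @param ped,map Paths to the `.ped` and `.map` files.
#' @return A [genotype_dataset()] (no INFO metadata).
#' @export
read_plink_text <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) stop("map file must have 4 columns")
  m <- nrow(mp)
  lines <- readLines(ped)
  n <- length(lines)
  if (n == 0) stop("empty ped file")
  fam <- matrix("", n, 6)
  alle <- matrix("", n, 2 * m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop("ped line ", i, " has ", length(f), " fields; expected ", 6 + 2 * m)
    }
    fam[i, ] <- f[1:6]
    alle[i, ] <- f[-(1:6)]
  }
  dosage <- matrix(NA_real_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    g <- alle[, c(2 * j - 1, 2 * j), drop = FALSE]
    called <- g[, 1] != "0" & g[, 2] != "0"
    seen <- unique(as.vector(g[called, , drop = FALSE]))
    if (length(seen) > 2) stop("SNP ", mp[j, 2], " has >2 alleles")
    a1[j] <- if (length(seen) >= 1) seen[1] else "0"
    a2[j] <- if (length(seen) == 2) seen[2] else "0"
    dosage[called, j] <- (g[called, 1] == a1[j]) + (g[called, 2] == a1[j])
  }
  genotype_dataset(dosage,
                   data.frame(id = mp[, 2], chr = mp[, 1], pos = mp[, 4],
                              a1 = a1, a2 = a2, stringsAsFactors = FALSE),
                   data.frame(fid = fam[, 1], iid = fam[, 2],
                              stringsAsFactors = FALSE))
}

#' Write a genotype dataset as PLINK binary (bed/bim/fam)
#'
#' SNP-major bed layout: magic bytes `0x6c 0x1b`, mode byte `0x01`, then per
#' SNP two bits per sample (`00` hom A1, `10` het, `11` hom A2, `01`
#' missing), four samples per byte, low bits first.
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Path prefix for `.bed`, `.bim`, `.fam`.
#' @return The prefix, invisibly.
#' @export
write_plink_binary <- function(dataset, prefix) {
  snps <- dataset$snps
  utils::write.table(data.frame(snps$chr, snps$id, 0, snps$pos, snps$a1,
                                snps$a2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(dataset$samples$fid, dataset$samples$iid,
                                0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(dataset)
  m <- n_snps(dataset)
  codes <- matrix(1L, n, m)                       # 01 = missing
  codes[!is.na(dataset$dosage) & dataset$dosage == 2] <- 0L
  codes[!is.na(dataset$dosage) & dataset$dosage == 1] <- 2L
  codes[!is.na(dataset$dosage) & dataset$dosage == 0] <- 3L
  bps <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bps - n
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    cj <- c(codes[, j], rep(1L, pad))
    byte <- colSums(matrix(cj * rep(mult, bps), 4, bps))
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read PLINK binary genotypes (bed/bim/fam)
#'
#' Validates the magic bytes and SNP-major mode byte, then decodes two-bit
#' genotypes; A1 from the bim file is the counted allele.
#'
#' @param bed,bim,fam Paths to the three files; `bim`/`fam` default to the
#'   bed path with swapped extensions.
#' @return A [genotype_dataset()].
#' @export
read_plink_binary <- function(bed, bim = sub("\\.bed$", ".bim", bed),
                              fam = sub("\\.bed$", ".fam", bed)) {
  bm <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  fm <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fm); m <- nrow(bm)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * m) {
    stop("bed file truncated: expected ", bps * m, " body bytes, found ",
         length(body))
  }
  ints <- as.integer(body)
  two_bits <- rbind(ints %% 4, (ints %/% 4) %% 4,
                    (ints %/% 16) %% 4, (ints %/% 64) %% 4)
  codes <- matrix(as.vector(two_bits), nrow = 4 * bps)[seq_len(n), ,
                                                       drop = FALSE]
  dosage <- matrix(NA_real_, n, m)
  dosage[codes == 0L] <- 2
  dosage[codes == 2L] <- 1
  dosage[codes == 3L] <- 0
  genotype_dataset(dosage,
                   data.frame(id = bm[, 2], chr = bm[, 1], pos = bm[, 4],
                              a1 = as.character(bm[, 5]),
                              a2 = as.character(bm[, 6]),
                              stringsAsFactors = FALSE),
                   data.frame(fid = as.character(fm[, 1]),
                              iid = as.character(fm[, 2]),
                              stringsAsFactors = FALSE))
}

#' Write the per-SNP metadata sidecar (INFO scores)
#' @param dataset A [genotype_dataset()].
#' @param path Output TSV path (columns `id`, `chr`, `pos`, `a1`, `a2`,
#'   `info`).
#' @export
write_snp_metadata <- function(dataset, path) {
  cols <- intersect(c("id", "chr", "pos", "a1", "a2", "info"),
                    names(dataset$snps))
  utils::write.table(dataset$snps[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Attach INFO scores from a metadata sidecar
#' @param dataset A [genotype_dataset()].
#' @param path TSV with columns `id` and `info`.
#' @return The dataset with `snps$info` filled by SNP id.
#' @export
read_snp_metadata <- function(dataset, path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  dataset$snps$info <- md$info[match(dataset$snps$id, md$id)]
  dataset
}
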