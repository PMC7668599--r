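#' Read PLINK-format genotypes
#'
#' Reads a PLINK fileset — text (`.ped`/`.map`) or binary
#' (`.bed`/`.bim`/`.fam`, SNP-major 2-bit encoding) — into a
#' [genotype_dataset()]. Population labels are taken from the family-ID
#' column. All rows are retained, including non-autosomal ones, which are
#' flagged by the logical `autosome` column of the SNP map; filtering happens
#' later in [apply_qc()].
#'
#' Genotypes count copies of the ALT allele. In binary files ALT is the A1
#' allele of the `.bim` (so the coding is lossless); in text files allele
#' identities are not declared, so the reader assigns REF/ALT alphabetically
#' per SNP (REF = alphabetically first observed allele). Monomorphic SNPs in
#' text files keep their single observed allele as REF.
#'
#' @param path_prefix Path without extension.
#' @param format `"binary"`, `"text"`, or `"auto"` (probe for `.bed`, then
#'   `.ped`).
#' @return A [genotype_dataset()].
#' @seealso [write_plink()]
#' @export
read_plink <- function(path_prefix, format = c("auto", "binary", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(path_prefix, ".bed"))) "binary" else "text"
  }
  if (format == "binary") read_plink_binary(path_prefix) else read_plink_text(path_prefix)
}

require_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  path
}

read_plink_text <- function(prefix) {
  map_path <- require_file(paste0(prefix, ".map"))
  ped_path <- require_file(paste0(prefix, ".ped"))
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4) stop("format error: .map must have 4 columns, got ", ncol(map))
  names(map) <- c("chromosome", "snp_id", "cm", "position_bp")
  m <- nrow(map)

  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6 + 2 * m) {
    stop("format error: .ped has ", ncol(ped), " columns but .map implies ",
         6 + 2 * m)
  }
  n <- nrow(ped)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  geno <- matrix(NA_integer_, n, m)
  allele_ref <- character(m)
  allele_alt <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2) {
      stop("format error: SNP ", map$snp_id[j], " has >2 alleles: ",
           paste(obs, collapse = "/"))
    }
    ref <- if (length(obs)) obs[1] else "A"
    alt <- if (length(obs) == 2) obs[2] else "B"
    allele_ref[j] <- ref
    allele_alt[j] <- alt
    g <- (a1[, j] == alt) + (a2[, j] == alt)
    g[is.na(a1[, j]) | is.na(a2[, j])] <- NA
    geno[, j] <- as.integer(g)
  }

  samples <- tibble::tibble(sample_id = ped[[2]], population = ped[[1]])
  snps <- tibble::tibble(
    snp_id = map$snp_id, chromosome = map$chromosome,
    position_bp = as.integer(map$position_bp),
    allele_ref = allele_ref, allele_alt = allele_alt,
    autosome = is_autosome(map$chromosome)
  )
  genotype_dataset(samples, snps, geno)
}

read_plink_binary <- function(prefix) {
  bed_path <- require_file(paste0(prefix, ".bed"))
  bim_path <- require_file(paste0(prefix, ".bim"))
  fam_path <- require_file(paste0(prefix, ".fam"))

  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  names(bim) <- c("chromosome", "snp_id", "cm", "position_bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("format error: ", bed_path, " lacks the PLINK .bed magic bytes")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("format error: only SNP-major .bed files are supported")
  }
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * m) {
    stop("format error: .bed payload is ", length(body),
         " bytes; .fam/.bim imply ", bps * m,
         " (sample or SNP count mismatch)")
  }
  # decode lookup: byte -> 4 genotypes (2 bits each, LSB first)
  # 00 = hom A1 (2 ALT copies), 01 = missing, 10 = het, 11 = hom A2
  two_bit <- c(2L, NA_integer_, 1L, 0L)
  bytes <- 0:255
  lut <- cbind(
    two_bit[bytes %% 4 + 1],
    two_bit[(bytes %/% 4) %% 4 + 1],
    two_bit[(bytes %/% 16) %% 4 + 1],
    two_bit[(bytes %/% 64) %% 4 + 1]
  )
  vals <- lut[as.integer(body) + 1, , drop = FALSE]  # (bps*m) x 4
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    rows <- ((j - 1) * bps + 1):(j * bps)
    g <- as.vector(t(vals[rows, , drop = FALSE]))
    geno[, j] <- g[seq_len(n)]
  }

  samples <- tibble::tibble(sample_id = fam[[2]], population = fam[[1]])
  snps <- tibble::tibble(
    snp_id = bim$snp_id, chromosome = bim$chromosome,
    position_bp = as.integer(bim$position_bp),
    allele_ref = bim$a2, allele_alt = bim$a1,
    autosome = is_autosome(bim$chromosome)
  )
  genotype_dataset(samples, snps, geno)
}

#' Write PLINK-format genotypes
#'
#' Writes a [genotype_dataset()] as a PLINK text (`.ped`/`.map`) or binary
#' (`.bed`/`.bim`/`.fam`) fileset. The family-ID column carries the
#' population label. In binary output A1 = ALT, A2 = REF, so
#' `read_plink(..., "binary")` round-trips the genotype coding exactly.
#'
#' @param data A [genotype_dataset()].
#' @param path_prefix Output path without extension.
#' @param format `"binary"` or `"text"`.
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(data, path_prefix, format = c("binary", "text")) {
  format <- match.arg(format)
  if (format == "binary") write_plink_binary(data, path_prefix)
  else write_plink_text(data, path_prefix)
  invisible(path_prefix)
}

write_plink_text <- function(data, prefix) {
  snps <- data$snps
  geno <- data$genotypes
  n <- nrow(geno); m <- ncol(geno)
  ref <- snps$allele_ref; alt <- snps$allele_alt
  al1 <- matrix("0", n, m); al2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    g <- geno[, j]
    al1[, j] <- ifelse(is.na(g), "0", ifelse(g >= 1, alt[j], ref[j]))
    al2[, j] <- ifelse(is.na(g), "0", ifelse(g == 2, alt[j], ref[j]))
  }
  inter <- matrix("", n, 2 * m)
  inter[, seq(1, 2 * m, 2)] <- al1
  inter[, seq(2, 2 * m, 2)] <- al2
  ped <- cbind(data$samples$population, data$samples$sample_id,
               "0", "0", "0", "-9", inter)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- cbind(snps$chromosome, snps$snp_id, "0", snps$position_bp)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

write_plink_binary <- function(data, prefix) {
  geno <- data$genotypes
  n <- nrow(geno); m <- ncol(geno)
  bps <- ceiling(n / 4)
  # 2 ALT copies -> 00, missing -> 01, het -> 10, hom REF -> 11
  code <- matrix(1L, bps * 4, m)  # pad positions encode "missing"
  enc <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  g <- geno
  cvals <- matrix(1L, n, m)
  cvals[!is.na(g) & g == 0L] <- 3L
  cvals[!is.na(g) & g == 1L] <- 2L
  cvals[!is.na(g) & g == 2L] <- 0L
  code[seq_len(n), ] <- cvals
  idx <- seq(1, bps * 4, by = 4)
  bytes <- code[idx, , drop = FALSE] +
    4L * code[idx + 1, , drop = FALSE] +
    16L * code[idx + 2, , drop = FALSE] +
    64L * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  fam <- cbind(data$samples$population, data$samples$sample_id,
               "0", "0", "0", "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- cbind(data$snps$chromosome, data$snps$snp_id, "0",
               data$snps$position_bp, data$snps$allele_alt,
               data$snps$allele_ref)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
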