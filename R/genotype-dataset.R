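#' Construct a genotype dataset
#'
#' The central container of the package: a diploid, biallelic SNP-array
#' genotype matrix together with its sample sheet and SNP map. Genotypes are
#' stored as counts of the declared ALT allele (0, 1, 2, or `NA` for a
#' missing call) in a samples-by-SNPs integer matrix. SNPs are kept sorted by
#' (chromosome, position) with strictly increasing base-pair positions within
#' a chromosome; duplicate positions are collapsed on construction with a
#' warning.
#'
#' @param samples A data frame with columns `sample_id` (unique character)
#'   and `population` (character label, e.g. a breed acronym).
#' @param snps A data frame with columns `snp_id` (unique character),
#'   `chromosome` (character or integer; autosomes are numeric 1-29 for
#'   cattle), `position_bp` (positive integer, 1-based), and optionally
#'   `allele_ref` / `allele_alt` (single-character codes, default "A"/"B").
#' @param genotypes An integer matrix, `nrow(samples)` x `nrow(snps)`, with
#'   values in `{0, 1, 2, NA}` counting copies of the ALT allele.
#'
#' @return An object of class `genotype_dataset`: a list with tibbles
#'   `$samples`, `$snps` and the integer matrix `$genotypes` (dimnames set to
#'   sample and SNP ids).
#' @export
#' @examples
#' gd <- genotype_dataset(
#'   samples = data.frame(sample_id = c("s1", "s2"), population = "POP"),
#'   snps = data.frame(snp_id = c("m1", "m2"), chromosome = 1,
#'                     position_bp = c(100L, 200L)),
#'   genotypes = matrix(c(0L, 1L, 2L, NA), nrow = 2)
#' )
#' gd
genotype_dataset <- function(samples, snps, genotypes) {
  samples <- tibble::as_tibble(samples)
  snps <- tibble::as_tibble(snps)
  stopifnot(
    all(c("sample_id", "population") %in% names(samples)),
    all(c("snp_id", "chromosome", "position_bp") %in% names(snps))
  )
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position_bp <- as.integer(snps$position_bp)
  if (!"allele_ref" %in% names(snps)) snps$allele_ref <- "A"
  if (!"allele_alt" %in% names(snps)) snps$allele_alt <- "B"

  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(samples) || ncol(genotypes) != nrow(snps)) {
    stop("genotype matrix must be n_samples x n_snps (",
         nrow(samples), " x ", nrow(snps), "), got ",
         nrow(genotypes), " x ", ncol(genotypes))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id values")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id values")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype values must be in {0, 1, 2, NA}")
  }
  if (any(snps$position_bp < 1L, na.rm = TRUE)) {
    stop("position_bp must be positive (1-based)")
  }

  ord <- order(chrom_order(snps$chromosome), snps$position_bp)
  snps <- snps[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  dup <- duplicated(cbind(snps$chromosome, snps$position_bp))
  if (any(dup)) {
    warning(sum(dup), " SNP(s) at duplicated positions dropped: ",
            paste(utils::head(snps$snp_id[dup], 5), collapse = ", "))
    snps <- snps[!dup, , drop = FALSE]
    genotypes <- genotypes[, !dup, drop = FALSE]
  }
  dimnames(genotypes) <- list(samples$sample_id, snps$snp_id)
  structure(
    list(samples = samples, snps = snps, genotypes = genotypes),
    class = "genotype_dataset"
  )
}

# Orders chromosome labels numerically where numeric, then lexically (X, Y...)
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(is.na(num), Inf, num)
  tie <- match(chrom, sort(unique(chrom)))
  rank + tie * 1e-9
}

#' @export
print.genotype_dataset <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("<genotype_dataset> ", nrow(x$samples), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  cat("  populations: ",
      paste0(names(pops), " (", pops, ")", collapse = ", "), "\n", sep = "")
  cat("  chromosomes: ", length(unique(x$snps$chromosome)),
      "; missing calls: ",
      format(round(mean(is.na(x$genotypes)), 4)), "\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a genotype dataset
#' @param x A [genotype_dataset()].
#' @return An integer.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_snps <- function(x) nrow(x$snps)

#' Is a chromosome label an autosome?
#'
#' Autosomes are numeric labels in `1:max_autosome` (29 for cattle).
#'
#' @param chrom Character vector of chromosome labels.
#' @param max_autosome Largest autosome number (default 29, the cattle karyotype).
#' @return Logical vector.
#' @export
is_autosome <- function(chrom, max_autosome = 29L) {
  num <- suppressWarnings(as.integer(chrom))
  !is.na(num) & num >= 1L & num <= max_autosome
}

#' Subset a genotype dataset
#'
#' @param x A [genotype_dataset()].
#' @param samples Logical/integer/character index into samples (default all).
#' @param snps Logical/integer/character index into SNPs (default all).
#' @return A [genotype_dataset()].
#' @export
subset_dataset <- function(x, samples = NULL, snps = NULL) {
  si <- resolve_index(samples, x$samples$sample_id, "sample")
  vi <- resolve_index(snps, x$snps$snp_id, "SNP")
  genotype_dataset(
    x$samples[si, , drop = FALSE],
    x$snps[vi, , drop = FALSE],
    x$genotypes[si, vi, drop = FALSE]
  )
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ", what, " id(s): ",
                         paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) {
    stopifnot(length(idx) == length(ids))
    return(which(idx))
  }
  as.integer(idx)
}

#' Genotypes of one population
#'
#' @param x A [genotype_dataset()].
#' @param population A population label present in `x$samples$population`.
#' @return An integer genotype matrix (samples of that population x SNPs).
#' @export
population_genotypes <- function(x, population) {
  keep <- x$samples$population == population
  if (!any(keep)) stop("unknown population: ", population)
  x$genotypes[keep, , drop = FALSE]
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a genotype dataset
#'
#' @param x A [genotype_dataset()].
#' @param ... Unused.
#' @return A one-row tibble: sample, SNP, chromosome and population counts,
#'   overall missing-call rate and mean per-SNP observed heterozygosity.
#' @export
glance.genotype_dataset <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_snps = nrow(x$snps),
    n_chromosomes = length(unique(x$snps$chromosome)),
    n_populations = length(unique(x$samples$population)),
    missing_rate = mean(is.na(x$genotypes)),
    mean_het = mean(colMeans(x$genotypes == 1L, na.rm = TRUE), na.rm = TRUE)
  )
}

#' Long-format genotype table
#'
#' @param x A [genotype_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, SNP): `sample_id`,
#'   `population`, `snp_id`, `chromosome`, `position_bp`, `genotype`.
#' @export
tidy.genotype_dataset <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = nrow(x$snps)),
    population = rep(x$samples$population, times = nrow(x$snps)),
    snp_id = rep(x$snps$snp_id, each = nrow(x$samples)),
    chromosome = rep(x$snps$chromosome, each = nrow(x$samples)),
    position_bp = rep(x$snps$position_bp, each = nrow(x$samples)),
    genotype = as.integer(x$genotypes)
  )
}
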