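#' Apply genotype quality control
#'
#' Standard SNP-array QC in the fixed PLINK order: (1) remove samples whose
#' missing-call fraction exceeds `max_sample_missing` (`--mind`); (2) remove
#' SNPs whose missing fraction among the surviving samples exceeds
#' `max_snp_missing` (`--geno`); (3) drop non-autosomal SNPs; (4) optionally
#' drop SNPs whose minor-allele frequency among surviving samples is strictly
#' below `min_maf` (`--maf`; a MAF exactly at the threshold is kept). The
#' minor allele is defined per SNP from the observed allele counts.
#'
#' @param data A [genotype_dataset()].
#' @param max_sample_missing Maximum tolerated per-sample missing fraction
#'   (default 0.1).
#' @param max_snp_missing Maximum tolerated per-SNP missing fraction
#'   (default 0.1).
#' @param autosomes_only Drop SNPs on non-autosomal chromosomes (default TRUE).
#' @param min_maf Minimum minor-allele frequency, or `NULL` to skip the MAF
#'   filter (the default: diversity analyses typically run without it, F_ST
#'   scans with `min_maf = 0.05`).
#' @param max_autosome Largest autosome number (29 for cattle).
#' @return The filtered [genotype_dataset()], with a `qc_report` attribute
#'   (a tibble of per-step removal counts; see [qc_report()]).
#' @export
#' @examples
#' gd <- simulate_populations(n_pops = 2, n_per_pop = 10, n_snps = 200,
#'                            fst = 0.1, missing_rate = 0.05, seed = 1)$data
#' qc <- apply_qc(gd, min_maf = 0.05)
#' qc_report(qc)
apply_qc <- function(data, max_sample_missing = 0.1, max_snp_missing = 0.1,
                     autosomes_only = TRUE, min_maf = NULL,
                     max_autosome = 29L) {
  if (n_samples(data) == 0 || n_snps(data) == 0) stop("empty dataset")
  steps <- list()
  note <- function(step, removed, d) {
    tibble::tibble(step = step, removed = removed,
                   samples_left = n_samples(d), snps_left = n_snps(d))
  }

  smiss <- rowMeans(is.na(data$genotypes))
  keep_s <- smiss <= max_sample_missing
  if (!any(keep_s)) stop("all samples removed by the sample missingness filter")
  d <- subset_dataset(data, samples = keep_s)
  steps$mind <- note("sample_missingness", sum(!keep_s), d)

  vmiss <- colMeans(is.na(d$genotypes))
  keep_v <- vmiss <= max_snp_missing
  d <- subset_dataset(d, snps = keep_v)
  steps$geno <- note("snp_missingness", sum(!keep_v), d)

  if (autosomes_only) {
    keep_a <- is_autosome(d$snps$chromosome, max_autosome)
    d <- subset_dataset(d, snps = keep_a)
    steps$auto <- note("non_autosomal", sum(!keep_a), d)
  }

  if (!is.null(min_maf)) {
    maf <- snp_maf(d)
    keep_m <- !is.na(maf) & maf >= min_maf
    d <- subset_dataset(d, snps = keep_m)
    steps$maf <- note("maf", sum(!keep_m), d)
  }

  if (n_snps(d) == 0) warning("no SNPs survive QC")
  attr(d, "qc_report") <- dplyr::bind_rows(steps)
  d
}

#' Per-step QC removal counts
#'
#' @param data A dataset returned by [apply_qc()].
#' @return A tibble with columns `step`, `removed`, `samples_left`,
#'   `snps_left`, one row per filter applied (in application order).
#' @export
qc_report <- function(data) {
  rep <- attr(data, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; was apply_qc() run?")
  rep
}

#' Per-SNP minor-allele frequency
#'
#' @param data A [genotype_dataset()].
#' @return Numeric vector (length `n_snps`): `min(p, 1 - p)` of the observed
#'   ALT frequency among typed alleles; `NA` where no sample is typed.
#' @export
snp_maf <- function(data) {
  g <- data$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA_real_
  maf
}

# Squared Pearson correlation of genotype dosages, pairwise-complete.
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD-prune a genotype dataset
#'
#' Greedy sliding-window LD pruning (the `--indep-pairwise` procedure):
#' within windows of `window_snps` SNPs advanced by `step_snps` along each
#' chromosome, while any retained pair has genotype-dosage r-squared above
#' `r2_threshold`, one SNP of the offending pair is removed — the one with
#' the higher missing-call count, ties broken by removing the later SNP.
#' Pairs are examined in index order, so the retained set is deterministic
#' for a given input order. r-squared is the squared Pearson correlation of
#' dosages over jointly non-missing samples.
#'
#' @param data A [genotype_dataset()].
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Step between window starts in SNPs (default 5).
#' @param r2_threshold Remove one of each pair with r-squared strictly above
#'   this (default 0.5).
#' @return The pruned [genotype_dataset()].
#' @export
ld_prune <- function(data, window_snps = 50L, step_snps = 5L,
                     r2_threshold = 0.5) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (step_snps < 1) stop("step_snps must be >= 1")
  g <- data$genotypes
  keep <- rep(TRUE, n_snps(data))
  nmiss <- colSums(is.na(g))
  for (chr in unique(data$snps$chromosome)) {
    idx <- which(data$snps$chromosome == chr)
    if (length(idx) < 2) next
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      if (length(win) < 2) next
      repeat {
        ret <- win[keep[win]]
        if (length(ret) < 2) break
        hit <- find_high_r2_pair(g, ret, r2_threshold)
        if (is.null(hit)) break
        i <- hit[1]; j <- hit[2]
        drop <- if (nmiss[i] > nmiss[j]) i else if (nmiss[j] > nmiss[i]) j else max(i, j)
        keep[drop] <- FALSE
      }
    }
  }
  subset_dataset(data, snps = keep)
}

# First retained pair (by i then j, column indices ascending) exceeding the
# r2 threshold, or NULL.
find_high_r2_pair <- function(g, ret, thr) {
  for (a in seq_len(length(ret) - 1)) {
    for (b in (a + 1):length(ret)) {
      r2 <- dosage_r2(g[, ret[a]], g[, ret[b]])
      if (!is.na(r2) && r2 > thr) return(c(ret[a], ret[b]))
    }
  }
  NULL
}

#' Pairwise identical-by-state distance matrix
#'
#' For each sample pair, IBS at a SNP counts shared alleles (0, 1 or 2);
#' the distance is `1 - mean(IBS / 2)` over SNPs typed in both samples.
#' The diagonal is exactly 0. Suitable for export to Neighbor-Net /
#' phylogeny software (see [write_ibs_phylip()], [write_ibs_nexus()]).
#'
#' @param data A [genotype_dataset()] with at least 2 samples.
#' @return A symmetric numeric matrix (samples x samples) with values in
#'   `[0, 1]`, dimnames = sample ids.
#' @export
ibs_distance_matrix <- function(data) {
  g <- data$genotypes
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples")
  ids <- data$samples$sample_id
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok)) {
        stop("no jointly typed SNPs for pair ", ids[i], " / ", ids[j])
      }
      ibs <- 2 - abs(g[i, ok] - g[j, ok])
      D[i, j] <- D[j, i] <- 1 - mean(ibs) / 2
    }
  }
  D
}

#' Export an IBS distance matrix
#'
#' `write_ibs_phylip()` writes PHYLIP square format; `write_ibs_nexus()`
#' writes a NEXUS distances block (both consumable by SplitsTree-style
#' Neighbor-Net software).
#'
#' @param D A symmetric distance matrix with sample-id dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ibs_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_ibs_phylip
#' @export
write_ibs_nexus <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", nrow(D)),
    paste0("  TAXLABELS ", paste(rownames(D), collapse = " "), ";"),
    "END;",
    "BEGIN DISTANCES;",
    "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
    "  MATRIX"
  ), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste("   ", rownames(D)[i],
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
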