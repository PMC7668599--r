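#' Per-locus diversity within a population
#'
#' For each SNP with at least two typed samples in the population, computes
#' the ALT allele frequency `p_alt`, observed heterozygosity `ho` (fraction
#' of typed samples that are heterozygous) and Nei's unbiased expected
#' heterozygosity `uhe = (2n / (2n - 1)) * 2p(1 - p)`, with `n` the number of
#' typed samples at the locus. Loci with fewer than two typed samples are
#' skipped (their count is reported in the `n_skipped` attribute).
#'
#' @param data A [genotype_dataset()].
#' @param population A population label.
#' @return A tibble: `snp_id`, `population`, `n_typed`, `p_alt`, `ho`, `uhe`.
#' @export
#' @examples
#' gd <- simulate_populations(2, 10, 100, fst = 0.05, seed = 1)$data
#' head(locus_diversity(gd, "pop1"))
locus_diversity <- function(data, population) {
  g <- population_genotypes(data, population)
  n_typed <- colSums(!is.na(g))
  keep <- n_typed >= 2
  gk <- g[, keep, drop = FALSE]
  n <- n_typed[keep]
  p <- colMeans(gk, na.rm = TRUE) / 2
  ho <- colSums(gk == 1L, na.rm = TRUE) / n
  uhe <- (2 * n / (2 * n - 1)) * 2 * p * (1 - p)
  out <- tibble::tibble(
    snp_id = data$snps$snp_id[keep],
    population = population,
    n_typed = as.integer(n),
    p_alt = as.numeric(p),
    ho = as.numeric(ho),
    uhe = as.numeric(uhe)
  )
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Population diversity summary with bootstrap F_IS
#'
#' Aggregates per-locus diversity into across-locus means and the
#' heterozygosity-based inbreeding coefficient
#' `uF_IS = 1 - mean(Ho) / mean(uHe)` (ratio of means, so a negative value
#' means heterozygote excess). Its 95% confidence interval is a percentile
#' bootstrap over loci (resampled with replacement, seeded). Standard errors
#' of the means are across-locus standard errors.
#'
#' @param loci A tibble from [locus_diversity()] (single population).
#' @param n_bootstrap Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `population`, `n_loci`, `ho_mean`, `ho_se`,
#'   `uhe_mean`, `uhe_se`, `ufis`, `ufis_ci_low`, `ufis_ci_high`.
#' @export
population_summary <- function(loci, n_bootstrap = 1000L, seed = 1L) {
  if (nrow(loci) < 2) stop("need at least 2 loci")
  ho_mean <- mean(loci$ho)
  uhe_mean <- mean(loci$uhe)
  if (uhe_mean == 0) stop("uF_IS undefined: mean unbiased heterozygosity is 0")
  ufis <- 1 - ho_mean / uhe_mean

  m <- nrow(loci)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(m, m, replace = TRUE)
      1 - mean(loci$ho[idx]) / mean(loci$uhe[idx])
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, na.rm = TRUE)

  tibble::tibble(
    population = loci$population[1],
    n_loci = m,
    ho_mean = ho_mean,
    ho_se = stats::sd(loci$ho) / sqrt(m),
    uhe_mean = uhe_mean,
    uhe_se = stats::sd(loci$uhe) / sqrt(m),
    ufis = ufis,
    ufis_ci_low = ci[1],
    ufis_ci_high = ci[2]
  )
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles per locus in a rarefied draw of `g`
#' allele copies: `A_R = sum_a (1 - C(2N - n_a, g) / C(2N, g))` over the
#' locus's alleles, with `N` typed samples and `n_a` copies of allele `a`
#' (biallelic SNPs: A_R lies in [1, 2]). Reported as the across-locus mean
#' per population. With `g = "auto"`, `g` is set to twice the smallest
#' per-population typed sample size over all loci, so every locus is
#' rarefied to a common depth.
#'
#' @param data A [genotype_dataset()].
#' @param populations Character vector of population labels (default: all).
#' @param g Rarefaction depth in allele copies (`>= 2`), or `"auto"`.
#' @return A tibble: `population`, `g`, `n_loci`, `ar_mean`, `ar_se`.
#' @export
allelic_richness <- function(data, populations = NULL, g = "auto") {
  if (is.null(populations)) populations <- unique(data$samples$population)
  counts <- lapply(populations, function(pop) {
    gm <- population_genotypes(data, pop)
    N <- colSums(!is.na(gm))
    n_alt <- colSums(gm, na.rm = TRUE)
    list(N = N, n_alt = n_alt)
  })
  if (identical(g, "auto")) {
    g <- min(vapply(counts, function(x) {
      typed <- x$N[x$N > 0]
      if (!length(typed)) Inf else 2 * min(typed)
    }, numeric(1)))
    if (!is.finite(g)) stop("no typed loci in any population")
  }
  g <- as.integer(g)
  if (g < 2) stop("rarefaction depth g must be >= 2")

  purrr::map2_dfr(populations, counts, function(pop, ct) {
    ok <- 2 * ct$N >= g & ct$N > 0
    N2 <- 2 * ct$N[ok]
    na <- ct$n_alt[ok]
    ar <- rarefied_allele_count(N2, na, g) +
      rarefied_allele_count(N2, N2 - na, g)
    tibble::tibble(
      population = pop, g = g, n_loci = sum(ok),
      ar_mean = mean(ar), ar_se = stats::sd(ar) / sqrt(sum(ok))
    )
  })
}

# P(allele with n_a copies out of n2 appears in a draw of g), via lchoose
# for numerical stability; exactly 0 probability of appearing when n_a = 0.
rarefied_allele_count <- function(n2, n_a, g) {
  miss <- exp(lchoose(n2 - n_a, g) - lchoose(n2, g))
  ifelse(n_a > 0, 1 - miss, 0)
}
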