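#' Per-SNP Weir & Cockerham F_ST between two populations
#'
#' The two-population variance-components estimator theta of Weir &
#' Cockerham (1984), computed per SNP from the sample sizes, ALT allele
#' frequencies and observed heterozygote frequencies of the two populations:
#' `theta = a / (a + b + c)` with `a` the among-population, `b` the
#' among-individual-within-population and `c` the within-individual
#' component. SNPs typed in fewer than 2 samples in either population, or
#' with a zero denominator (monomorphic across both populations), are
#' flagged undefined (`NA` theta) and excluded from the genome-wide
#' aggregates. Negative per-SNP estimates are retained.
#'
#' Two genome-wide aggregates are attached as the `genome_wide` attribute:
#' the arithmetic mean of defined per-SNP theta (`mean_theta`, the headline
#' "average pairwise F_ST") and the variance-component ratio of sums
#' `sum(a) / sum(a + b + c)` (`ratio_of_sums`, the weighted estimator).
#'
#' @param data A [genotype_dataset()].
#' @param pop_a,pop_b Two distinct population labels.
#' @return A tibble with one row per SNP: `snp_id`, `chromosome`,
#'   `position_bp`, `pop_a`, `pop_b`, variance components `a`, `b`, `c`, and
#'   `theta`. Attribute `genome_wide` is a one-row tibble
#'   (`pop_a`, `pop_b`, `n_snps_defined`, `mean_theta`, `ratio_of_sums`);
#'   see [genome_wide_fst()].
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
#' @examples
#' sim <- simulate_populations(2, 30, 1000, fst = 0.1, seed = 3)
#' rec <- wc_fst_pair(sim$data, "pop1", "pop2")
#' genome_wide_fst(rec)
wc_fst_pair <- function(data, pop_a, pop_b) {
  if (identical(pop_a, pop_b)) stop("pop_a and pop_b must differ")
  ga <- population_genotypes(data, pop_a)
  gb <- population_genotypes(data, pop_b)

  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colMeans(ga, na.rm = TRUE) / 2
  p2 <- colMeans(gb, na.rm = TRUE) / 2
  h1 <- colMeans(ga == 1L, na.rm = TRUE)
  h2 <- colMeans(gb == 1L, na.rm = TRUE)

  cmp <- wc_theta_components(unname(n1), unname(p1), unname(h1),
                             unname(n2), unname(p2), unname(h2))
  defined <- unname(n1 >= 2 & n2 >= 2) & !is.na(cmp$theta)
  theta <- ifelse(defined, cmp$theta, NA_real_)

  rec <- tibble::tibble(
    snp_id = data$snps$snp_id,
    chromosome = data$snps$chromosome,
    position_bp = data$snps$position_bp,
    pop_a = pop_a, pop_b = pop_b,
    a = cmp$a, b = cmp$b, c = cmp$c,
    theta = theta
  )
  gw <- tibble::tibble(
    pop_a = pop_a, pop_b = pop_b,
    n_snps_defined = sum(defined),
    mean_theta = mean(theta[defined]),
    ratio_of_sums = sum(cmp$a[defined]) /
      sum((cmp$a + cmp$b + cmp$c)[defined])
  )
  attr(rec, "genome_wide") <- gw
  rec
}

#' @rdname wc_fst_pair
#' @param records A tibble returned by `wc_fst_pair()`.
#' @export
genome_wide_fst <- function(records) {
  gw <- attr(records, "genome_wide")
  if (is.null(gw)) stop("no genome_wide attribute; was wc_fst_pair() run?")
  gw
}

# Vectorised Weir & Cockerham (1984) a, b, c for r = 2 populations.
# n_i sample sizes, p_i ALT frequencies, h_i observed het frequencies.
wc_theta_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2

  denom <- a + b + c
  theta <- ifelse(is.finite(denom) & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = c, theta = theta)
}

#' Select the top fraction of a per-SNP scan
#'
#' Returns the `k = ceiling(fraction * N)` records with the largest theta,
#' `N` counting only records with a defined (non-`NA`) statistic. All
#' records tied with the k-th largest value are included, so the output may
#' exceed `k`. The realised threshold (the smallest selected theta) is
#' attached as the `threshold` attribute.
#'
#' @param records A tibble with a `theta` column (e.g. from
#'   [wc_fst_pair()]).
#' @param fraction Fraction to select (default 0.001, the top 0.1% rule).
#' @param stat Name of the statistic column (default `"theta"`).
#' @return The selected rows, ordered by decreasing statistic.
#' @export
select_top_fraction <- function(records, fraction = 0.001, stat = "theta") {
  if (nrow(records) == 0) stop("empty scan")
  stopifnot(fraction > 0, fraction <= 1)
  vals <- records[[stat]]
  defined <- which(!is.na(vals))
  n <- length(defined)
  if (n < 1 / fraction) {
    warning("only ", n, " defined records for fraction ", fraction,
            "; selection is a single record band")
  }
  k <- ceiling(fraction * n)
  ord <- defined[order(vals[defined], decreasing = TRUE)]
  thr <- vals[ord[k]]
  sel <- defined[vals[defined] >= thr]
  out <- records[sel[order(vals[sel], decreasing = TRUE)], , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "k") <- k
  out
}

#' Candidate windows around top SNPs
#'
#' Each top SNP is flanked by `flank_bp` on each side (the 0.2 Mb up/down
#' rule, giving 0.4 Mb windows), clipped to `[1, chromosome length]`;
#' overlapping or bookended windows on the same chromosome are merged and
#' their member SNP lists concatenated.
#'
#' @param top A tibble of selected SNPs (needs `snp_id`, `chromosome`,
#'   `position_bp`).
#' @param chromosome_lengths Named numeric vector of chromosome lengths
#'   (names = chromosome labels), covering every chromosome in `top`.
#' @param flank_bp Flank on each side in bp (default 200,000).
#' @return A tibble of windows: `chromosome`, `start_bp`, `end_bp`,
#'   `n_snps`, `snp_ids` (list column).
#' @export
windows_from_snps <- function(top, chromosome_lengths, flank_bp = 2e5) {
  if (nrow(top) == 0) {
    return(tibble::tibble(chromosome = character(), start_bp = numeric(),
                          end_bp = numeric(), n_snps = integer(),
                          snp_ids = list()))
  }
  miss <- setdiff(unique(top$chromosome), names(chromosome_lengths))
  if (length(miss)) {
    stop("no declared length for chromosome(s): ", paste(miss, collapse = ", "))
  }
  len <- chromosome_lengths[top$chromosome]
  if (any(top$position_bp > len)) {
    bad <- top$snp_id[top$position_bp > len][1]
    stop("SNP ", bad, " lies beyond its declared chromosome length")
  }
  win <- tibble::tibble(
    chromosome = top$chromosome,
    start_bp = pmax(1, top$position_bp - flank_bp),
    end_bp = pmin(len, top$position_bp + flank_bp),
    snp_id = top$snp_id
  ) |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$start_bp)

  win |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(df, key) {
      # merge overlapping or bookended ([a,b] [b+1,c]) windows
      grp <- cumsum(c(1, df$start_bp[-1] >
                        cummax(df$end_bp[-nrow(df)] + 1)))
      df |>
        dplyr::mutate(grp = grp) |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(start_bp = min(.data$start_bp),
                         end_bp = max(.data$end_bp),
                         n_snps = dplyr::n(),
                         snp_ids = list(.data$snp_id), .groups = "drop") |>
        dplyr::select(-"grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$start_bp)
}
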