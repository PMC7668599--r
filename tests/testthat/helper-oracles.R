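# Independent oracles and fixture builders shared across the test files.
# Every oracle is written against the definitions directly (prefix sums,
# scalar formulas, exhaustive enumeration) and never calls the code paths
# it is used to check.

# -- dataset fixtures --------------------------------------------------------

# Random small genotype dataset: genotypes iid with given het/missing rates.
random_dataset <- function(seed, n_samples = 3, n_snps = 200,
                           n_chrom = 2, chrom_len = 10e6,
                           p_het = 0.3, p_miss = 0.05) {
  withr::with_seed(seed, {
    chrom <- sort(sample.int(n_chrom, n_snps, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix)
      sort(sample.int(chrom_len, length(ix)))))
    g <- matrix(sample(c(0L, 1L, 2L, NA),
                       n_samples * n_snps, replace = TRUE,
                       prob = c((1 - p_het - p_miss) / 2, p_het,
                                (1 - p_het - p_miss) / 2, p_miss)),
                n_samples, n_snps)
    genotype_dataset(
      samples = tibble::tibble(
        sample_id = sprintf("s%02d", seq_len(n_samples)),
        population = "pop"),
      snps = tibble::tibble(
        snp_id = sprintf("m%04d", seq_len(n_snps)),
        chromosome = as.character(sort(chrom)), position_bp = pos),
      genotypes = g
    )
  })
}

# Dataset from an explicit genotype matrix on one chromosome.
dataset_from_matrix <- function(g, pos = NULL, chromosome = "1",
                                populations = NULL) {
  g <- as.matrix(g)
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 10000L
  if (is.null(populations)) populations <- rep("pop", nrow(g))
  genotype_dataset(
    samples = tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(nrow(g))),
      population = populations),
    snps = tibble::tibble(
      snp_id = sprintf("m%04d", seq_len(ncol(g))),
      chromosome = chromosome, position_bp = as.integer(pos)),
    genotypes = g
  )
}

# -- ROH oracle --------------------------------------------------------------

# Naive exhaustive-substring scanner: for every eligible start, the maximal
# valid end is found from prefix-sum counts and the gap-violation list, the
# run is trimmed to homozygous ends, filtered, and the scan resumes after
# the breaking call. Vectorised formulation, independent of the package's
# stateful incremental scanner.
oracle_roh_runs <- function(gvec, pos, max_het = 1, max_miss = 1,
                            max_gap = 1e6, min_snps = 2, min_len = 0) {
  n <- length(gvec)
  is_miss <- is.na(gvec)
  is_het <- !is_miss & gvec == 1L
  is_hom <- !is_miss & !is_het
  chet <- c(0, cumsum(is_het))
  cmiss <- c(0, cumsum(is_miss))
  gapbad <- which(diff(pos) > max_gap)  # gap between j and j+1
  res <- list()
  s <- 1L
  while (s <= n) {
    if (!is_hom[s]) { s <- s + 1L; next }
    gb <- gapbad[gapbad >= s]
    jgap <- if (length(gb)) gb[1] else n
    js <- s:jgap
    ok <- (chet[js + 1] - chet[s] <= max_het) &
      (cmiss[js + 1] - cmiss[s] <= max_miss)
    firstbad <- which(!ok)
    j <- if (length(firstbad)) js[firstbad[1]] - 1L else jgap
    broke_allow <- length(firstbad) > 0
    e <- j
    while (!is_hom[e]) e <- e - 1L
    if (e - s + 1L >= min_snps && pos[e] - pos[s] + 1 >= min_len) {
      res[[length(res) + 1]] <- c(start = s, end = e)
    }
    s <- if (broke_allow) j + 2L else j + 1L
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# -- Weir & Cockerham oracle -------------------------------------------------

# Scalar, term-by-term transcription of the 1984 two-population formulas.
oracle_wc_theta <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# -- LD pruning oracle -------------------------------------------------------

# Exhaustive replay of the documented greedy rule on a genotype matrix
# (single chromosome): scan windows, repeatedly find the first offending
# pair among retained columns and drop by the tie-break.
oracle_ld_prune_keep <- function(g, window, step, thr) {
  m <- ncol(g)
  nmiss <- colSums(is.na(g))
  r2 <- function(a, b) {
    ok <- !is.na(g[, a]) & !is.na(g[, b])
    if (sum(ok) < 2) return(NA_real_)
    x <- g[ok, a]; y <- g[ok, b]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }
  keep <- rep(TRUE, m)
  for (s in seq(1, m, by = step)) {
    win <- s:min(s + window - 1, m)
    if (length(win) < 2) next
    repeat {
      ret <- win[keep[win]]
      if (length(ret) < 2) break
      removed <- FALSE
      for (ai in seq_len(length(ret) - 1)) {
        for (bi in (ai + 1):length(ret)) {
          v <- r2(ret[ai], ret[bi])
          if (!is.na(v) && v > thr) {
            i <- ret[ai]; j <- ret[bi]
            drop <- if (nmiss[i] > nmiss[j]) i
                    else if (nmiss[j] > nmiss[i]) j else max(i, j)
            keep[drop] <- FALSE
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!removed) break
    }
  }
  which(keep)
}

# -- consensus recount -------------------------------------------------------

# Independent point-sampling recount: at a grid of points inside a region's
# core, count distinct methods covering each point.
recount_min_coverage <- function(intervals, chromosome, core_start, core_end,
                                 n_points = 25) {
  pts <- unique(round(seq(core_start, core_end, length.out = n_points)))
  sapply(pts, function(x) {
    hit <- intervals$chromosome == chromosome &
      intervals$start_bp <= x & intervals$end_bp >= x
    length(unique(intervals$method[hit]))
  })
}

# Random interval set builder for consensus property tests.
random_interval_sets <- function(seed, n_methods = 3, max_per = 4,
                                 span = 1e6) {
  withr::with_seed(seed, {
    labels <- paste0("M", seq_len(n_methods))
    out <- lapply(labels, function(l) {
      k <- sample.int(max_per, 1)
      st <- sort(sample.int(span, k))
      en <- st + sample.int(span / 4, k)
      tibble::tibble(chromosome = "1", start_bp = st, end_bp = en)
    })
    names(out) <- labels
    out
  })
}
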