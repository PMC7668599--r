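#' Default log-spaced LD distance bins
#'
#' Twenty log-spaced physical-distance bins from 50 kb to 10 Mb, the range
#' whose implied time depths span roughly the last 500 generations for a
#' 1 cM/Mb genome.
#'
#' @param n_bins Number of bins (default 20).
#' @param min_bp,max_bp Overall distance range (defaults 5e4 and 1e7).
#' @return A tibble with `dist_lo_bp`, `dist_hi_bp`.
#' @export
default_ld_bins <- function(n_bins = 20L, min_bp = 5e4, max_bp = 1e7) {
  edges <- exp(seq(log(min_bp), log(max_bp), length.out = n_bins + 1))
  tibble::tibble(dist_lo_bp = edges[-length(edges)], dist_hi_bp = edges[-1])
}

#' Mean LD (r-squared) in physical-distance bins
#'
#' For one population, computes squared Pearson correlations of genotype
#' dosages for same-chromosome SNP pairs, bins them by base-pair distance
#' (`lo <= d < hi`) and reports per-bin means. Only SNPs with a
#' minor-allele frequency strictly above `min_maf` in the population are
#' used. Bins holding more than `max_pairs_per_bin` pairs are represented by
#' a seeded uniform subsample. The sample-size-corrected mean,
#' `mean_r2_adj`, subtracts the expected inflation `1/n` for unphased
#' genotypes (`1/(2n)` if `phased = TRUE`).
#'
#' @param data A [genotype_dataset()].
#' @param population Population label.
#' @param bins A tibble with `dist_lo_bp`, `dist_hi_bp` (non-overlapping;
#'   default [default_ld_bins()]).
#' @param min_maf MAF strictly required of every SNP used (default 0.05).
#' @param max_pairs_per_bin Subsampling cap per bin (default 1e6).
#' @param seed Integer seed for the subsample.
#' @param phased Use the phased-haplotype correction `1/(2n)` instead of the
#'   unphased `1/n` (default FALSE).
#' @return A tibble: `dist_lo_bp`, `dist_hi_bp`, `midpoint_bp`, `n_pairs`,
#'   `mean_r2`, `mean_r2_adj`, with the population's sample count as the
#'   `n_samples` attribute.
#' @export
binned_r2 <- function(data, population, bins = default_ld_bins(),
                      min_maf = 0.05, max_pairs_per_bin = 1e6, seed = 1L,
                      phased = FALSE) {
  g <- population_genotypes(data, population)
  n <- nrow(g)
  if (n < 2) stop("population has fewer than 2 samples")
  if (n < 10) warning("population has fewer than 10 samples; ",
                      "LD-based estimates will be unstable")
  bins <- dplyr::arrange(tibble::as_tibble(bins), .data$dist_lo_bp)
  if (any(bins$dist_lo_bp[-1] < bins$dist_hi_bp[-nrow(bins)])) {
    stop("bins must be non-overlapping")
  }

  p <- colMeans(g, na.rm = TRUE) / 2
  maf_ok <- !is.na(p) & pmin(p, 1 - p) > min_maf
  max_d <- max(bins$dist_hi_bp)

  acc_i <- list(); acc_j <- list(); acc_d <- list(); nacc <- 0L
  for (chr in unique(data$snps$chromosome)) {
    vi <- which(data$snps$chromosome == chr & maf_ok)
    if (length(vi) < 2) next
    pos <- data$snps$position_bp[vi]
    hi <- findInterval(pos + max_d, pos)  # last j with pos[j] <= pos[i]+max_d
    for (a in seq_along(vi)) {
      if (hi[a] <= a) next
      b <- (a + 1):hi[a]
      nacc <- nacc + 1L
      acc_i[[nacc]] <- rep(vi[a], length(b))
      acc_j[[nacc]] <- vi[b]
      acc_d[[nacc]] <- as.numeric(pos[b] - pos[a])
    }
  }
  ii <- unlist(acc_i); jj <- unlist(acc_j); dd <- unlist(acc_d)
  if (is.null(ii)) { ii <- integer(0); jj <- integer(0); dd <- numeric(0) }
  bn <- findInterval(dd, bins$dist_lo_bp)
  in_bin <- bn >= 1 & dd < bins$dist_hi_bp[pmax(bn, 1L)]
  bin_of <- as.integer(ifelse(in_bin, bn, 0L))

  keep <- withr::with_seed(seed, {
    k <- rep(TRUE, length(dd))
    for (bn in seq_len(nrow(bins))) {
      at <- which(bin_of == bn)
      if (length(at) > max_pairs_per_bin) {
        k[at] <- FALSE
        k[sample(at, max_pairs_per_bin)] <- TRUE
      }
    }
    k
  })
  keep <- keep & bin_of > 0L
  ii <- ii[keep]; jj <- jj[keep]; bin_of <- bin_of[keep]

  r2 <- pairwise_r2(g, ii, jj)
  corr <- if (phased) 1 / (2 * n) else 1 / n
  out <- bins
  out$midpoint_bp <- (bins$dist_lo_bp + bins$dist_hi_bp) / 2
  out$n_pairs <- as.integer(tabulate(bin_of, nbins = nrow(bins)))
  sums <- vapply(seq_len(nrow(bins)), function(bn)
    sum(r2[bin_of == bn], na.rm = TRUE), numeric(1))
  nn <- vapply(seq_len(nrow(bins)), function(bn)
    sum(!is.na(r2[bin_of == bn])), numeric(1))
  out$mean_r2 <- ifelse(nn > 0, sums / nn, NA_real_)
  out$mean_r2_adj <- out$mean_r2 - corr
  attr(out, "n_samples") <- n
  out
}

# r2 of many column pairs of a genotype matrix, pairwise-complete over
# missing calls, vectorised across pairs in chunks.
pairwise_r2 <- function(g, ii, jj, chunk = 2e5) {
  P <- length(ii)
  if (P == 0) return(numeric(0))
  M <- !is.na(g)
  X <- g; X[!M] <- 0L
  storage.mode(X) <- "double"
  storage.mode(M) <- "double"
  out <- numeric(P)
  for (from in seq(1, P, by = chunk)) {
    to <- min(from + chunk - 1, P)
    ia <- ii[from:to]; ib <- jj[from:to]
    xa <- X[, ia, drop = FALSE]; xb <- X[, ib, drop = FALSE]
    ma <- M[, ia, drop = FALSE]; mb <- M[, ib, drop = FALSE]
    joint <- ma * mb
    nab <- colSums(joint)
    sa <- colSums(xa * joint); sb <- colSums(xb * joint)
    saa <- colSums(xa^2 * joint); sbb <- colSums(xb^2 * joint)
    sab <- colSums(xa * xb * joint)
    num <- nab * sab - sa * sb
    den <- (nab * saa - sa^2) * (nab * sbb - sb^2)
    r2 <- ifelse(nab >= 2 & den > 0, num^2 / den, NA_real_)
    out[from:to] <- r2
  }
  out
}

# physical (Morgans) -> recombination fraction mappings
recomb_mapping <- function(d, mapping) {
  switch(mapping,
    sved_feldman = d / (1 + 2 * d),
    haldane = (1 - exp(-2 * d)) / 2,
    linear = d,
    stop("unknown mapping: ", mapping)
  )
}

#' Effective population size from binned LD
#'
#' Converts each LD bin into a point on an N_E trajectory. The bin midpoint
#' distance `d` (Morgans; physical distance times `cm_per_mb`) is mapped to
#' a recombination fraction `c` (Sved & Feldman mapping `c = d/(1+2d)` by
#' default; Haldane `c = (1-e^{-2d})/2` and `linear` `c = d` available),
#' giving the time depth `t = 1/(2c)` generations ago and
#' `N_E(t) = (1/(4c)) * (1/mean_r2_adj - alpha_mut)`, where `alpha_mut`
#' adjusts for mutation (2.2 by default). Bins whose corrected r-squared is
#' non-positive or that yield a negative N_E are flagged invalid and
#' excluded with a warning.
#'
#' @param bins A tibble from [binned_r2()].
#' @param alpha_mut Mutation adjustment constant (default 2.2).
#' @param cm_per_mb Genetic map density, cM per Mb (default 1.0, the cattle
#'   genome-wide average).
#' @param mapping `"sved_feldman"` (default), `"haldane"` or `"linear"`.
#' @return An object of class `ne_trajectory`: list with `points` (tibble
#'   `t`, `ne`, `c`, `d_morgans`, `midpoint_bp`, `n_pairs`, `mean_r2_adj`,
#'   sorted by `t` ascending) and metadata fields `mapping`, `alpha_mut`,
#'   `cm_per_mb`, `n_excluded`.
#' @export
ne_from_r2 <- function(bins, alpha_mut = 2.2, cm_per_mb = 1.0,
                       mapping = c("sved_feldman", "haldane", "linear")) {
  mapping <- match.arg(mapping)
  bins <- tibble::as_tibble(bins)
  d <- bins$midpoint_bp * cm_per_mb / 100 / 1e6
  cc <- recomb_mapping(d, mapping)
  valid <- !is.na(bins$mean_r2_adj) & bins$mean_r2_adj > 0 & bins$n_pairs > 0
  ne <- ifelse(valid, (1 / (4 * cc)) * (1 / bins$mean_r2_adj - alpha_mut),
               NA_real_)
  bad <- valid & ne < 0
  if (any(bad)) {
    warning(sum(bad), " bin(s) yielded negative N_E and were excluded")
  }
  ok <- valid & !bad
  if (sum(!ok & bins$n_pairs > 0) > 0 && !any(bad)) {
    # bins empty of pairs or with non-positive corrected r2
    warning(sum(!ok), " bin(s) excluded (no pairs or non-positive ",
            "corrected r-squared)")
  }
  points <- tibble::tibble(
    t = 1 / (2 * cc[ok]),
    ne = ne[ok],
    c = cc[ok],
    d_morgans = d[ok],
    midpoint_bp = bins$midpoint_bp[ok],
    n_pairs = bins$n_pairs[ok],
    mean_r2_adj = bins$mean_r2_adj[ok]
  ) |> dplyr::arrange(.data$t)
  structure(list(points = points, mapping = mapping, alpha_mut = alpha_mut,
                 cm_per_mb = cm_per_mb, n_excluded = sum(!ok)),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("<ne_trajectory> ", nrow(x$points), " points (", x$mapping,
      " mapping, alpha = ", x$alpha_mut, ", ", x$cm_per_mb, " cM/Mb)\n",
      sep = "")
  print(x$points)
  invisible(x)
}

#' @rdname ne_from_r2
#' @param x An `ne_trajectory`.
#' @param ... Unused.
#' @export
tidy.ne_trajectory <- function(x, ...) x$points

#' @rdname ne_from_r2
#' @export
glance.ne_trajectory <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points), mapping = x$mapping,
                 alpha_mut = x$alpha_mut, cm_per_mb = x$cm_per_mb,
                 ne_most_recent = if (nrow(x$points)) x$points$ne[1] else NA_real_,
                 t_most_recent = if (nrow(x$points)) x$points$t[1] else NA_real_)
}

#' N_E-changing ratio (normalised trajectory slopes)
#'
#' For each pair of neighbouring trajectory points (sorted by time depth),
#' the slope `(ne2 - ne1) / (t2 - t1)` normalised by the median N_E of the
#' `window_recent` most recent (smallest-`t`) points. Large negative values
#' flag episodes of accelerated decline.
#'
#' @param traj An `ne_trajectory` from [ne_from_r2()].
#' @param window_recent How many recent points define the normalising
#'   median (default 50).
#' @return A tibble: `t_mid`, `slope`, `nec`.
#' @export
nec_slopes <- function(traj, window_recent = 50L) {
  pts <- dplyr::arrange(traj$points, .data$t)
  if (nrow(pts) < 2) stop("need at least 2 trajectory points")
  if (anyDuplicated(pts$t)) stop("duplicate time depths make slopes degenerate")
  med <- stats::median(utils::head(pts$ne, window_recent))
  n <- nrow(pts)
  slope <- diff(pts$ne) / diff(pts$t)
  tibble::tibble(
    t_mid = (pts$t[-n] + pts$t[-1]) / 2,
    slope = slope,
    nec = slope / med
  )
}
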