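#' Simulate structured populations (Balding-Nichols model)
#'
#' Generates diploid biallelic genotypes for `n_pops` populations whose
#' allele frequencies diverge around shared ancestral frequencies to a
#' target F_ST. Ancestral frequencies are uniform on [0.05, 0.95]; each
#' population's frequency is Beta-distributed with mean `p` and variance
#' `fst * p * (1 - p)` (shape parameters `p(1-F)/F` and `(1-p)(1-F)/F`);
#' genotypes are Binomial(2, p_pop) per sample, so Hardy-Weinberg holds
#' within populations. SNP positions are uniform along the chromosomes
#' (allocated proportionally to length) and sorted; missing calls are
#' dropped uniformly at `missing_rate`. With `fst = 0` all populations
#' share the ancestral frequencies exactly.
#'
#' The defaults mirror a small livestock breed-comparison design: two to
#' three populations of a few dozen samples on a 3 x 50 Mb genome.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Samples per population (recycled to length `n_pops`).
#' @param n_snps Total SNP count.
#' @param fst Target differentiation in `[0, 1)`.
#' @param chromosomes Numeric vector of chromosome lengths in bp
#'   (default three 50 Mb autosomes).
#' @param missing_rate Per-call missing probability (default 0).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param pop_names Population labels (default `pop1`, `pop2`, ...).
#' @return A list with `data` (a [genotype_dataset()]) and `truth` (list:
#'   `target_fst`, `ancestral_p`, `pop_freqs` matrix, `seed`).
#' @export
#' @examples
#' sim <- simulate_populations(2, 30, 5000, fst = 0.09, seed = 42)
#' genome_wide_fst(wc_fst_pair(sim$data, "pop1", "pop2"))
simulate_populations <- function(n_pops = 2L, n_per_pop = 30L,
                                 n_snps = 10000L, fst = 0.09,
                                 chromosomes = rep(50e6, 3),
                                 missing_rate = 0, seed = 1L,
                                 pop_names = paste0("pop", seq_len(n_pops))) {
  stopifnot(fst >= 0, fst < 1, n_pops >= 1, n_snps >= 1)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  withr::with_seed(seed, {
    p_anc <- stats::runif(n_snps, 0.05, 0.95)
    pop_freqs <- matrix(NA_real_, n_snps, n_pops,
                        dimnames = list(NULL, pop_names))
    for (k in seq_len(n_pops)) {
      pop_freqs[, k] <- if (fst == 0) p_anc else {
        stats::rbeta(n_snps, p_anc * (1 - fst) / fst,
                     (1 - p_anc) * (1 - fst) / fst)
      }
    }
    n_total <- sum(n_per_pop)
    geno <- matrix(NA_integer_, n_total, n_snps)
    row0 <- 0L
    for (k in seq_len(n_pops)) {
      nk <- n_per_pop[k]
      geno[row0 + seq_len(nk), ] <- matrix(
        stats::rbinom(nk * n_snps, 2L, rep(pop_freqs[, k], each = nk)),
        nk, n_snps)
      row0 <- row0 + nk
    }
    if (missing_rate > 0) {
      geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
    }

    chrom_of <- sample(rep(seq_along(chromosomes),
                           times = round_alloc(n_snps, chromosomes)))
    pos <- as.integer(floor(stats::runif(n_snps) *
                              chromosomes[chrom_of]) + 1)
    # dedupe positions within chromosome deterministically
    key <- paste(chrom_of, pos)
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      pos[dup] <- pos[dup] + 1L
      key <- paste(chrom_of, pos)
    }
    ord <- order(chrom_of, pos)

    samples <- tibble::tibble(
      sample_id = unlist(lapply(seq_len(n_pops), function(k)
        sprintf("%s_%02d", pop_names[k], seq_len(n_per_pop[k])))),
      population = rep(pop_names, times = n_per_pop)
    )
    snps <- tibble::tibble(
      snp_id = sprintf("snp%06d", seq_len(n_snps)),
      chromosome = as.character(chrom_of),
      position_bp = pos,
      allele_ref = "A", allele_alt = "B"
    )
    data <- genotype_dataset(samples, snps[ord, ], geno[, ord, drop = FALSE])
    truth <- list(target_fst = fst, ancestral_p = p_anc[ord],
                  pop_freqs = pop_freqs[ord, , drop = FALSE], seed = seed)
    list(data = data, truth = truth)
  })
}

# integer allocation of n items proportional to weights, summing to n
round_alloc <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plant autozygous segments
#'
#' Rewrites the genotypes of chosen samples homozygous within given
#' intervals, creating ground-truth runs of homozygosity for detector
#' validation. Within an interval every SNP call of the sample becomes 0 or
#' 2, drawn once per SNP by the ALT allele frequency in the sample's
#' population (so planted runs have realistic allele content). The truth
#' records the bp of the first and last SNP actually covered.
#'
#' Planting rewrites genotypes rather than simulating identity-by-descent;
#' that is sufficient ground truth for testing detection, not a model of
#' inbreeding.
#'
#' @param data A [genotype_dataset()].
#' @param spec A data frame: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive). Intervals of one sample must not overlap.
#' @param seed Integer seed.
#' @param delimit_flanks Number of SNPs immediately outside each planted
#'   interval to force heterozygous in the carrier (default 0). Without
#'   delimiting, chance homozygosity at the flanks leaves the true run
#'   boundary ambiguous; with `delimit_flanks` of at least
#'   `max_het_in_run + 1` the detectable run ends exactly at the planted
#'   edge, which is what boundary-recovery studies need.
#' @return A list with `data` (modified dataset) and `truth` (tibble:
#'   `sample_id`, `chromosome`, `start_bp`, `end_bp`, `first_snp_bp`,
#'   `last_snp_bp`, `n_snps`; plus attribute `seed`).
#' @export
plant_autozygous_segments <- function(data, spec, seed = 1L,
                                      delimit_flanks = 0L) {
  spec <- tibble::as_tibble(spec)
  if (nrow(spec) == 0) {
    return(list(data = data,
                truth = tibble::tibble(sample_id = character(),
                                       chromosome = character(),
                                       start_bp = numeric(), end_bp = numeric(),
                                       first_snp_bp = integer(),
                                       last_snp_bp = integer(),
                                       n_snps = integer())))
  }
  spec$chromosome <- as.character(spec$chromosome)
  # overlap check per sample
  by_s <- split(spec, paste(spec$sample_id, spec$chromosome))
  for (s in by_s) {
    if (nrow(s) < 2) next
    s <- s[order(s$start_bp), ]
    if (any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
      stop("overlapping planted intervals for sample ", s$sample_id[1])
    }
  }
  geno <- data$genotypes
  truth <- spec
  truth$first_snp_bp <- NA_integer_
  truth$last_snp_bp <- NA_integer_
  truth$n_snps <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(nrow(spec))) {
      si <- match(spec$sample_id[r], data$samples$sample_id)
      if (is.na(si)) stop("unknown sample: ", spec$sample_id[r])
      vi <- which(data$snps$chromosome == spec$chromosome[r] &
                    data$snps$position_bp >= spec$start_bp[r] &
                    data$snps$position_bp <= spec$end_bp[r])
      if (!length(vi)) {
        warning("planted interval contains no SNPs: ", spec$sample_id[r],
                " chr", spec$chromosome[r])
        next
      }
      pop <- data$samples$population[si]
      in_pop <- data$samples$population == pop
      p <- colMeans(geno[in_pop, vi, drop = FALSE], na.rm = TRUE) / 2
      p[is.nan(p)] <- 0.5
      geno[si, vi] <- 2L * stats::rbinom(length(vi), 1L, p)
      if (delimit_flanks > 0) {
        on_chr <- which(data$snps$chromosome == spec$chromosome[r])
        before <- on_chr[on_chr < vi[1]]
        after <- on_chr[on_chr > vi[length(vi)]]
        flank <- c(utils::tail(before, delimit_flanks),
                   utils::head(after, delimit_flanks))
        if (length(flank)) geno[si, flank] <- 1L
      }
      truth$first_snp_bp[r] <- data$snps$position_bp[vi[1]]
      truth$last_snp_bp[r] <- data$snps$position_bp[vi[length(vi)]]
      truth$n_snps[r] <- length(vi)
    }
  })
  out <- genotype_dataset(data$samples, data$snps, geno)
  attr(truth, "seed") <- seed
  list(data = out, truth = truth)
}

#' Plant a differentiated region
#'
#' Redraws one population's genotypes inside a region from allele
#' frequencies shifted by `freq_shift` (clipped to [0.01, 0.99]), creating
#' ground truth for top-fraction F_ST sweep selection.
#'
#' @param data A [genotype_dataset()].
#' @param pop_a,pop_b Population labels; only `pop_b` is modified.
#' @param chromosome,start_bp,end_bp Region (1-based inclusive); must
#'   contain at least 5 SNPs.
#' @param freq_shift Added to `pop_b`'s current ALT frequencies (may be
#'   negative; 0 triggers a no-op warning).
#' @param seed Integer seed.
#' @return A list with `data` and `truth` (list: region bounds, SNP ids
#'   inside, `freq_shift`, `seed`).
#' @export
plant_differentiated_region <- function(data, pop_a, pop_b, chromosome,
                                        start_bp, end_bp, freq_shift,
                                        seed = 1L) {
  chromosome <- as.character(chromosome)
  vi <- which(data$snps$chromosome == chromosome &
                data$snps$position_bp >= start_bp &
                data$snps$position_bp <= end_bp)
  if (length(vi) < 5) stop("region must contain at least 5 SNPs, found ",
                           length(vi))
  in_b <- data$samples$population == pop_b
  if (!any(in_b)) stop("unknown population: ", pop_b)
  if (freq_shift == 0) {
    warning("freq_shift = 0: planting is a no-op")
    return(list(data = data,
                truth = list(chromosome = chromosome, start_bp = start_bp,
                             end_bp = end_bp,
                             snp_ids = data$snps$snp_id[vi],
                             freq_shift = 0, seed = seed)))
  }
  geno <- data$genotypes
  withr::with_seed(seed, {
    p <- colMeans(geno[in_b, vi, drop = FALSE], na.rm = TRUE) / 2
    p[is.nan(p)] <- 0.5
    p_new <- pmin(pmax(p + freq_shift, 0.01), 0.99)
    nb <- sum(in_b)
    geno[in_b, vi] <- matrix(
      stats::rbinom(nb * length(vi), 2L, rep(p_new, each = nb)),
      nb, length(vi))
  })
  out <- genotype_dataset(data$samples, data$snps, geno)
  truth <- list(chromosome = chromosome, start_bp = start_bp,
                end_bp = end_bp, snp_ids = data$snps$snp_id[vi],
                freq_shift = freq_shift, seed = seed)
  list(data = out, truth = truth)
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete-generation, random-mating Wright-Fisher population of
#' `n_diploids` individuals on a single chromosome of `chrom_morgans`
#' Morgans. Initial haplotype alleles are drawn independently with SNP
#' frequencies uniform on [0.1, 0.9]; each offspring gamete recombines its
#' parent's two haplotypes at Poisson(`chrom_morgans`) crossover points
#' placed uniformly on the genetic map. After `generations` generations a
#' sample of `sample_size` diploids is returned; SNPs that fixed during the
#' simulation are dropped and counted. Physical positions assume 1 cM/Mb
#' (1 Morgan = 100 Mb).
#'
#' @param n_diploids Population size (>= 20).
#' @param generations Number of generations (>= 4 x `n_diploids`
#'   recommended so LD reaches drift-recombination equilibrium).
#' @param chrom_morgans Chromosome genetic length in Morgans.
#' @param n_snps Number of SNPs.
#' @param sample_size Diploids sampled from the final generation.
#' @param seed Integer seed.
#' @return A list with `data` (a [genotype_dataset()], population label
#'   `"wf"`) and `truth` (list: `true_ne`, `generations`, `chrom_morgans`,
#'   `n_monomorphic_dropped`, `seed`).
#' @export
simulate_wf_ld <- function(n_diploids = 100L, generations = 400L,
                           chrom_morgans = 0.5, n_snps = 2000L,
                           sample_size = 50L, seed = 1L) {
  stopifnot(n_diploids >= 20, sample_size <= n_diploids, n_snps >= 2)
  withr::with_seed(seed, {
    gpos <- sort(stats::runif(n_snps, 0, chrom_morgans))
    p0 <- stats::runif(n_snps, 0.1, 0.9)
    H <- matrix(stats::rbinom(n_snps * 2 * n_diploids, 1L, p0),
                n_snps, 2 * n_diploids)
    for (gen in seq_len(generations)) {
      H <- wf_next_generation(H, gpos, chrom_morgans, n_diploids)
    }
    idx <- sample.int(n_diploids, sample_size)
    geno <- H[, 2 * idx - 1, drop = FALSE] + H[, 2 * idx, drop = FALSE]
    mono <- rowSums(geno) == 0 | rowSums(geno) == 2 * sample_size
    if (all(mono)) {
      stop("all SNPs fixed; increase n_snps or reduce generations")
    }
    keep <- which(!mono)
    pos_bp <- as.integer(round(gpos * 1e8))  # 1 cM/Mb
    pos_bp <- pos_bp + seq_along(pos_bp)     # break exact ties, keep order
    samples <- tibble::tibble(
      sample_id = sprintf("wf_%03d", seq_len(sample_size)),
      population = "wf")
    snps <- tibble::tibble(
      snp_id = sprintf("wfsnp%05d", keep),
      chromosome = "1",
      position_bp = pos_bp[keep],
      allele_ref = "A", allele_alt = "B")
    data <- genotype_dataset(samples, snps, t(geno[keep, , drop = FALSE]))
    truth <- list(true_ne = n_diploids, generations = generations,
                  chrom_morgans = chrom_morgans,
                  n_monomorphic_dropped = sum(mono), seed = seed)
    list(data = data, truth = truth)
  })
}

# One Wright-Fisher generation: 2N gametes from randomly chosen parents.
# Zero-crossover gametes (the common case for short maps) are a single
# column copy; recombinant gametes interleave parental haplotypes at
# uniform crossover points.
wf_next_generation <- function(H, gpos, chrom_morgans, n_diploids) {
  n_gam <- 2L * n_diploids
  parent <- sample.int(n_diploids, n_gam, replace = TRUE)
  ncross <- stats::rpois(n_gam, chrom_morgans)
  start_hap <- sample.int(2L, n_gam, replace = TRUE) - 1L
  Hnew <- matrix(0L, nrow(H), n_gam)
  plain <- ncross == 0L
  if (any(plain)) {
    Hnew[, plain] <- H[, 2L * parent[plain] - 1L + start_hap[plain],
                       drop = FALSE]
  }
  for (k in which(!plain)) {
    breaks <- sort(stats::runif(ncross[k], 0, chrom_morgans))
    seg <- findInterval(gpos, breaks)
    use_b <- (seg + start_hap[k]) %% 2L == 1L
    a <- H[, 2L * parent[k] - 1L]
    a[use_b] <- H[use_b, 2L * parent[k]]
    Hnew[, k] <- a
  }
  Hnew
}
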