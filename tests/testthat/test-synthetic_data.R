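test_that("generators are pure functions of parameters and seed", {
  a <- simulate_populations(2, 10, 500, fst = 0.1, missing_rate = 0.02,
                            seed = 7)
  b <- simulate_populations(2, 10, 500, fst = 0.1, missing_rate = 0.02,
                            seed = 7)
  expect_identical(a$data$genotypes, b$data$genotypes)
  expect_identical(a$data$snps, b$data$snps)
  c <- simulate_populations(2, 10, 500, fst = 0.1, missing_rate = 0.02,
                            seed = 8)
  expect_false(identical(a$data$genotypes, c$data$genotypes))

  w1 <- simulate_wf_ld(20, 30, 0.5, 200, 10, seed = 5)
  w2 <- simulate_wf_ld(20, 30, 0.5, 200, 10, seed = 5)
  expect_identical(w1$data$genotypes, w2$data$genotypes)
})

test_that("simulated datasets satisfy container invariants and round-trip", {
  sim <- simulate_populations(3, c(8, 6, 5), 400, fst = 0.08,
                              missing_rate = 0.03, seed = 13)
  gd <- sim$data
  expect_equal(nrow(gd$samples), 19)
  expect_equal(n_snps(gd), 400)
  for (chr in unique(gd$snps$chromosome)) {
    pos <- gd$snps$position_bp[gd$snps$chromosome == chr]
    expect_true(all(diff(pos) > 0))
  }
  expect_true(all(gd$genotypes %in% c(0L, 1L, 2L, NA)))

  prefix <- file.path(withr::local_tempdir(), "sim")
  write_plink(gd, prefix, "binary")
  back <- read_plink(prefix)
  expect_identical(unname(back$genotypes), unname(gd$genotypes))
})

test_that("Balding-Nichols output matches its target differentiation", {
  # null case: fst = 0 -> weighted estimate within +-0.01
  sim0 <- simulate_populations(2, 30, 10000, fst = 0, seed = 101)
  gw0 <- genome_wide_fst(wc_fst_pair(sim0$data, "pop1", "pop2"))
  expect_lt(abs(gw0$ratio_of_sums), 0.01)

  # moderate differentiation recovers near the target
  sim <- simulate_populations(2, 30, 20000, fst = 0.09, seed = 102)
  gw <- genome_wide_fst(wc_fst_pair(sim$data, "pop1", "pop2"))
  expect_gt(gw$ratio_of_sums, 0.07)
  expect_lt(gw$ratio_of_sums, 0.11)
})

test_that("Hardy-Weinberg holds marginally within simulated populations", {
  # large sample and common alleles keep the chi-square approximation
  # honest (all expected genotype counts comfortably above 5)
  sim <- simulate_populations(1, 150, 4000, fst = 0, seed = 301)
  g <- sim$data$genotypes
  pvals <- apply(g, 2, function(col) {
    n <- length(col)
    p <- mean(col) / 2
    if (p < 0.2 || p > 0.8) return(NA_real_)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(col + 1L, 3)
    x2 <- sum((obs - expd)^2 / expd)
    # 1 df: the allele frequency is estimated from the same sample
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  })
  rej <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("planted autozygous segments are recovered by the detector", {
  sim <- simulate_populations(1, 6, 1200, fst = 0, seed = 201,
                              chromosomes = c(30e6, 30e6))
  spec <- tibble::tibble(sample_id = c("pop1_01", "pop1_01", "pop1_03"),
                         chromosome = c("1", "2", "1"),
                         start_bp = c(5e6, 10e6, 20e6),
                         end_bp = c(8e6, 14e6, 24e6))
  pl <- plant_autozygous_segments(sim$data, spec, seed = 202,
                                  delimit_flanks = 2)
  seg <- detect_roh(pl$data, roh_params(min_snps = 31, min_length_bp = 1e6))
  for (r in seq_len(nrow(spec))) {
    hit <- seg[seg$sample_id == spec$sample_id[r] &
                 seg$chromosome == spec$chromosome[r] &
                 seg$start_bp <= pl$truth$first_snp_bp[r] + 1 &
                 seg$end_bp >= pl$truth$last_snp_bp[r] - 1, ]
    expect_equal(nrow(hit), 1, info = paste("interval", r))
    expect_equal(hit$start_bp, pl$truth$first_snp_bp[r])
    expect_equal(hit$end_bp, pl$truth$last_snp_bp[r])
  }

  # empty spec is a no-op
  pl0 <- plant_autozygous_segments(sim$data, spec[0, ], seed = 1)
  expect_identical(pl0$data$genotypes, sim$data$genotypes)

  # overlapping intervals for one sample -> error
  bad <- tibble::tibble(sample_id = "pop1_01", chromosome = "1",
                        start_bp = c(1e6, 2e6), end_bp = c(3e6, 4e6))
  expect_error(plant_autozygous_segments(sim$data, bad), "overlapping")
})

test_that("F_ROH matches the planted autozygous fraction", {
  sim <- simulate_populations(1, 4, 3000, fst = 0, seed = 211,
                              chromosomes = c(50e6, 50e6))
  spec <- tibble::tibble(sample_id = "pop1_02", chromosome = c("1", "2"),
                         start_bp = c(10e6, 5e6), end_bp = c(25e6, 15e6))
  pl <- plant_autozygous_segments(sim$data, spec, seed = 212,
                                  delimit_flanks = 2)
  seg <- detect_roh(pl$data, roh_params(min_snps = 31, min_length_bp = 1e6))
  sm <- summarize_roh(seg, pl$data, genome_bp = 100e6)
  froh <- sm$per_sample$froh[sm$per_sample$sample_id == "pop1_02"]
  expect_equal(froh, 25e6 / 100e6, tolerance = 0.01)
})

test_that("planted differentiated regions dominate the top-F_ST tail", {
  hits_inside <- vapply(1:5, function(seed) {
    sim <- simulate_populations(2, 25, 5000, fst = 0.02, seed = 400 + seed,
                                chromosomes = rep(50e6, 2))
    # pick a 20-SNP span on chromosome 1
    on1 <- which(sim$data$snps$chromosome == "1")
    lo <- sim$data$snps$position_bp[on1[200]]
    hi <- sim$data$snps$position_bp[on1[219]]
    pd <- plant_differentiated_region(sim$data, "pop1", "pop2", "1",
                                      lo, hi, freq_shift = 0.6,
                                      seed = 500 + seed)
    rec <- wc_fst_pair(pd$data, "pop1", "pop2")
    top <- select_top_fraction(rec, 0.001)
    inside <- top$chromosome == "1" & top$position_bp >= lo - 1 &
      top$position_bp <= hi + 1
    mean(inside)
  }, numeric(1))
  expect_gte(mean(hits_inside), 0.8)

  # shift 0 warns and leaves the top fraction unenriched
  sim <- simulate_populations(2, 25, 5000, fst = 0.02, seed = 451,
                              chromosomes = rep(50e6, 2))
  expect_warning(
    pd0 <- plant_differentiated_region(sim$data, "pop1", "pop2", "1",
                                       1e6, 10e6, freq_shift = 0,
                                       seed = 452),
    "no-op")
  expect_identical(pd0$data$genotypes, sim$data$genotypes)

  expect_error(plant_differentiated_region(sim$data, "pop1", "pop2", "1",
                                           1, 2, freq_shift = 0.5),
               "at least 5 SNPs")
})

test_that("candidate windows around planted hits overlap the truth region", {
  sim <- simulate_populations(2, 25, 4000, fst = 0.02, seed = 601,
                              chromosomes = 50e6)
  on1 <- which(sim$data$snps$chromosome == "1")
  lo <- sim$data$snps$position_bp[on1[1000]]
  hi <- sim$data$snps$position_bp[on1[1019]]
  pd <- plant_differentiated_region(sim$data, "pop1", "pop2", "1", lo, hi,
                                    freq_shift = 0.6, seed = 602)
  rec <- wc_fst_pair(pd$data, "pop1", "pop2")
  top <- select_top_fraction(rec, 0.001)
  win <- windows_from_snps(top, c("1" = 50e6))
  expect_true(any(win$start_bp <= hi & win$end_bp >= lo))
})

test_that("Wright-Fisher LD decays with distance unless recombination is off", {
  wf <- simulate_wf_ld(n_diploids = 50, generations = 150,
                       chrom_morgans = 0.5, n_snps = 600, sample_size = 40,
                       seed = 71)
  bins <- binned_r2(wf$data, "wf", tibble::tibble(
    dist_lo_bp = c(0, 20e6), dist_hi_bp = c(2e6, 50e6)), min_maf = 0.05)
  expect_gt(bins$mean_r2[1], bins$mean_r2[2])

  # zero map length: no recombination, so r2 does not decay with (index)
  # distance -- compare nearby and distant pairs on the degenerate map
  # (few generations: without recombination the whole chromosome drifts as
  # one locus and would otherwise fix entirely)
  wf0 <- simulate_wf_ld(n_diploids = 50, generations = 40,
                        chrom_morgans = 0, n_snps = 300, sample_size = 40,
                        seed = 72)
  n0 <- n_snps(wf0$data)
  span <- max(wf0$data$snps$position_bp)
  b0 <- binned_r2(wf0$data, "wf", tibble::tibble(
    dist_lo_bp = c(1, span * 0.5), dist_hi_bp = c(span * 0.1, span + 1)),
    min_maf = 0.05)
  expect_gte(b0$mean_r2[2], 0.8 * b0$mean_r2[1])
})
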