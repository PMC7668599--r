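test_that("minimum-SNP threshold follows the false-positive formula", {
  # direct high-precision evaluation: ln(0.05 / 5e6) / ln(0.64) ~ 41.28
  direct <- log(0.05 / (50000 * 100)) / log(1 - 0.36)
  expect_equal(min_snp_threshold(50000, 100, 0.05, 0.36), ceiling(direct))
  expect_equal(min_snp_threshold(50000, 100, 0.05, 0.36), 42L)

  # numerator ln(1) = 0 -> clamped to the floor
  expect_equal(min_snp_threshold(10, 10, alpha = 0.9999, het = 0.3,
                                 floor = 2L) >= 2L, TRUE)
  expect_equal(min_snp_threshold(1, 1, alpha = 0.99, het = 0.5), 2L)

  # monotonicity in ns, ni and het
  base <- min_snp_threshold(50000, 100, 0.05, 0.36)
  expect_gte(min_snp_threshold(100000, 100, 0.05, 0.36), base)
  expect_gte(min_snp_threshold(50000, 200, 0.05, 0.36), base)
  expect_lte(min_snp_threshold(50000, 100, 0.05, 0.50), base)

  expect_error(min_snp_threshold(100, 10, 0.05, het = 0), "het")
  expect_error(min_snp_threshold(100, 10, 0.05, het = 1), "het")
})

test_that("consecutive-runs detector handles the canonical cases", {
  # fully heterozygous sample -> no runs
  g <- matrix(1L, 1, 60)
  pos <- seq(1e5, by = 4e4, length.out = 60)
  gd <- dataset_from_matrix(g, pos)
  expect_equal(nrow(detect_roh(gd, roh_params(min_snps = 5))), 0)

  # 40 homozygous SNPs spanning 1.56 Mb with one interior heterozygote:
  # one run covering all 40 SNPs
  g2 <- matrix(1L, 1, 60)
  g2[1, 11:50] <- 0L
  g2[1, 30] <- 1L
  gd2 <- dataset_from_matrix(g2, pos)
  seg <- detect_roh(gd2, roh_params(min_snps = 31, min_length_bp = 1e6))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 40L)
  expect_equal(seg$start_bp, pos[11])
  expect_equal(seg$end_bp, pos[50])
  expect_equal(seg$n_het_inside, 1L)

  # two interior heterozygotes 5 SNPs apart: both flanking sub-runs fail
  # the 31-SNP minimum -> nothing reported
  g3 <- g2
  g3[1, 35] <- 1L
  gd3 <- dataset_from_matrix(g3, pos)
  expect_equal(nrow(detect_roh(gd3, roh_params(min_snps = 31,
                                               min_length_bp = 1e6))), 0)

  # a gap larger than max_gap_bp splits a run
  g4 <- matrix(0L, 1, 40)
  pos4 <- c(seq(1e5, by = 4e4, length.out = 20),
            seq(5e6, by = 4e4, length.out = 20))
  gd4 <- dataset_from_matrix(g4, pos4)
  seg4 <- detect_roh(gd4, roh_params(min_snps = 10, min_length_bp = 5e5,
                                     max_gap_bp = 1e6))
  expect_equal(nrow(seg4), 2)
})

test_that("detector agrees with the naive exhaustive scanner", {
  for (seed in 1:40) {
    gd <- random_dataset(seed, n_samples = 2, n_snps = 300, n_chrom = 2,
                         chrom_len = 8e6, p_het = 0.25, p_miss = 0.05)
    params <- roh_params(min_snps = 10, min_length_bp = 2e5,
                         max_gap_bp = 5e5)
    seg <- detect_roh(gd, params)
    for (si in 1:2) {
      for (chr in unique(gd$snps$chromosome)) {
        vi <- which(gd$snps$chromosome == chr)
        orc <- oracle_roh_runs(gd$genotypes[si, vi],
                               gd$snps$position_bp[vi],
                               max_het = 1, max_miss = 1, max_gap = 5e5,
                               min_snps = 10, min_len = 2e5)
        got <- seg[seg$sample_id == gd$samples$sample_id[si] &
                     seg$chromosome == chr, ]
        got <- got[order(got$start_bp), ]
        if (is.null(orc)) {
          expect_equal(nrow(got), 0, info = paste("seed", seed))
        } else {
          expect_equal(got$start_bp, gd$snps$position_bp[vi][orc[, "start"]],
                       info = paste("seed", seed))
          expect_equal(got$end_bp, gd$snps$position_bp[vi][orc[, "end"]],
                       info = paste("seed", seed))
        }
      }
    }
  }
})

test_that("runs never start or end on heterozygous or missing calls", {
  for (seed in 41:50) {
    gd <- random_dataset(seed, n_samples = 3, n_snps = 250, n_chrom = 1,
                         chrom_len = 6e6, p_het = 0.2, p_miss = 0.1)
    seg <- detect_roh(gd, roh_params(min_snps = 8, min_length_bp = 1e5,
                                     max_gap_bp = 1e6))
    if (!nrow(seg)) next
    pos <- gd$snps$position_bp
    for (r in seq_len(nrow(seg))) {
      si <- match(seg$sample_id[r], gd$samples$sample_id)
      gstart <- gd$genotypes[si, match(seg$start_bp[r], pos)]
      gend <- gd$genotypes[si, match(seg$end_bp[r], pos)]
      expect_true(gstart %in% c(0L, 2L))
      expect_true(gend %in% c(0L, 2L))
      expect_lte(seg$n_het_inside[r], 1L)
      expect_lte(seg$n_missing_inside[r], 1L)
    }
  }
})

test_that("ROH summaries compute F_ROH and length classes", {
  seg <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"), population = "p",
    chromosome = "1",
    start_bp = c(1e6, 10e6, 20e6),
    end_bp = c(1e6 + 125.5e6 / 2 - 1, 10e6 + 125.5e6 / 2 - 1, 23e6 - 1),
    n_snps = c(100L, 100L, 40L),
    length_bp = c(125.5e6 / 2, 125.5e6 / 2, 3e6),
    n_het_inside = 0L, n_missing_inside = 0L)
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            population = "p")
  sm <- summarize_roh(seg, samples, genome_bp = 2.51e9)
  # s1 totals 125.5 Mb -> F_ROH = 0.05; s3 has no segments -> 0
  expect_equal(sm$per_sample$froh[sm$per_sample$sample_id == "s1"], 0.05)
  expect_equal(sm$per_sample$froh[sm$per_sample$sample_id == "s3"], 0)
  # the 3 Mb segment: class [2,4); included in cumulative >1 and >2, not >4
  cls <- sm$per_class[sm$per_class$class == "[2,4)", ]
  expect_equal(cls$n_segments, 1L)
  cum <- sm$cumulative
  expect_equal(cum$n_segments[cum$min_mb == 2], 3L)
  expect_equal(cum$n_segments[cum$min_mb == 4], 2L)
  # empty input -> zeros
  sm0 <- summarize_roh(empty <- seg[0, ], samples)
  expect_true(all(sm0$per_sample$froh == 0))
})

test_that("island calling honours the strict majority rule", {
  # 10 samples, one chromosome, 200 SNPs; plant a shared segment in k
  # samples and check the carrier-fraction logic
  make_island_data <- function(k, seed) {
    sim <- simulate_populations(1, 10, 400, fst = 0, seed = seed,
                                chromosomes = 10e6)
    spec <- tibble::tibble(
      sample_id = sprintf("pop1_%02d", seq_len(k)),
      chromosome = "1", start_bp = 3e6, end_bp = 4.5e6)
    plant_autozygous_segments(sim$data, spec, seed = seed + 1,
                              delimit_flanks = 2)
  }
  pl6 <- make_island_data(6, 61)
  seg6 <- detect_roh(pl6$data, roh_params(min_length_bp = 3e5))
  res6 <- roh_incidence_and_islands(seg6, pl6$data, "pop1")
  expect_equal(nrow(res6$islands), 1)
  expect_equal(res6$islands$carrier_fraction, 0.6)
  expect_false(res6$islands$strongest)
  expect_gte(res6$islands$start_bp, 3e6)
  expect_lte(res6$islands$end_bp, 4.5e6)

  # exactly 50% is not "more than 50%"
  pl5 <- make_island_data(5, 62)
  seg5 <- detect_roh(pl5$data, roh_params(min_length_bp = 3e5))
  res5 <- roh_incidence_and_islands(seg5, pl5$data, "pop1")
  expect_equal(nrow(res5$islands), 0)

  # 8 of 10 -> strongest
  pl8 <- make_island_data(8, 63)
  seg8 <- detect_roh(pl8$data, roh_params(min_length_bp = 3e5))
  res8 <- roh_incidence_and_islands(seg8, pl8$data, "pop1")
  expect_equal(res8$islands$carrier_fraction, 0.8)
  expect_true(res8$islands$strongest)

  # per-SNP counting oracle inside the planted interval
  inside <- res6$incidence$position_bp >= 3e6 &
    res6$incidence$position_bp <= 4.5e6
  expect_true(all(res6$incidence$n_carriers[inside] == 6))

  expect_error(roh_incidence_and_islands(seg6, pl6$data, "ghost"),
               "unknown or empty")
})

test_that("islands within a population never overlap", {
  for (seed in 71:75) {
    sim <- simulate_populations(1, 8, 500, fst = 0, seed = seed,
                                chromosomes = c(8e6, 8e6))
    k <- 5 + (seed %% 3)
    spec <- dplyr::bind_rows(
      tibble::tibble(sample_id = sprintf("pop1_%02d", seq_len(k)),
                     chromosome = "1", start_bp = 2e6, end_bp = 3e6),
      tibble::tibble(sample_id = sprintf("pop1_%02d", seq_len(k)),
                     chromosome = "2", start_bp = 4e6, end_bp = 5.5e6))
    pl <- plant_autozygous_segments(sim$data, spec, seed = seed,
                                    delimit_flanks = 2)
    seg <- detect_roh(pl$data, roh_params(min_snps = 10,
                                          min_length_bp = 3e5))
    isl <- roh_incidence_and_islands(seg, pl$data, "pop1")$islands
    expect_gte(nrow(isl), 1)
    for (chr in unique(isl$chromosome)) {
      x <- isl[isl$chromosome == chr, ]
      x <- x[order(x$start_bp), ]
      if (nrow(x) > 1) {
        expect_true(all(x$start_bp[-1] > x$end_bp[-nrow(x)]))
      }
    }
  }
})

test_that("BED export converts to 0-based half-open coordinates", {
  seg <- tibble::tibble(chromosome = "3", start_bp = 101L, end_bp = 200L,
                        sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed_intervals(seg, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
})
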