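test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), rep(0.04, 4))  # hand BH: 4*p_(i)/i = 0.04 all
  expect_equal(as.numeric(q), p.adjust(p, "BH"))

  expect_equal(as.numeric(storey_qvalues(rep(1, 5))), rep(1, 5))

  withr::with_seed(8, {
    for (r in 1:20) {
      pv <- runif(sample(5:50, 1))
      q <- storey_qvalues(pv, pi0 = 1)
      expect_equal(as.numeric(q), p.adjust(pv, "BH"), tolerance = 1e-12)
      # monotone in p
      expect_true(all(diff(q[order(pv)]) >= -1e-12))
    }
  })

  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("pi0 estimation shrinks q-values under signal and stays sane", {
  # short vectors fall back to pi0 = 1
  expect_equal(attr(storey_qvalues(runif(20)), "pi0"), 1)
  withr::with_seed(12, {
    # mixture: 30% strong signals -> pi0 well below 1
    pv <- c(rbeta(600, 0.2, 8), runif(1400))
    q <- storey_qvalues(pv)
    expect_lt(attr(q, "pi0"), 1)
    expect_gt(attr(q, "pi0"), 0.4)
    # uniform nulls -> pi0 close to 1
    q0 <- storey_qvalues(runif(2000))
    expect_gt(attr(q0, "pi0"), 0.8)
  })
})

test_that("regions are seeded, extended, merged and ranked as specified", {
  mk_scan <- function(p) {
    tibble::tibble(snp_id = sprintf("m%03d", seq_along(p)),
                   chromosome = "1",
                   position_bp = seq_along(p) * 100000L, p_value = p)
  }
  # no SNP below 1e-3 -> no regions
  expect_equal(nrow(regions_from_pvalues(mk_scan(runif(50, 0.01, 1)),
                                         q_max = NULL)), 0)

  # single 1e-6 SNP flanked by p = 0.5 -> single-SNP region, strongest
  p <- rep(0.5, 21); p[11] <- 1e-6
  reg <- regions_from_pvalues(mk_scan(p), q_max = NULL)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start_bp, 11 * 100000L)
  expect_equal(reg$end_bp, 11 * 100000L)
  expect_equal(reg$n_snps, 1L)
  expect_true(reg$strongest)

  # two seeds whose -log10(p) > 1 extensions touch -> one merged region
  p2 <- rep(0.5, 30)
  p2[10] <- 1e-4; p2[14] <- 1e-4   # seeds
  p2[10:14] <- pmin(p2[10:14], 0.05)  # bridge above the extend threshold
  reg2 <- regions_from_pvalues(mk_scan(p2), q_max = NULL)
  expect_equal(nrow(reg2), 1)
  expect_equal(reg2$start_bp, 10 * 100000L)
  expect_equal(reg2$end_bp, 14 * 100000L)
  expect_false(reg2$strongest)

  # q-value condition can veto weak seeds: single p = 5e-4 among many
  # uniform nulls fails q <= 0.05
  withr::with_seed(44, {
    p3 <- c(runif(499, 0.2, 1), 5e-4)
    reg3 <- regions_from_pvalues(mk_scan(sample(p3)))
    expect_equal(nrow(reg3), 0)
  })

  expect_equal(nrow(regions_from_pvalues(mk_scan(numeric(0)))), 0)
})

test_that("scan tables round-trip through TSV import", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("a", "b"), Chr = c("1", "2"),
                   bp = c(100L, 200L), P = c(0.5, 1e-4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  scan <- read_scan_table(path, method_label = "HAPFLK")
  expect_equal(scan$snp_id, c("a", "b"))
  expect_equal(scan$p_value, c(0.5, 1e-4))
  expect_equal(attr(scan, "method_label"), "HAPFLK")
  expect_error(read_scan_table(withr::local_tempfile()), "file not found")
})

test_that("consensus follows the sweep-line >= 2-method rule", {
  # FST window 1-5 Mb and ROH island 3-8 Mb -> union extent 1-8 Mb,
  # core 3-5 Mb, both methods listed
  cr <- consensus_regions(list(
    FST = tibble::tibble(chromosome = "1", start_bp = 1e6, end_bp = 5e6),
    ROH50 = tibble::tibble(chromosome = "1", start_bp = 3e6, end_bp = 8e6)))
  expect_equal(nrow(cr$consensus), 1)
  expect_equal(cr$consensus$start_bp, 1e6)
  expect_equal(cr$consensus$end_bp, 8e6)
  expect_equal(cr$consensus$core_start_bp, 3e6)
  expect_equal(cr$consensus$core_end_bp, 5e6)
  expect_equal(cr$consensus$methods, "FST,ROH50")
  expect_equal(nrow(cr$unsupported), 0)

  # disjoint single-method intervals -> no consensus, both unsupported
  cr2 <- consensus_regions(list(
    FST = tibble::tibble(chromosome = "1", start_bp = 1e6, end_bp = 2e6),
    ROH50 = tibble::tibble(chromosome = "1", start_bp = 5e6, end_bp = 6e6)))
  expect_equal(nrow(cr2$consensus), 0)
  expect_equal(nrow(cr2$unsupported), 2)

  # three pairwise-overlapping methods with a common core -> one region
  # carrying all three labels
  cr3 <- consensus_regions(list(
    FST = tibble::tibble(chromosome = "2", start_bp = 1e6, end_bp = 4e6),
    HAPFLK = tibble::tibble(chromosome = "2", start_bp = 2e6, end_bp = 6e6),
    ROH50 = tibble::tibble(chromosome = "2", start_bp = 3e6, end_bp = 9e6)))
  expect_equal(nrow(cr3$consensus), 1)
  expect_equal(cr3$consensus$methods, "FST,HAPFLK,ROH50")
  expect_equal(cr3$consensus$n_methods, 3L)

  # two intervals of the SAME method do not make a consensus
  cr4 <- consensus_regions(list(
    FST = tibble::tibble(chromosome = "1", start_bp = c(1e6, 2e6),
                         end_bp = c(3e6, 4e6))))
  expect_equal(nrow(cr4$consensus), 0)

  expect_error(consensus_regions(
    stats::setNames(list(tibble::tibble(chromosome = "1", start_bp = 1,
                                        end_bp = 2)), "")), "named list")
})

test_that("consensus is order-symmetric and idempotent", {
  sets <- random_interval_sets(99, n_methods = 3)
  a <- consensus_regions(sets)
  b <- consensus_regions(rev(sets))
  expect_equal(a$consensus[order(a$consensus$start_bp),
                           c("start_bp", "end_bp", "core_start_bp",
                             "core_end_bp", "n_methods")],
               b$consensus[order(b$consensus$start_bp),
                           c("start_bp", "end_bp", "core_start_bp",
                             "core_end_bp", "n_methods")])
  if (nrow(a$consensus)) {
    again <- consensus_regions(
      list(CONS = a$consensus[, c("chromosome", "start_bp", "end_bp")]),
      min_methods = 1)
    expect_equal(again$consensus$start_bp, a$consensus$start_bp)
    expect_equal(again$consensus$end_bp, a$consensus$end_bp)
  }
})

test_that("every consensus core survives an independent coverage recount", {
  for (seed in 1:30) {
    sets <- random_interval_sets(seed, n_methods = 3)
    cr <- consensus_regions(sets)
    if (!nrow(cr$consensus)) next
    flat <- purrr::imap_dfr(sets, ~ dplyr::mutate(.x, method = .y))
    for (r in seq_len(nrow(cr$consensus))) {
      cores <- cr$consensus$core_intervals[[r]]
      for (k in seq_len(nrow(cores))) {
        cov <- recount_min_coverage(flat, cr$consensus$chromosome[r],
                                    cores$start_bp[k], cores$end_bp[k])
        expect_true(all(cov >= 2), info = paste("seed", seed, "region", r))
      }
    }
  }
})

test_that("gene annotation reports >= 1 bp overlaps in order", {
  regions <- tibble::tibble(chromosome = c("1", "1", "2"),
                            start_bp = c(15000, 50000, 1000),
                            end_bp = c(30000, 60000, 2000))
  genes <- tibble::tibble(
    chromosome = c("1", "1", "1", "2"),
    start_bp = c(10000, 29000, 40000, 3000),
    end_bp = c(20000, 35000, 49999, 4000),
    name = c("G1", "G2", "G3", "G4"))
  ann <- annotate_regions_with_genes(regions, genes)
  expect_equal(ann$gene_list[[1]], c("G1", "G2"))  # partial overlaps count
  expect_equal(ann$n_genes[2], 0L)  # G3 ends at region start - 1: excluded
  expect_equal(ann$n_genes[3], 0L)

  # brute-force pairwise overlap oracle on a 20-gene table
  withr::with_seed(55, {
    genes2 <- tibble::tibble(
      chromosome = sample(c("1", "2"), 20, replace = TRUE),
      start_bp = sample.int(90000, 20))
    genes2$end_bp <- genes2$start_bp + sample.int(20000, 20)
    genes2$name <- paste0("g", 1:20)
    regs <- tibble::tibble(chromosome = c("1", "2", "2"),
                           start_bp = c(20000, 5000, 70000),
                           end_bp = c(50000, 30000, 95000))
    ann2 <- annotate_regions_with_genes(regs, genes2)
    for (r in 1:3) {
      want <- genes2$name[genes2$chromosome == regs$chromosome[r] &
                            genes2$start_bp <= regs$end_bp[r] &
                            genes2$end_bp >= regs$start_bp[r]]
      expect_setequal(ann2$gene_list[[r]], want)
    }
  })

  # chromosome naming mismatch -> guidance error
  expect_error(
    annotate_regions_with_genes(
      regions, dplyr::mutate(genes, chromosome = paste0("chr", chromosome))),
    "harmonise")
})

test_that("gene tables read from BED and GFF3", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tGENEA", "2\t0\t500\tGENEB"), bed)
  gt <- read_gene_table(bed)
  expect_equal(gt$start_bp, c(1000L, 1L))  # 0-based half-open -> 1-based
  expect_equal(gt$end_bp, c(2000L, 500L))

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gene1;Name=GENEA",
    "1\ttest\texon\t1000\t1200\t.\t+\t.\tID=exon1",
    "2\ttest\tgene\t300\t900\t.\t-\t.\tID=gene2;Name=GENEB"), gff)
  gt2 <- read_gene_table(gff)
  expect_equal(nrow(gt2), 2)  # exon rows dropped
  expect_setequal(gt2$name, c("GENEA", "GENEB"))
  expect_equal(gt2$start_bp[gt2$name == "GENEA"], 1000L)
})
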