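#' Minimum number of SNPs for a run of homozygosity
#'
#' The false-positive control of Lencz/Purfield: the minimum run length in
#' SNPs such that, genome-wide, fewer than `alpha` chance runs are expected:
#' `l = ceiling( ln(alpha / (ns * ni)) / ln(1 - het) )`, with `ns` SNPs per
#' individual, `ni` individuals, and `het` the mean observed heterozygosity
#' across SNPs. The result is clamped below at `floor` (a run needs at least
#' 2 SNPs).
#'
#' @param ns Number of genotyped SNPs per individual.
#' @param ni Number of genotyped individuals.
#' @param alpha Expected number of false-positive runs genome-wide
#'   (default 0.05).
#' @param het Mean heterozygosity across SNPs, strictly in (0, 1).
#' @param floor Lower clamp (default 2).
#' @return An integer SNP-count threshold.
#' @export
#' @examples
#' min_snp_threshold(ns = 50000, ni = 100, alpha = 0.05, het = 0.36)  # 42
min_snp_threshold <- function(ns, ni, alpha = 0.05, het, floor = 2L) {
  stopifnot(ns >= 1, ni >= 1, alpha > 0, alpha < 1)
  if (!is.finite(het) || het <= 0 || het >= 1) {
    stop("het must be strictly between 0 and 1")
  }
  l <- ceiling(log(alpha / (ns * ni)) / log(1 - het))
  as.integer(max(floor, l))
}

#' ROH detection parameters
#'
#' Bundles the tuning constants of the consecutive-runs detector. Two passes
#' are conventional: a "stats" pass (minimum length 1 Mb) for inbreeding and
#' length-class summaries, and an "islands" pass (minimum length 0.3 Mb) for
#' shared-homozygosity island calling.
#'
#' @param min_snps Minimum SNPs per run, or `NULL` to derive it from the
#'   data with [min_snp_threshold()] at detection time.
#' @param min_length_bp Minimum run length in bp (default 1,000,000).
#' @param max_het_in_run Heterozygous calls tolerated inside a run (default 1).
#' @param max_missing_in_run Missing calls tolerated inside a run (default 1).
#' @param max_gap_bp Maximum adjacent-SNP gap inside a run (default 1,000,000).
#' @param alpha False-positive allowance for the derived `min_snps`
#'   (default 0.05).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = NULL, min_length_bp = 1e6,
                       max_het_in_run = 1L, max_missing_in_run = 1L,
                       max_gap_bp = 1e6, alpha = 0.05) {
  stopifnot(min_length_bp > 0, max_gap_bp > 0,
            max_het_in_run >= 0, max_missing_in_run >= 0)
  if (!is.null(min_snps) && min_snps < 2) stop("min_snps must be >= 2")
  structure(list(
    min_snps = min_snps, min_length_bp = min_length_bp,
    max_het_in_run = as.integer(max_het_in_run),
    max_missing_in_run = as.integer(max_missing_in_run),
    max_gap_bp = max_gap_bp, alpha = alpha
  ), class = "roh_params")
}

#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Window-free scan of each sample and chromosome for maximal runs of
#' consecutive SNPs containing at most `max_het_in_run` heterozygous and
#' `max_missing_in_run` missing calls, with no adjacent-SNP gap above
#' `max_gap_bp`. A run can neither start nor end on a heterozygous or
#' missing call; a disqualifying (e.g. second) heterozygote terminates the
#' run before it and the scan resumes after it. Runs shorter than
#' `min_length_bp` or with fewer than `min_snps` SNPs are discarded. Run
#' coordinates are the bp positions of the first and last SNP (1-based,
#' inclusive; `length_bp = end_bp - start_bp + 1`).
#'
#' If `params$min_snps` is `NULL` it is derived with [min_snp_threshold()]
#' from this dataset: `ns` = SNPs, `ni` = samples, `het` = mean observed
#' heterozygosity across SNPs (all populations pooled).
#'
#' @param data A [genotype_dataset()].
#' @param params A [roh_params()] object.
#' @return A tibble of segments: `sample_id`, `population`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`, `n_het_inside`,
#'   `n_missing_inside`. The `min_snps` actually used is attached as the
#'   `min_snps` attribute.
#' @export
#' @examples
#' sim <- simulate_populations(1, 5, 500, fst = 0, seed = 7,
#'                             chromosomes = 50e6)
#' pl <- plant_autozygous_segments(
#'   sim$data, spec = data.frame(sample_id = "pop1_01", chromosome = 1,
#'                               start_bp = 10e6, end_bp = 20e6), seed = 8)
#' detect_roh(pl$data, roh_params(min_snps = 20))
detect_roh <- function(data, params = roh_params()) {
  g <- data$genotypes
  min_snps <- params$min_snps
  if (is.null(min_snps)) {
    het <- mean(g == 1L, na.rm = TRUE)
    min_snps <- min_snp_threshold(ns = n_snps(data), ni = n_samples(data),
                                  alpha = params$alpha, het = het)
  }
  chroms <- unique(data$snps$chromosome)
  out <- vector("list", n_samples(data) * length(chroms))
  k <- 0L
  for (chr in chroms) {
    vi <- which(data$snps$chromosome == chr)
    pos <- data$snps$position_bp[vi]
    for (i in seq_len(n_samples(data))) {
      runs <- scan_consecutive_runs(
        g[i, vi], pos,
        max_het = params$max_het_in_run,
        max_miss = params$max_missing_in_run,
        max_gap = params$max_gap_bp
      )
      if (is.null(runs)) next
      keep <- runs$n_snps >= min_snps & runs$length_bp >= params$min_length_bp
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        sample_id = data$samples$sample_id[i],
        population = data$samples$population[i],
        chromosome = chr,
        runs[keep, , drop = FALSE]
      )
    }
  }
  res <- if (k == 0L) empty_roh_tibble() else dplyr::bind_rows(out[seq_len(k)])
  res <- dplyr::arrange(res, chrom_order(.data$chromosome), .data$start_bp,
                        .data$sample_id)
  attr(res, "min_snps") <- min_snps
  res
}

empty_roh_tibble <- function() {
  tibble::tibble(
    sample_id = character(), population = character(),
    chromosome = character(), start_bp = integer(), end_bp = integer(),
    n_snps = integer(), length_bp = numeric(),
    n_het_inside = integer(), n_missing_inside = integer()
  )
}

# One sample, one chromosome. Incremental left-to-right scan: from each
# eligible (homozygous) start, extend while the het/missing allowance and
# the gap constraint hold, then trim the trailing non-homozygous calls.
# When extension stops on an exhausted allowance the breaking call belongs
# to no run and the scan resumes after it.
scan_consecutive_runs <- function(gvec, pos, max_het, max_miss, max_gap) {
  n <- length(gvec)
  if (n == 0) return(NULL)
  is_miss <- is.na(gvec)
  is_het <- !is_miss & gvec == 1L
  is_hom <- !is_miss & !is_het
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!is_hom[i]) { i <- i + 1L; next }
    j <- i; het <- 0L; miss <- 0L; broke_allow <- FALSE
    while (j < n) {
      if (pos[j + 1L] - pos[j] > max_gap) break
      h2 <- het + is_het[j + 1L]
      m2 <- miss + is_miss[j + 1L]
      if (h2 > max_het || m2 > max_miss) { broke_allow <- TRUE; break }
      j <- j + 1L; het <- h2; miss <- m2
    }
    e <- j
    while (!is_hom[e]) e <- e - 1L
    starts <- c(starts, i); ends <- c(ends, e)
    i <- if (broke_allow) j + 2L else j + 1L
  }
  if (!length(starts)) return(NULL)
  tibble::tibble(
    start_bp = pos[starts],
    end_bp = pos[ends],
    n_snps = ends - starts + 1L,
    length_bp = as.numeric(pos[ends]) - pos[starts] + 1,
    n_het_inside = vapply(seq_along(starts), function(r)
      sum(is_het[starts[r]:ends[r]]), integer(1)),
    n_missing_inside = vapply(seq_along(starts), function(r)
      sum(is_miss[starts[r]:ends[r]]), integer(1))
  )
}

roh_length_classes <- c("[1,2)", "[2,4)", "[4,8)", "[8,16)", ">=16")

#' Summarise runs of homozygosity
#'
#' Per-sample counts, mean lengths and the genomic inbreeding coefficient
#' `F_ROH` (summed ROH length / `genome_bp`); per-population means with
#' standard errors; and Mb length-class breakdowns, both as disjoint classes
#' (1-2, 2-4, 4-8, 8-16, >=16 Mb) and cumulative thresholds (>1, >2, >4,
#' >8, >16 Mb). Samples without segments contribute zeros, which is why the
#' sample sheet is required.
#'
#' @param segments A segment tibble from [detect_roh()].
#' @param samples A [genotype_dataset()] or a tibble with `sample_id` and
#'   `population`, defining the full sample set.
#' @param genome_bp Autosomal genome length covered by the array, in bp
#'   (default 2.51e9, the cattle HD-array coverage).
#' @return A list of class `roh_summary` with tibbles `per_sample`
#'   (`sample_id`, `population`, `n_roh`, `sum_mb`, `mean_mb`, `froh`),
#'   `per_population` (means and SEs across samples), `per_class`
#'   (per population and Mb class: mean count/length per sample and the
#'   percentage of that population's segments in the class) and `cumulative`
#'   (per population and minimum length: mean summed length and mean count).
#' @export
summarize_roh <- function(segments, samples, genome_bp = 2.51e9) {
  if (inherits(samples, "genotype_dataset")) samples <- samples$samples
  samples <- tibble::as_tibble(samples)[, c("sample_id", "population")]

  seg <- tibble::as_tibble(segments)
  seg$mb <- seg$length_bp / 1e6
  per_sample <- seg |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_roh = dplyr::n(), sum_mb = sum(.data$mb),
                     mean_mb = mean(.data$mb), .groups = "drop") |>
    dplyr::right_join(samples, by = "sample_id") |>
    dplyr::mutate(
      n_roh = dplyr::coalesce(.data$n_roh, 0L),
      sum_mb = dplyr::coalesce(.data$sum_mb, 0),
      froh = .data$sum_mb * 1e6 / genome_bp
    ) |>
    dplyr::select("sample_id", "population", "n_roh", "sum_mb",
                  "mean_mb", "froh") |>
    dplyr::arrange(.data$population, .data$sample_id)

  se <- function(x) stats::sd(x) / sqrt(length(x))
  per_population <- per_sample |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_n_roh = mean(.data$n_roh), se_n_roh = se(.data$n_roh),
      mean_sum_mb = mean(.data$sum_mb), se_sum_mb = se(.data$sum_mb),
      mean_froh = mean(.data$froh), se_froh = se(.data$froh),
      .groups = "drop"
    )

  seg2 <- dplyr::left_join(seg, samples, by = "sample_id",
                           suffix = c("", ".sheet"))
  if (!"population" %in% names(seg2)) seg2$population <- seg2$population.sheet
  seg2$class <- cut(seg2$mb, breaks = c(1, 2, 4, 8, 16, Inf),
                    labels = roh_length_classes, right = FALSE)
  n_pop_samples <- stats::setNames(
    as.integer(table(samples$population)[unique(samples$population)]),
    unique(samples$population))
  per_class <- seg2 |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$population, .data$class, .drop = FALSE) |>
    dplyr::summarise(n_segments = dplyr::n(), sum_mb = sum(.data$mb),
                     .groups = "drop_last") |>
    dplyr::mutate(pct_of_segments = 100 * .data$n_segments /
                    sum(.data$n_segments),
                  pct_of_length = 100 * .data$sum_mb / sum(.data$sum_mb)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      mean_n_per_sample = .data$n_segments /
        n_pop_samples[as.character(.data$population)],
      mean_mb_per_sample = .data$sum_mb /
        n_pop_samples[as.character(.data$population)]
    )

  cumulative <- purrr::map_dfr(c(1, 2, 4, 8, 16), function(thr) {
    seg2 |>
      dplyr::filter(.data$mb > thr) |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(n_segments = dplyr::n(), sum_mb = sum(.data$mb),
                       .groups = "drop") |>
      dplyr::right_join(tibble::tibble(
        population = unique(samples$population)), by = "population") |>
      dplyr::mutate(
        min_mb = thr,
        n_segments = dplyr::coalesce(.data$n_segments, 0L),
        sum_mb = dplyr::coalesce(.data$sum_mb, 0),
        mean_mb_per_sample = .data$sum_mb /
          n_pop_samples[as.character(.data$population)]
      ) |>
      dplyr::select("population", "min_mb", "n_segments", "sum_mb",
                    "mean_mb_per_sample")
  })

  structure(list(per_sample = per_sample, per_population = per_population,
                 per_class = per_class, cumulative = cumulative,
                 genome_bp = genome_bp),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("<roh_summary> genome_bp =", format(x$genome_bp, big.mark = ","), "\n")
  print(x$per_population)
  invisible(x)
}

#' @rdname summarize_roh
#' @param x A `roh_summary`.
#' @param ... Unused.
#' @export
tidy.roh_summary <- function(x, ...) x$per_sample

#' @rdname summarize_roh
#' @export
glance.roh_summary <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$per_sample),
                 n_populations = nrow(x$per_population),
                 mean_froh = mean(x$per_sample$froh))
}

#' Per-SNP ROH incidence and island calling
#'
#' For one population, computes at every SNP the fraction of that
#' population's samples whose qualifying ROH (length at least
#' `min_segment_bp`) covers the SNP, then calls islands as maximal runs of
#' consecutive SNPs whose incidence is strictly above `threshold` (the
#' "shared by more than 50% of samples" rule). Islands whose maximum
#' incidence is strictly above `strong_threshold` are flagged `strongest`.
#' Island coordinates are the bp of their first and last SNP.
#'
#' @param segments Segment tibble from [detect_roh()] run on `data`
#'   (typically an "islands" pass with a 0.3 Mb minimum length).
#' @param data The [genotype_dataset()] the segments were detected on.
#' @param population Population label to analyse.
#' @param min_segment_bp Minimum segment length for a segment to count
#'   (default 300,000).
#' @param threshold Incidence that must be exceeded (default 0.5).
#' @param strong_threshold Incidence above which an island is "strongest"
#'   (default 0.7).
#' @return A list with `incidence` (tibble: `snp_id`, `chromosome`,
#'   `position_bp`, `n_carriers`, `incidence`) and `islands` (tibble:
#'   `population`, `chromosome`, `start_bp`, `end_bp`, `n_snps`,
#'   `carrier_fraction`, `strongest`).
#' @export
roh_incidence_and_islands <- function(segments, data, population,
                                      min_segment_bp = 3e5,
                                      threshold = 0.5,
                                      strong_threshold = 0.7) {
  pop_samples <- data$samples$sample_id[data$samples$population == population]
  n_pop <- length(pop_samples)
  if (n_pop == 0) stop("unknown or empty population: ", population)

  seg <- dplyr::filter(tibble::as_tibble(segments),
                       .data$sample_id %in% pop_samples,
                       .data$length_bp >= min_segment_bp)
  carriers <- integer(n_snps(data))
  for (chr in unique(seg$chromosome)) {
    vi <- which(data$snps$chromosome == chr)
    pos <- data$snps$position_bp[vi]
    schr <- seg[seg$chromosome == chr, , drop = FALSE]
    for (sid in unique(schr$sample_id)) {
      s <- schr[schr$sample_id == sid, , drop = FALSE]
      covered <- rep(FALSE, length(vi))
      for (r in seq_len(nrow(s))) {
        covered <- covered | (pos >= s$start_bp[r] & pos <= s$end_bp[r])
      }
      carriers[vi] <- carriers[vi] + covered
    }
  }
  incidence <- tibble::tibble(
    snp_id = data$snps$snp_id,
    chromosome = data$snps$chromosome,
    position_bp = data$snps$position_bp,
    n_carriers = carriers,
    incidence = carriers / n_pop
  )

  islands <- incidence |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(df, key) {
      hot <- df$incidence > threshold
      if (!any(hot)) {
        return(tibble::tibble(start_bp = integer(), end_bp = integer(),
                              n_snps = integer(), carrier_fraction = numeric()))
      }
      r <- rle(hot)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      tibble::tibble(
        start_bp = df$position_bp[starts[runs]],
        end_bp = df$position_bp[ends[runs]],
        n_snps = r$lengths[runs],
        carrier_fraction = vapply(runs, function(k)
          max(df$incidence[starts[k]:ends[k]]), numeric(1))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(population = population,
                  strongest = .data$carrier_fraction > strong_threshold) |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$start_bp) |>
    dplyr::select("population", "chromosome", "start_bp", "end_bp",
                  "n_snps", "carrier_fraction", "strongest")

  list(incidence = incidence, islands = islands)
}

#' Write genomic intervals as BED
#'
#' Converts the package's 1-based inclusive interval columns (`start_bp`,
#' `end_bp`) to BED's 0-based half-open convention (`start - 1`, `end`).
#'
#' @param intervals A tibble with `chromosome`, `start_bp`, `end_bp` and
#'   optionally a `name` column (otherwise row numbers are used).
#' @param path Output path.
#' @param name_col Column to use for the BED name field (default: auto).
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path, name_col = NULL) {
  nm <- if (!is.null(name_col)) as.character(intervals[[name_col]])
        else if ("sample_id" %in% names(intervals)) intervals$sample_id
        else if ("population" %in% names(intervals)) intervals$population
        else as.character(seq_len(nrow(intervals)))
  bed <- data.frame(
    chrom = intervals$chromosome,
    start = format(intervals$start_bp - 1, scientific = FALSE, trim = TRUE),
    end = format(intervals$end_bp, scientific = FALSE, trim = TRUE),
    name = nm
  )
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
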