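#' Build a pipeline configuration
#'
#' Assembles (and validates) the nested configuration consumed by
#' [run_pipeline()]. Any field may also be supplied in a YAML file read
#' with [read_pipeline_config()]; values given here override file values.
#'
#' @param input Either a list `list(plink = "<prefix>", format = "auto")`
#'   naming a PLINK fileset, or `list(simulate = list(...))` with arguments
#'   for [simulate_populations()].
#' @param out_dir Output directory (created; stage subdirectories `qc/`,
#'   `diversity/`, `roh/`, `fst/`, `ne/`, `consensus/`).
#' @param seed Top-level integer seed; all stage randomness derives from it.
#' @param qc List: `mind`, `geno`, `autosomes_only`, `maf` (NULL = no MAF
#'   filter at QC; the F_ST stage applies its own), `max_autosome`.
#' @param prune List for the diversity marker set: `window`, `step`, `r2`,
#'   or `NULL` to skip pruning.
#' @param diversity List: `n_bootstrap`, `g` (rarefaction depth or "auto").
#' @param roh_stats,roh_islands [roh_params()]-style lists for the two
#'   detection passes (stats: 1 Mb minimum; islands: 0.3 Mb minimum).
#' @param islands List: `threshold`, `strong_threshold`, `min_segment_bp`.
#' @param fst List: `pairs` (list of 2-vectors; NULL = all pairs), `maf`,
#'   `top_fraction`, `flank_bp`.
#' @param ne List: `populations` (NULL = all), `min_maf`, `alpha_mut`,
#'   `cm_per_mb`, `mapping`, `max_pairs_per_bin`, `window_recent`.
#' @param scans List of imported per-SNP scans, each
#'   `list(path =, label =, population =)`.
#' @param consensus List: `min_methods`.
#' @param genes Optional path to a BED/GFF3 gene table for region
#'   annotation.
#' @param genome_bp Autosomal genome length for F_ROH (default 2.51e9).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, seed = 1L,
                            qc = list(), prune = list(), diversity = list(),
                            roh_stats = list(), roh_islands = list(),
                            islands = list(), fst = list(), ne = list(),
                            scans = list(), consensus = list(),
                            genes = NULL, genome_bp = 2.51e9) {
  defaults <- list(
    qc = list(mind = 0.1, geno = 0.1, autosomes_only = TRUE, maf = NULL,
              max_autosome = 29L),
    prune = list(window = 50L, step = 5L, r2 = 0.5),
    diversity = list(n_bootstrap = 1000L, g = "auto"),
    roh_stats = list(min_snps = NULL, min_length_bp = 1e6,
                     max_het_in_run = 1L, max_missing_in_run = 1L,
                     max_gap_bp = 1e6, alpha = 0.05),
    roh_islands = list(min_snps = NULL, min_length_bp = 3e5,
                       max_het_in_run = 1L, max_missing_in_run = 1L,
                       max_gap_bp = 1e6, alpha = 0.05),
    islands = list(threshold = 0.5, strong_threshold = 0.7,
                   min_segment_bp = 3e5),
    fst = list(pairs = NULL, maf = 0.05, top_fraction = 0.001,
               flank_bp = 2e5),
    ne = list(populations = NULL, min_maf = 0.05, alpha_mut = 2.2,
              cm_per_mb = 1.0, mapping = "sved_feldman",
              max_pairs_per_bin = 1e6, window_recent = 50L),
    consensus = list(min_methods = 2L)
  )
  merge_cfg <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    input = input, out_dir = out_dir, seed = as.integer(seed),
    qc = merge_cfg(qc, defaults$qc),
    prune = if (is.null(prune)) NULL else merge_cfg(prune, defaults$prune),
    diversity = merge_cfg(diversity, defaults$diversity),
    roh_stats = merge_cfg(roh_stats, defaults$roh_stats),
    roh_islands = merge_cfg(roh_islands, defaults$roh_islands),
    islands = merge_cfg(islands, defaults$islands),
    fst = merge_cfg(fst, defaults$fst),
    ne = merge_cfg(ne, defaults$ne),
    scans = scans,
    consensus = merge_cfg(consensus, defaults$consensus),
    genes = genes, genome_bp = genome_bp
  )
  stopifnot(cfg$qc$mind >= 0, cfg$qc$mind <= 1,
            cfg$qc$geno >= 0, cfg$qc$geno <= 1,
            cfg$fst$top_fraction > 0, cfg$fst$top_fraction <= 1,
            cfg$consensus$min_methods >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; its top-level keys are passed to
#'   [pipeline_config()].
#' @param ... Overrides applied after reading (flags win over the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(require_file(path))
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

stage_seed <- function(seed, offset) (seed %% 100000L) * 13L + offset

#' Run the full selection-signature pipeline
#'
#' Executes, in order: input loading (or simulation), QC, LD pruning and
#' diversity statistics, ROH detection (a "stats" pass for F_ROH and length
#' classes and an "islands" pass for shared-homozygosity islands), per-SNP
#' F_ST for every configured population pair with top-fraction sweep
#' windows, LD-based N_E trajectories, import/thresholding of external
#' per-SNP scans, and per-population multi-method consensus regions with
#' optional gene annotation. Every output table is TSV with a comment
#' header recording the package version, a configuration hash and the seed.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file for
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with all stage results (`data`, `qc`,
#'   `diversity`, `roh`, `islands`, `fst`, `ne`, `consensus`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  for (d in c("", "qc", "diversity", "roh", "fst", "ne", "consensus")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  cfg_hashable <- unclass(config)
  cfg_hashable$out_dir <- NULL  # the hash identifies the analysis, not where it lands
  hash <- rlang::hash(cfg_hashable)
  stamp <- sprintf("# snpsel %s; config_hash=%s; seed=%d",
                   as.character(utils::packageVersion("snpsel")),
                   hash, config$seed)
  emit <- function(df, path) {
    if (is.null(df) || !nrow(df)) {
      writeLines(c(stamp, paste(names(df), collapse = "\t")), path)
      return(invisible(path))
    }
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.list), ~ vapply(.x, paste, character(1), collapse = ",")))
    con <- file(path, "w")
    writeLines(stamp, con)
    suppressWarnings(utils::write.table(
      df, con, sep = "\t", quote = FALSE, row.names = FALSE))
    close(con)
    invisible(path)
  }
  logmsg <- function(...) message("[snpsel] ", ...)
  yaml::write_yaml(unclass(config), file.path(out, "config_used.yaml"))

  # ---- input ----
  if (!is.null(config$input$plink)) {
    data <- read_plink(config$input$plink,
                       format = config$input$format %||% "auto")
  } else if (!is.null(config$input$simulate)) {
    sim_args <- config$input$simulate
    sim_args$seed <- sim_args$seed %||% stage_seed(config$seed, 1L)
    sim <- do.call(simulate_populations, sim_args)
    data <- sim$data
  } else {
    stop("config$input must name a plink prefix or a simulate block")
  }
  logmsg("input: ", n_samples(data), " samples, ", n_snps(data), " SNPs")

  # ---- qc ----
  qc_data <- apply_qc(data, max_sample_missing = config$qc$mind,
                      max_snp_missing = config$qc$geno,
                      autosomes_only = config$qc$autosomes_only,
                      min_maf = config$qc$maf,
                      max_autosome = config$qc$max_autosome)
  emit(qc_report(qc_data), file.path(out, "qc", "qc_report.tsv"))
  logmsg("qc: ", n_samples(qc_data), " samples, ", n_snps(qc_data),
         " SNPs retained")

  # ---- diversity (on the pruned set) ----
  div_data <- if (is.null(config$prune)) qc_data else {
    ld_prune(qc_data, config$prune$window, config$prune$step, config$prune$r2)
  }
  logmsg("diversity marker set: ", n_snps(div_data), " SNPs")
  pops <- unique(div_data$samples$population)
  div <- purrr::imap_dfr(stats::setNames(pops, pops), function(pop, nm) {
    population_summary(locus_diversity(div_data, pop),
                       n_bootstrap = config$diversity$n_bootstrap,
                       seed = stage_seed(config$seed, 2L))
  })
  ar <- allelic_richness(div_data, pops, g = config$diversity$g)
  div <- dplyr::left_join(div, ar, by = "population")
  ibs <- ibs_distance_matrix(div_data)
  utils::write.table(ibs, file.path(out, "diversity", "ibs_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  write_ibs_phylip(ibs, file.path(out, "diversity", "ibs_matrix.phy"))

  # ---- roh ----
  roh_stats_params <- do.call(roh_params, config$roh_stats)
  seg_stats <- detect_roh(qc_data, roh_stats_params)
  roh_sum <- summarize_roh(seg_stats, qc_data, genome_bp = config$genome_bp)
  emit(seg_stats, file.path(out, "roh", "segments_stats.tsv"))
  emit(roh_sum$per_sample, file.path(out, "roh", "froh_per_sample.tsv"))
  emit(roh_sum$per_class, file.path(out, "roh", "length_classes.tsv"))
  if (nrow(seg_stats)) {
    write_bed_intervals(seg_stats, file.path(out, "roh", "segments_stats.bed"))
  }
  div$froh_mean <- roh_sum$per_population$mean_froh[
    match(div$population, roh_sum$per_population$population)]
  emit(div, file.path(out, "diversity", "summary.tsv"))

  roh_isl_params <- do.call(roh_params, config$roh_islands)
  seg_isl <- detect_roh(qc_data, roh_isl_params)
  islands <- purrr::map(stats::setNames(pops, pops), function(pop) {
    roh_incidence_and_islands(
      seg_isl, qc_data, pop,
      min_segment_bp = config$islands$min_segment_bp,
      threshold = config$islands$threshold,
      strong_threshold = config$islands$strong_threshold)
  })
  all_islands <- purrr::map_dfr(islands, "islands")
  emit(all_islands, file.path(out, "roh", "islands.tsv"))
  purrr::iwalk(islands, function(x, pop) {
    emit(x$incidence, file.path(out, "roh",
                                paste0("incidence_", pop, ".tsv")))
  })
  logmsg("roh: ", nrow(seg_stats), " stats segments, ",
         nrow(all_islands), " islands")

  # ---- fst ----
  fst_data <- if (is.null(config$fst$maf)) qc_data else {
    apply_qc(qc_data, max_sample_missing = 1, max_snp_missing = 1,
             autosomes_only = FALSE, min_maf = config$fst$maf)
  }
  pairs <- config$fst$pairs %||% utils::combn(pops, 2, simplify = FALSE)
  chrom_len <- tapply(fst_data$snps$position_bp, fst_data$snps$chromosome, max)
  chrom_len <- stats::setNames(as.numeric(chrom_len), names(chrom_len))
  fst_res <- purrr::map(pairs, function(pr) {
    rec <- wc_fst_pair(fst_data, pr[1], pr[2])
    top <- select_top_fraction(rec, config$fst$top_fraction)
    win <- windows_from_snps(top, chrom_len, flank_bp = config$fst$flank_bp)
    tag <- paste0(pr[1], "_", pr[2])
    emit(dplyr::select(rec, -"a", -"b", -"c"),
         file.path(out, "fst", paste0("persnp_", tag, ".tsv")))
    emit(top, file.path(out, "fst", paste0("top_", tag, ".tsv")))
    emit(win, file.path(out, "fst", paste0("windows_", tag, ".tsv")))
    list(pair = pr, records = rec, genome_wide = genome_wide_fst(rec),
         top = top, windows = win)
  })
  emit(purrr::map_dfr(fst_res, "genome_wide"),
       file.path(out, "fst", "genome_wide.tsv"))

  # ---- ne ----
  ne_pops <- config$ne$populations %||% pops
  ne_res <- purrr::map(stats::setNames(ne_pops, ne_pops), function(pop) {
    bins <- binned_r2(qc_data, pop, min_maf = config$ne$min_maf,
                      max_pairs_per_bin = config$ne$max_pairs_per_bin,
                      seed = stage_seed(config$seed, 3L))
    traj <- ne_from_r2(bins, alpha_mut = config$ne$alpha_mut,
                       cm_per_mb = config$ne$cm_per_mb,
                       mapping = config$ne$mapping)
    nec <- if (nrow(traj$points) >= 2) {
      nec_slopes(traj, config$ne$window_recent)
    } else NULL
    emit(traj$points, file.path(out, "ne", paste0("trajectory_", pop, ".tsv")))
    if (!is.null(nec)) {
      emit(nec, file.path(out, "ne", paste0("nec_", pop, ".tsv")))
    }
    list(bins = bins, trajectory = traj, nec = nec)
  })

  # ---- imported scans ----
  scan_regions <- purrr::map(config$scans, function(sc) {
    scan <- read_scan_table(sc$path, method_label = sc$label %||% "HAPFLK")
    reg <- regions_from_pvalues(scan)
    reg$population <- sc$population %||% NA_character_
    reg
  })

  # ---- consensus ----
  consensus <- purrr::map(stats::setNames(pops, pops), function(pop) {
    inputs <- list()
    fst_win <- purrr::map_dfr(fst_res, function(fr) {
      if (pop %in% fr$pair) fr$windows else NULL
    })
    if (nrow(fst_win)) inputs$FST <- fst_win
    isl <- islands[[pop]]$islands
    if (nrow(isl)) inputs$ROH50 <- isl
    for (reg in scan_regions) {
      if (nrow(reg) && (is.na(reg$population[1]) ||
                        reg$population[1] == pop)) {
        inputs[[reg$method[1]]] <- reg
      }
    }
    if (length(inputs) < config$consensus$min_methods) {
      warning("population ", pop, ": only ", length(inputs),
              " method(s) available; consensus is empty")
    }
    cr <- consensus_regions(inputs, min_methods = config$consensus$min_methods,
                            population = pop)
    if (!is.null(config$genes) && nrow(cr$consensus)) {
      genes <- read_gene_table(config$genes)
      cr$consensus <- annotate_regions_with_genes(cr$consensus, genes)
    }
    cons_tab <- cr$consensus
    cons_tab$core_intervals <- NULL
    emit(cons_tab, file.path(out, "consensus",
                             paste0("consensus_", pop, ".tsv")))
    emit(cr$unsupported, file.path(out, "consensus",
                                   paste0("unsupported_", pop, ".tsv")))
    cr
  })
  logmsg("consensus: ",
         sum(purrr::map_int(consensus, ~ nrow(.x$consensus))),
         " region(s) across populations")

  invisible(list(data = data, qc = qc_data, diversity = div,
                 roh = list(segments = seg_stats, summary = roh_sum,
                            islands_segments = seg_isl),
                 islands = islands, fst = fst_res, ne = ne_res,
                 scans = scan_regions, consensus = consensus,
                 out_dir = out))
}
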