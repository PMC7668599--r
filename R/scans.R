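#' Storey q-values
#'
#' False-discovery-rate q-values for a vector of p-values. The proportion of
#' true nulls `pi0` is estimated by the smoother method (natural cubic
#' smoothing spline through `pi0(lambda) = #{p > lambda} / (m (1 - lambda))`
#' on the grid `lambda = 0.05, 0.10, ..., 0.95`, evaluated at the largest
#' lambda). For short vectors (fewer than 100 p-values) or when the
#' smoother misbehaves, `pi0` falls back to 1, in which case q-values equal
#' Benjamini-Hochberg adjusted p-values exactly. Q-values are monotone
#' non-decreasing in p.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param pi0 Optionally force a null proportion in (0, 1] instead of
#'   estimating it.
#' @return Numeric vector of q-values, same order as `p`; the `pi0` used is
#'   attached as attribute `pi0`.
#' @references Storey, J.D. & Tibshirani, R. (2003) Statistical significance
#'   for genomewide studies. PNAS 100:9440-9445.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p)
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  ord <- order(p)
  # grouping (m / k) * p mirrors stats::p.adjust, so pi0 = 1 is bit-exact BH
  q <- pi0 * ((m / seq_len(m)) * p[ord])
  q <- rev(cummin(rev(q)))  # enforce monotonicity from the largest p down
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  attr(out, "pi0") <- pi0
  out
}

estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 100) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- tryCatch(stats::smooth.spline(lambda, pi0_l, df = 3),
                  error = function(e) NULL)
  if (is.null(fit)) return(1)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0) return(1)
  min(pi0, 1)
}

#' Import a per-SNP scan table
#'
#' Reads an externally computed per-SNP scan (e.g. a haplotype-based
#' differentiation test such as hapFLK) from a TSV with a header. Columns
#' are matched case-insensitively: SNP id (`snp`/`snp_id`/`rs`), chromosome
#' (`chrom`/`chr`/`chromosome`/`bta`), position (`bp`/`pos`/`position_bp`)
#' and p-value (`p`/`pvalue`/`p_value`).
#'
#' @param path TSV file path.
#' @param method_label Label naming the method (attached as the
#'   `method_label` attribute and used by [consensus_regions()]).
#' @return A tibble `snp_id`, `chromosome`, `position_bp`, `p_value`,
#'   sorted by (chromosome, position).
#' @export
read_scan_table <- function(path, method_label = "HAPFLK") {
  require_file(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- which(tolower(names(tab)) %in% cands)
    if (!length(hit)) stop("scan table lacks a column among: ",
                           paste(cands, collapse = "/"))
    tab[[hit[1]]]
  }
  out <- tibble::tibble(
    snp_id = as.character(pick(c("snp", "snp_id", "rs", "marker"))),
    chromosome = as.character(pick(c("chrom", "chr", "chromosome", "bta"))),
    position_bp = as.integer(pick(c("bp", "pos", "position", "position_bp"))),
    p_value = as.numeric(pick(c("p", "pvalue", "p_value")))
  ) |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$position_bp)
  attr(out, "method_label") <- method_label
  out
}

#' Call regions from a per-SNP p-value scan
#'
#' Seed SNPs are those with `-log10(p)` strictly above `peak_threshold`
#' (default 3, i.e. p < 0.001) and q-value at most `q_max`. Each region is
#' the maximal run of consecutive SNPs around a seed whose `-log10(p)`
#' stays strictly above `extend_threshold`; regions containing a SNP with
#' `-log10(p)` above `strong_threshold` (default 5) are flagged
#' `strongest`. Region coordinates are the bp of the first and last SNP of
#' the run.
#'
#' @param scan A tibble from [read_scan_table()] (or with the same columns),
#'   sorted by position within chromosome.
#' @param peak_threshold Seed threshold on `-log10(p)` (default 3).
#' @param strong_threshold "Strongest" threshold on `-log10(p)` (default 5).
#' @param extend_threshold Extension threshold on `-log10(p)` (default 1).
#' @param q_max Maximum q-value for a seed (default 0.05); set to `NULL` to
#'   skip the FDR condition.
#' @param method_label Label for the output regions; defaults to the scan's
#'   `method_label` attribute, or `"SCAN"`.
#' @return A tibble of regions: `chromosome`, `start_bp`, `end_bp`,
#'   `n_snps`, `min_p`, `strongest`, `method`.
#' @export
regions_from_pvalues <- function(scan, peak_threshold = 3,
                                 strong_threshold = 5,
                                 extend_threshold = 1, q_max = 0.05,
                                 method_label = NULL) {
  if (is.null(method_label)) {
    method_label <- attr(scan, "method_label") %||% "SCAN"
  }
  empty <- tibble::tibble(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), n_snps = integer(),
                          min_p = numeric(), strongest = logical(),
                          method = character())
  if (nrow(scan) == 0) return(empty)
  lp <- -log10(scan$p_value)
  seed <- lp > peak_threshold
  if (!is.null(q_max)) {
    q <- storey_qvalues(scan$p_value)
    seed <- seed & q <= q_max
  }
  if (!any(seed)) return(empty)

  scan |>
    dplyr::mutate(lp = lp, seed = seed) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(df, key) {
      ext <- df$lp > extend_threshold
      r <- rle(ext)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      rows <- purrr::map_dfr(runs, function(k) {
        span <- starts[k]:ends[k]
        if (!any(df$seed[span])) return(NULL)
        tibble::tibble(
          start_bp = df$position_bp[starts[k]],
          end_bp = df$position_bp[ends[k]],
          n_snps = length(span),
          min_p = min(df$p_value[span]),
          strongest = any(df$lp[span] > strong_threshold)
        )
      })
      rows
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(method = method_label) |>
    dplyr::arrange(chrom_order(.data$chromosome), .data$start_bp)
}

#' Consensus regions across selection-scan methods
#'
#' Implements the "identified by at least two different methods" rule.
#' Inputs are per-method interval tables (sweep windows, scan regions, ROH
#' islands — anything with `chromosome`, `start_bp`, `end_bp`) on the same
#' population and coordinate system. A consensus core is a maximal genomic
#' interval every point of which is covered by intervals of at least
#' `min_methods` distinct methods (found by a sweep line over interval
#' endpoints); each consensus region is reported as the union extent of the
#' intervals contributing to its core, with the full method-label set.
#' Input intervals supporting no core are returned in the `unsupported`
#' table.
#'
#' @param inputs Named list: method label -> interval tibble. Labels must be
#'   unique. A `strongest` logical column, if present, is propagated (a
#'   consensus region is strongest if any contributing interval is).
#' @param min_methods Minimum number of distinct methods (default 2).
#' @param population Optional population label stamped on the output.
#' @return An object of class `consensus_result`: list with tibbles
#'   `consensus` (`chromosome`, `start_bp`, `end_bp`, `core_start_bp` /
#'   `core_end_bp` spanning the covered core(s), list column
#'   `core_intervals` with each maximal >=`min_methods`-covered interval,
#'   `n_methods`, `methods`, `strongest`, `population`) and `unsupported`
#'   (`method`, `chromosome`, `start_bp`, `end_bp`). Regions whose union
#'   extents overlap are merged, so reported regions are disjoint.
#' @export
#' @examples
#' cr <- consensus_regions(list(
#'   FST = data.frame(chromosome = "1", start_bp = 1e6, end_bp = 5e6),
#'   ROH50 = data.frame(chromosome = "1", start_bp = 3e6, end_bp = 8e6)
#' ))
#' cr$consensus
consensus_regions <- function(inputs, min_methods = 2L, population = NA) {
  if (is.null(names(inputs)) || any(names(inputs) == "") ||
      anyDuplicated(names(inputs))) {
    stop("inputs must be a named list with unique method labels")
  }
  iv <- purrr::imap_dfr(inputs, function(df, label) {
    df <- tibble::as_tibble(df)
    if (nrow(df) == 0) return(NULL)
    tibble::tibble(
      method = label,
      chromosome = as.character(df$chromosome),
      start_bp = as.numeric(df$start_bp),
      end_bp = as.numeric(df$end_bp),
      strongest = if ("strongest" %in% names(df)) df$strongest else FALSE
    )
  })
  empty_cons <- tibble::tibble(
    chromosome = character(), start_bp = numeric(), end_bp = numeric(),
    core_start_bp = numeric(), core_end_bp = numeric(),
    core_intervals = list(), n_methods = integer(), methods = character(),
    strongest = logical(), population = as.character(population)[0]
  )
  if (is.null(iv) || nrow(iv) == 0) {
    return(structure(list(consensus = empty_cons,
                          unsupported = tibble::tibble(
                            method = character(), chromosome = character(),
                            start_bp = numeric(), end_bp = numeric()),
                          min_methods = min_methods),
                     class = "consensus_result"))
  }

  cons_list <- list()
  supported <- rep(FALSE, nrow(iv))
  for (chr in unique(iv$chromosome)) {
    at <- which(iv$chromosome == chr)
    cores <- coverage_cores(iv$start_bp[at], iv$end_bp[at], iv$method[at],
                            min_methods)
    if (is.null(cores)) next
    for (r in seq_len(nrow(cores))) {
      touch <- at[iv$start_bp[at] <= cores$end[r] &
                    iv$end_bp[at] >= cores$start[r]]
      supported[touch] <- TRUE
      cons_list[[length(cons_list) + 1]] <- tibble::tibble(
        chromosome = chr,
        start_bp = min(iv$start_bp[touch]),
        end_bp = max(iv$end_bp[touch]),
        core_start_bp = cores$start[r],
        core_end_bp = cores$end[r],
        n_methods = length(unique(iv$method[touch])),
        methods = paste(sort(unique(iv$method[touch])), collapse = ","),
        strongest = any(iv$strongest[touch])
      )
    }
  }
  consensus <- if (length(cons_list)) {
    # distinct cores can share contributing intervals, making union extents
    # overlap; merge such rows so reported regions are disjoint
    dplyr::bind_rows(cons_list) |>
      dplyr::arrange(chrom_order(.data$chromosome), .data$start_bp) |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::group_modify(function(df, key) {
        grp <- cumsum(c(1, df$start_bp[-1] >
                          cummax(df$end_bp[-nrow(df)])))
        df |>
          dplyr::mutate(grp = grp) |>
          dplyr::group_by(.data$grp) |>
          dplyr::summarise(
            core_intervals = list(stats::setNames(
              dplyr::pick("core_start_bp", "core_end_bp"),
              c("start_bp", "end_bp"))),
            start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
            core_start_bp = min(.data$core_start_bp),
            core_end_bp = max(.data$core_end_bp),
            methods = paste(sort(unique(unlist(
              strsplit(.data$methods, ",", fixed = TRUE)))), collapse = ","),
            strongest = any(.data$strongest), .groups = "drop") |>
          dplyr::mutate(n_methods = lengths(
            strsplit(.data$methods, ",", fixed = TRUE))) |>
          dplyr::select(-"grp")
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(population = as.character(population)) |>
      dplyr::select("chromosome", "start_bp", "end_bp", "core_start_bp",
                    "core_end_bp", "core_intervals", "n_methods", "methods",
                    "strongest", "population") |>
      dplyr::arrange(chrom_order(.data$chromosome), .data$start_bp)
  } else empty_cons
  unsupported <- iv[!supported, c("method", "chromosome", "start_bp", "end_bp")]
  structure(list(consensus = consensus, unsupported = unsupported,
                 min_methods = min_methods),
            class = "consensus_result")
}

# Sweep line: maximal intervals (1-based inclusive coords) covered by
# >= min_methods DISTINCT method labels. Returns data.frame(start, end).
coverage_cores <- function(starts, ends, methods, min_methods) {
  bp <- sort(unique(c(starts, ends + 1)))
  if (length(bp) < 2) return(NULL)
  seg_start <- bp[-length(bp)]
  seg_end <- bp[-1] - 1
  n_distinct <- vapply(seq_along(seg_start), function(k) {
    cover <- starts <= seg_start[k] & ends >= seg_end[k]
    length(unique(methods[cover]))
  }, integer(1))
  hot <- n_distinct >= min_methods
  if (!any(hot)) return(NULL)
  r <- rle(hot)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  runs <- which(r$values)
  # adjacent segments are bp-contiguous by construction
  data.frame(start = seg_start[s[runs]], end = seg_end[e[runs]])
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> min_methods =", x$min_methods, "\n")
  print(x$consensus)
  if (nrow(x$unsupported)) {
    cat(nrow(x$unsupported), "single-method (unsupported) interval(s)\n")
  }
  invisible(x)
}

#' @rdname consensus_regions
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @export
tidy.consensus_result <- function(x, ...) x$consensus

#' @rdname consensus_regions
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(n_consensus = nrow(x$consensus),
                 n_unsupported = nrow(x$unsupported),
                 min_methods = x$min_methods)
}

#' Read a gene/QTL interval table
#'
#' BED files (0-based half-open; converted to this package's 1-based
#' inclusive convention) or GFF3 (only rows whose `type` is `gene` are
#' kept; the `Name` or `ID` attribute becomes the gene name).
#'
#' @param path File path (`.bed`, `.gff`, `.gff3`).
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A tibble: `chromosome`, `start_bp`, `end_bp`, `name`.
#' @export
read_gene_table <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  require_file(path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    tibble::tibble(
      chromosome = as.character(tab[[1]]),
      start_bp = as.integer(tab[[2]]) + 1L,
      end_bp = as.integer(tab[[3]]),
      name = if (ncol(tab) >= 4) as.character(tab[[4]])
             else paste0("feature_", seq_len(nrow(tab)))
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "gene"]
    nm <- if (!is.null(gr$Name)) as.character(gr$Name)
          else as.character(gr$ID)
    tibble::tibble(
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr),
      name = nm
    )
  }
}

#' Annotate regions with overlapping genes
#'
#' A gene is assigned to a region when their intervals overlap by at least
#' one bp (genes localised entirely or partly within the region). Output
#' preserves region order; genes are listed by start position.
#'
#' @param regions A tibble with `chromosome`, `start_bp`, `end_bp` (e.g.
#'   `consensus_regions(...)$consensus`).
#' @param genes A gene table from [read_gene_table()] (columns `chromosome`,
#'   `start_bp`, `end_bp`, `name`).
#' @return `regions` with list column `gene_list`, integer `n_genes` and a
#'   comma-separated `genes` column.
#' @export
annotate_regions_with_genes <- function(regions, genes) {
  regions <- tibble::as_tibble(regions)
  genes <- tibble::as_tibble(genes)
  if (nrow(regions) && nrow(genes) &&
      !any(unique(genes$chromosome) %in% unique(regions$chromosome))) {
    stop("no chromosome labels shared between regions and genes; ",
         "harmonise naming conventions (e.g. strip 'chr' prefixes) first")
  }
  rgr <- GenomicRanges::GRanges(
    regions$chromosome,
    IRanges::IRanges(regions$start_bp, regions$end_bp))
  ggr <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  lists <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    gi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == r]
    gi <- gi[order(genes$start_bp[gi])]
    lists[[r]] <- genes$name[gi]
  }
  regions$gene_list <- lists
  regions$n_genes <- lengths(lists)
  regions$genes <- vapply(lists, paste, character(1), collapse = ",")
  regions
}

`%||%` <- function(a, b) if (is.null(a)) b else a
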