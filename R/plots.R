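#' Manhattan-style plot of a per-SNP scan
#'
#' Plots a per-SNP statistic (F_ST theta by default) along concatenated
#' chromosomes, with an optional horizontal cut-off line (e.g. the realised
#' top-0.1% threshold).
#'
#' @param records A tibble with `chromosome`, `position_bp` and the
#'   statistic column (e.g. from [wc_fst_pair()]).
#' @param stat Column to plot (default `"theta"`).
#' @param threshold Optional horizontal line value; defaults to the
#'   `threshold` attribute if present.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(records, stat = "theta", threshold = NULL) {
  threshold <- threshold %||% attr(records, "threshold")
  df <- tibble::as_tibble(records)
  df <- df[!is.na(df[[stat]]), , drop = FALSE]
  df <- df[order(chrom_order(df$chromosome), df$position_bp), , drop = FALSE]
  offs <- df |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(len = max(.data$position_bp), .groups = "drop") |>
    dplyr::arrange(chrom_order(.data$chromosome)) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  df <- dplyr::left_join(df, offs, by = "chromosome") |>
    dplyr::mutate(x = .data$position_bp + .data$offset,
                  parity = factor(chrom_order(.data$chromosome) %% 2))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x / 1e6, y = .data[[stat]], colour = .data$parity)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "genome position (Mb)", y = stat) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot an effective-population-size trajectory
#'
#' @param object An `ne_trajectory` from [ne_from_r2()].
#' @param ... Unused.
#' @return A ggplot object (N_E against generations ago, most recent left).
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$t, y = .data$ne)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generations ago", y = expression(N[E]),
                  title = paste0("LD-based effective population size (",
                                 object$mapping, " mapping)")) +
    ggplot2::theme_minimal()
}

#' Plot per-SNP ROH incidence for one population
#'
#' @param incidence The `incidence` tibble from
#'   [roh_incidence_and_islands()].
#' @param threshold Island-calling threshold line (default 0.5).
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_roh_incidence <- function(incidence, threshold = 0.5) {
  ggplot2::ggplot(incidence, ggplot2::aes(
    x = .data$position_bp / 1e6, y = .data$incidence)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "fraction of samples in ROH") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
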