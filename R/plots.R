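# ggplot2 visualisations for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rarefaction curve
#'
#' @param object a `tr_rarefaction` tibble from [rarefaction()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tr_rarefaction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = depth, y = mean_unique)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "subsampled reads", y = "unique CDR3s",
                  title = "Rarefaction of unique CDR3s") +
    ggplot2::theme_minimal()
}

#' Plot V-gene usage
#'
#' @param object a `tr_usage` tibble from [v_usage()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tr_usage <- function(object, ...) {
  dat <- mutate(object, gene = factor(gene, levels = object$gene))
  ggplot2::ggplot(dat, ggplot2::aes(x = gene, y = freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "usage frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot a CDR3 length distribution
#'
#' @param object a `tr_cdr3len` tibble from [cdr3_length_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tr_cdr3len <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = cdr3_len, y = prop)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "mean_length_exact"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "CDR3 length (aa)", y = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot public/private sharing proportions
#'
#' @param object a `tr_publicness` tibble from [publicness()].
#' @param ... unused.
#' @return a stacked-bar ggplot.
#' @export
autoplot.tr_publicness <- function(object, ...) {
  dat <- mutate(object, sharing_level = factor(sharing_level))
  ggplot2::ggplot(dat, ggplot2::aes(x = sample_id, y = prop,
                                    fill = sharing_level)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "shared by\n(fish)") +
    ggplot2::labs(x = NULL, y = "proportion of unique CDR3s") +
    ggplot2::theme_minimal()
}

#' Plot an annotated locus map
#'
#' Gene segments as arrows along the contig, coloured by type, pseudogenes
#' hatched grey.
#'
#' @param object a `tr_locus` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tr_locus <- function(object, ...) {
  dat <- tibble(
    start = object$start, end = object$end,
    y = ifelse(object$strand == "+", 1, -1),
    segment_type = object$segment_type,
    functionality = object$functionality
  )
  ggplot2::ggplot(dat) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = start, xmax = end, ymin = y * 0.1, ymax = y * 0.9,
                   fill = segment_type, alpha = functionality)
    ) +
    ggplot2::scale_alpha_manual(values = c(functional = 1,
                                           pseudogene = 0.35)) +
    ggplot2::scale_y_continuous(breaks = c(-0.5, 0.5),
                                labels = c("-", "+"), limits = c(-1, 1)) +
    ggplot2::labs(x = "contig position (nt)", y = "strand") +
    ggplot2::theme_minimal()
}

#' Rank-abundance plot of a repertoire
#'
#' Clone size against abundance rank on log-log axes, with the D50 rank
#' marked.
#'
#' @param sample clonotype tibble.
#' @return a ggplot.
#' @export
plot_rank_abundance <- function(sample) {
  validate_airr(sample)
  d <- d50(sample)
  dat <- tibble(
    count = sort(sample$duplicate_count, decreasing = TRUE)
  ) |> mutate(rank_ = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(x = rank_, y = count)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = d$d50_count, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone rank", y = "reads",
                  subtitle = sprintf("D50 = %d clonotypes (%.1f%% of unique)",
                                     d$d50_count, 100 * d$d50_proportion)) +
    ggplot2::theme_minimal()
}
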