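#' Homology dot plot of anchors on a chromosome pair
#'
#' @param anchors Anchor tibble (one or more chromosome pairs; facetted when
#'   several).
#' @param hit_classes Optional tibble from [rank_hit_classes()] to colour
#'   points by best / second / other.
#' @return A ggplot object.
#' @export
plot_synteny_dotplot <- function(anchors, hit_classes = NULL) {
  df <- anchors
  if (!is.null(hit_classes)) {
    df <- df |>
      left_join(hit_classes,
                by = c(gene_a = "query_id", gene_b = "subject_id")) |>
      mutate(hit_class = ifelse(is.na(.data$hit_class), "other",
                                .data$hit_class))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_a, y = .data$rank_b))
  if (!is.null(hit_classes)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$hit_class),
                                 size = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(best = "red", second = "blue", other = "grey60"))
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, colour = "grey30")
  }
  p +
    ggplot2::facet_grid(.data$chrom_b ~ .data$chrom_a, scales = "free") +
    ggplot2::labs(x = "gene rank (genome A)", y = "gene rank (genome B)") +
    ggplot2::theme_minimal()
}

#' Ks distribution of homologous pairs with event windows
#'
#' @param pair_ks Tibble with a `ks` column.
#' @param windows Optional [event_windows()] tibble drawn as shaded bands.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(pair_ks, windows = NULL, binwidth = 0.05) {
  p <- ggplot2::ggplot(pair_ks, ggplot2::aes(x = .data$ks))
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(windows),
      ggplot2::aes(xmin = .data$ks_min, xmax = .data$ks_max,
                   ymin = -Inf, ymax = Inf, fill = .data$name),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "Ks", y = "pairs", fill = "event") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_synteny_dotplot autoplot method for block objects: the
#'   anchors of each detected block, coloured by block.
#' @param object A `polyret_blocks` object.
#' @param ... Unused.
#' @export
autoplot.polyret_blocks <- function(object, ...) {
  an <- object$anchors |>
    left_join(object$blocks |> select("block_id", "chrom_a", "chrom_b"),
              by = "block_id")
  ggplot2::ggplot(an, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                   colour = factor(.data$block_id))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(.data$chrom_b ~ .data$chrom_a, scales = "free") +
    ggplot2::labs(x = "gene rank (A)", y = "gene rank (B)",
                  colour = "block") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot robustness profiles
#'
#' @param object A `polyret_robustness` tibble (one or more networks).
#' @param ... Unused.
#' @return A ggplot object: mean R per removal scheme, one line per network.
#' @export
autoplot.polyret_robustness <- function(object, ...) {
  df <- object |>
    mutate(scheme = factor(.data$scheme, levels = unique(.data$scheme)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$mean_R,
                                   group = .data$network,
                                   colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "nodes removed", y = "mean robustness R") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
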