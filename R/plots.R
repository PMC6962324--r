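#' Boxplot of F_multi by group and AF threshold
#'
#' The mother-vs-infant comparison layout: one panel per minor AF
#' threshold, boxes per group, log-scaled y.
#'
#' @param fm Combined [f_multi()] output for many samples.
#' @param groups A data frame mapping `sample_id` to a `group` column
#'   (e.g. role).
#' @return A ggplot.
#' @export
plot_f_multi <- function(fm, groups) {
  d <- fm |>
    left_join(groups, by = "sample_id") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$x), nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "F_multi") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @rdname effect_enrichment_lrt
#' @param object An `effect_lrt`.
#' @param ... Unused.
#' @export
autoplot.effect_lrt <- function(object, ...) {
  d <- object$per_category |>
    select("category", observed = "proportion",
           null = "null_proportion") |>
    tidyr::pivot_longer(-"category", names_to = "source",
                        values_to = "proportion")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$proportion,
                                  fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "proportion of sites") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Heatmap of a pairwise identity matrix
#'
#' Samples are ordered by the Ward (ward.D2) dendrogram leaf order.
#'
#' @param im An [identity_matrix()] result.
#' @return A ggplot.
#' @export
plot_identity_matrix <- function(im) {
  stopifnot(inherits(im, "identity_matrix"))
  ord <- im$order
  d <- as_tibble(im$matrix, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "identity") |>
    mutate(sample_a = factor(.data$sample_a, levels = ord),
           sample_b = factor(.data$sample_b, levels = ord))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_a, .data$sample_b,
                                  fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% identity", na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
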