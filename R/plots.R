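#' Volcano plot of a single-fraction contrast
#'
#' @param object A `tl_de` tibble from [run_contrast()].
#' @param up_threshold,down_threshold,q_cut Gates used for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_de <- function(object, up_threshold = 1.5, down_threshold = 0.667,
                           q_cut = 0.05, ...) {
  df <- as_tibble(object) %>%
    mutate(status = dplyr::case_when(
      .data$ratio > up_threshold & .data$q_value < q_cut ~ "up",
      .data$ratio < down_threshold & .data$q_value < q_cut ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(c(down_threshold, up_threshold)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(q_cut), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#2b8cbe",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (SEN / PRE)", y = "-log10 q",
                  colour = NULL,
                  title = paste0(unique(df$fraction), " fraction"))
}

#' @rdname autoplot.tl_de
#' @param de A `tl_de` tibble.
#' @export
plot_volcano <- function(de, ...) autoplot(de, ...)

#' Bar chart of translatome classification counts
#'
#' @param object A `tl_classification` tibble from [classify_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_classification <- function(object, ...) {
  df <- summarize_sets(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~category, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "genes")
}

#' @rdname autoplot.tl_classification
#' @param classifications A `tl_classification` tibble.
#' @export
plot_class_summary <- function(classifications, ...) autoplot(classifications, ...)

#' Cumulative population-doubling curve
#'
#' @param object A `tl_growth` tibble from [growth_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_growth <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$day, .data$cumulative_pd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "days in culture", y = "cumulative population doublings")
}

#' @rdname autoplot.tl_growth
#' @param records A `tl_growth` tibble.
#' @export
plot_growth_curve <- function(records, ...) autoplot(records, ...)
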