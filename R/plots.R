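#' Plot the rank-abundance profile
#'
#' Median relative abundance per within-gene rank with an interquartile
#' ribbon; a transcriptome dominated by one isoform per gene shows a steep
#' drop from rank 1 to rank 2.
#'
#' @param profile Output of [rank_abundance_profile()].
#' @return A ggplot object.
#' @export
plot_rank_abundance <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$rank, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = profile$rank) +
    ggplot2::labs(x = "Within-gene abundance rank",
                  y = "Relative abundance",
                  title = "Rank-abundance profile of transcripts") +
    ggplot2::theme_minimal()
}

#' Plot mRNA-pool fractions per sample
#'
#' @param pool Output of [pool_fractions()].
#' @return A ggplot object.
#' @export
plot_pool_fractions <- function(pool) {
  long <- tidyr::pivot_longer(pool, dplyr::starts_with("fraction"),
                              names_to = "class", values_to = "fraction") |>
    dplyr::mutate(class = sub("^fraction_", "", .data$class))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Fraction of mRNA pool",
                  title = "Pool mass of major and dominant transcripts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a switch expression profile
#'
#' @param profile Output of [switch_profile()].
#' @return A ggplot object.
#' @export
plot_switch_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$sample_id, y = .data$lr,
                                        group = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "ratio"),
                  title = "Switch expression profile") +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object A `txdom_report`.
#' @export
autoplot.txdom_report <- function(object, ...) {
  plot_rank_abundance(object$rank_profile)
}
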