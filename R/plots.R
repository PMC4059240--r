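# ggplot2 views of the standard result types.

#' Plot an unfolded site frequency spectrum
#'
#' Bars of the site proportions by derived count, optionally split by a
#' class column (e.g. direction), with the neutral `1/d` expectation
#' overlaid.
#'
#' @param object A `codon_sfs` tibble from [build_sfs()].
#' @param by Optional class column for dodged bars.
#' @param neutral Overlay the constant-size neutral expectation.
#' @param k Sample size (inferred from the spectrum if missing).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_sfs <- function(object, by = NULL, neutral = TRUE, k = NULL,
                               ...) {
  if (is.null(k)) k <- max(object$d) + 1
  df <- object
  if (is.null(by)) {
    df$prop <- df$n / sum(df$n)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$prop)) +
      ggplot2::geom_col(fill = "steelblue")
  } else {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$d, y = .data$prop, fill = .data[[by]]
    )) +
      ggplot2::geom_col(position = "dodge")
  }
  if (neutral) {
    p <- p + ggplot2::geom_point(
      data = neutral_sfs(k),
      ggplot2::aes(x = .data$d, y = .data$prop),
      inherit.aes = FALSE, shape = 21, fill = "black"
    )
  }
  p +
    ggplot2::scale_x_continuous(breaks = seq_len(k - 1)) +
    ggplot2::labs(
      x = "derived count d", y = "proportion of sites",
      title = "Unfolded site frequency spectrum"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a `codon_sfs`
#'
#' @param x A `codon_sfs`.
#' @param ... Passed to [autoplot.codon_sfs()].
#' @export
plot.codon_sfs <- function(x, ...) {
  print(autoplot.codon_sfs(x, ...))
  invisible(x)
}

#' Diversity (or codon bias) against recombination rate class
#'
#' @param summaries Tibble from [rate_class_summaries()] (needs
#'   `rate_upper` and the value column).
#' @param value Column to plot (default `"theta_w"`).
#' @return A ggplot object.
#' @export
plot_rate_classes <- function(summaries, value = "theta_w") {
  ggplot2::ggplot(summaries, ggplot2::aes(
    x = .data$rate_upper, y = .data[[value]]
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~site_type, scales = "free_y") +
    ggplot2::labs(
      x = "recombination rate class upper bound (cM/Mb)", y = value
    ) +
    ggplot2::theme_minimal()
}

#' Per-segment diversity along the chromosome
#'
#' @param summaries Tibble from [segment_summaries()].
#' @param value Column to plot (default `"theta_w"`).
#' @return A ggplot object.
#' @export
plot_segments <- function(summaries, value = "theta_w") {
  df <- summaries
  df$segment <- factor(df$segment, levels = unique(df$segment))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$segment, y = .data[[value]], group = .data$site_type,
    colour = .data$site_type
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "map segment", y = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
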