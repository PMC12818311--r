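# ggplot2 graphics for the main result types.

#' Plot predicted or observed SRT curves
#'
#' SRT against the eccentricity/diameter ratio, one curve per target
#' diameter — the collapse diagnostic.
#'
#' @param curve A tibble from [predict_srt_curve()] (or any data frame
#'   with `ratio`, `diameter_deg` and an SRT column).
#' @param srt_col Name of the SRT column.
#' @return A ggplot object.
#' @export
plot_srt_curve <- function(curve, srt_col = "predicted_median_srt_ms") {
  ggplot2::ggplot(
    curve,
    ggplot2::aes(
      x = .data$ratio, y = .data[[srt_col]],
      colour = factor(.data$diameter_deg),
      group = factor(.data$diameter_deg)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "eccentricity / diameter ratio",
      y = "median SRT (ms)",
      colour = "diameter (deg)"
    ) +
    ggplot2::theme_minimal()
}

#' Reciprobit plot of one or more latency samples
#'
#' Probit of the cumulative probability against negative reciprocal
#' latency; recinormal samples are straight lines.
#'
#' @param srts A numeric vector or a named list of numeric vectors.
#' @return A ggplot object.
#' @export
plot_reciprobit <- function(srts) {
  if (is.numeric(srts)) srts <- list(sample = srts)
  df <- purrr::imap(srts, function(v, nm) {
    dplyr::mutate(reciprobit_points(v), condition = nm)
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$condition)
  ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::stat_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "-1 / SRT (1/ms)", y = "probit(P)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.payoff_fit <- function(object, ...) {
  df <- object$fitted
  df$ratio <- ifelse(df$diameter_deg > 0,
                     df$eccentricity_deg / df$diameter_deg,
                     df$eccentricity_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_median_srt_ms)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$predicted_median_srt_ms,
                   group = factor(.data$diameter_deg)),
      colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "eccentricity / diameter ratio",
      y = "median SRT (ms)",
      title = sprintf("payoff model fit: k = %.3g, adj R2 = %.3f",
                      object$params$scaling_constant,
                      object$adj_r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot choice probability against reaction time
#'
#' Binned CP with binomial confidence intervals and the overall SRT
#' cumulative distribution overlaid.
#'
#' @param cp_table Output of [cp_by_srt()].
#' @return A ggplot object.
#' @export
plot_cp_by_srt <- function(cp_table) {
  cdf <- attr(cp_table, "srt_cdf")
  mid <- (cp_table$bin_lo + cp_table$bin_hi) / 2
  df <- dplyr::mutate(cp_table, mid = mid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$cp)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "SRT (ms)", y = "P(choose priority target)") +
    ggplot2::theme_minimal()
  if (!is.null(cdf)) {
    p <- p + ggplot2::geom_line(
      data = cdf,
      ggplot2::aes(x = .data$srt_ms, y = .data$cdf),
      colour = "grey50"
    )
  }
  p
}
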