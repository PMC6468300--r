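# ggplot2 autoplot methods for the main result types.

#' Plot a hit table
#'
#' Z-scores of every probe/sample pair, hits highlighted, with horizontal
#' lines at the two sigma thresholds.
#'
#' @param object A `hit_table` from [screen_hits()] or [call_hits()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hit_table
#' @export
autoplot.hit_table <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% c(2.5, 3.5)
  df <- dplyr::filter(object, !is.na(.data$z))
  df$call <- dplyr::case_when(df$hit_3p5 ~ "hit_3p5",
                              df$hit_2p5 ~ "hit_2p5",
                              TRUE ~ "none")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probe_id, y = .data$z,
                                   colour = .data$call)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(none = "grey60",
                                            hit_2p5 = "orange",
                                            hit_3p5 = "red")) +
    ggplot2::labs(x = NULL, y = "Z-score (log2 normalized counts)",
                  colour = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a response classification
#'
#' Treated vs treated-plus-inhibitor fold changes (log2 axes), coloured by
#' dependence class.
#'
#' @param object A `response_table` from [classify_dependence()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot response_table
#' @export
autoplot.response_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log2(.data$fc_t),
                                       y = log2(.data$fc_ti),
                                       colour = .data$dep_class)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log2 FC (treated vs control)",
                  y = "log2 FC (treated + inhibitor vs control)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a score table
#'
#' Activation score against the target gene's log2 expression, coloured by
#' stratum.
#'
#' @param object A `score_table` (component of [score_cohort()] output).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot score_table
#' @export
autoplot.score_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$target_log2,
                                       y = .data$activation_score,
                                       colour = .data$stratum)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::labs(x = "target gene log2 expression",
                  y = "signature activation score", colour = "stratum") +
    ggplot2::theme_minimal()
}

#' Plot a signature null distribution
#'
#' Histogram of the null correlations with the fitted Gumbel density and the
#' observed correlation marked.
#'
#' @param object A `signature_null` from [random_signature_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot signature_null
#' @export
autoplot.signature_null <- function(object, ...) {
  df <- tidy(object)
  mu <- object$gumbel_mu
  beta <- object$gumbel_beta
  xs <- seq(min(df$null_r, object$observed_r),
            max(df$null_r, object$observed_r), length.out = 400)
  sgn <- if (object$direction == "negative") -1 else 1
  dens <- tibble(x = xs, y = {
    z <- (sgn * xs - mu) / beta
    exp(-z - exp(-z)) / beta
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey75") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$observed_r, colour = "red") +
    ggplot2::labs(x = "null Pearson r (random signatures)", y = "density",
                  subtitle = sprintf("observed r = %.3f, Gumbel p = %.2g",
                                     object$observed_r, object$p_value)) +
    ggplot2::theme_minimal()
}
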