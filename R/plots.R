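# ggplot2 views of the main result types.

#' Plot an insulation track with called boundaries
#'
#' @param track Tibble from [insulation_score()].
#' @param boundaries Optional boundary tibble from [call_boundaries()].
#' @return A ggplot object.
#' @export
plot_insulation <- function(track, boundaries = NULL) {
  p <- ggplot2::ggplot(track[track$valid, ],
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$log2_insulation)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey70") +
    ggplot2::labs(x = "position (bp)", y = "log2 insulation") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries)) {
    b <- if ("passes_threshold" %in% names(boundaries)) {
      boundaries[boundaries$passes_threshold, ]
    } else boundaries
    p <- p + ggplot2::geom_vline(xintercept = (b$start + b$end) / 2,
                                 color = "firebrick", alpha = 0.6)
  }
  p
}

#' Plot pan/core accumulation curves
#'
#' Mean curve with a ribbon of +/- one sd over random genome orders.
#'
#' @param curves Tibble from [accumulation_curves()].
#' @return A ggplot object.
#' @export
plot_accumulation <- function(curves) {
  s <- curves |>
    pivot_longer(c("pan", "core"), names_to = "set",
                 values_to = "size") |>
    group_by(.data$k, .data$set) |>
    summarise(mean = mean(.data$size), sd = sd(.data$size),
              .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$k, y = .data$mean,
                                  color = .data$set, fill = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "genomes added", y = "cluster count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bootstrap_result <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_draws),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed,
                        color = "firebrick") +
    ggplot2::labs(x = "null coverage fraction", y = "draws",
                  title = sprintf("observed %.4g (p_dep %.3g, p_enr %.3g)",
                                  object$observed, object$p_depletion,
                                  object$p_enrichment)) +
    ggplot2::theme_minimal()
}

#' Plot the Fst / Pi-ratio candidate screen
#'
#' @param table Tibble from [screen_candidate_svs()].
#' @param top_frac Tail fraction whose cutoffs are drawn (default 0.05).
#' @return A ggplot object.
#' @export
plot_selection_screen <- function(table, top_frac = 0.05) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$fst,
                                      y = log2(.data$pi_ratio),
                                      color = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = quantile(table$fst, 1 - top_frac),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = log2(quantile(table$pi_ratio,
                                                   1 - top_frac)),
                        linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Fst", y = "log2 Pi-ratio") +
    ggplot2::theme_minimal()
}
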