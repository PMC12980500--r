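# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an inter-method similarity matrix
#' @param object An `inter_method_result`. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inter_method_result <- function(object, ...) {
  m <- object$mean_matrix
  df <- tibble::as_tibble(m, rownames = "method_a") |>
    tidyr::pivot_longer(-"method_a", names_to = "method_b",
                        values_to = "correlation")
  ggplot2::ggplot(df, ggplot2::aes(.data$method_a, .data$method_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Inter-method similarity (mean per-lead correlation)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-method self-consistency summary plot
#' @param object A `self_consistency_result`. @param ... Unused.
#' @export
autoplot.self_consistency_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(stats::reorder(.data$method, .data$mean),
                               .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "correlation across seeds",
                  title = "Self-consistency across random initializations") +
    ggplot2::theme_minimal()
}

#' Randomization trajectory plot
#' @param object A `randomization_trajectory`. @param ... Unused.
#' @export
autoplot.randomization_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(.data$step, .data$mean, colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "randomized layers (output-first)",
                  y = "correlation with trained-model maps",
                  title = "Cascading layer randomization") +
    ggplot2::theme_minimal()
}

#' Perturbation trajectory plot
#' @param object A `perturbation_trajectory`. @param ... Unused.
#' @export
autoplot.perturbation_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(100 * .data$cumulative_fraction,
                                   .data$auroc, colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "input perturbed (%)", y = "AUROC",
                  title = "Remove-and-debias perturbation") +
    ggplot2::theme_minimal()
}

#' Plot one ECG record with optional attribution overlay
#'
#' @param record An `ecg_record`.
#' @param map Optional `attribution_map` to overlay as a filled band.
#' @return A ggplot with one facet per lead.
#' @export
plot_record <- function(record, map = NULL) {
  L <- ncol(record$signal)
  t <- (seq_len(L) - 1) / record$sampling_rate
  df <- tibble::tibble(lead = factor(rep(rownames(record$signal), L),
                                     levels = ECG_LEADS),
                       time = rep(t, each = 8),
                       mv = as.vector(record$signal))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mv))
  if (!is.null(map)) {
    a <- abs(map_values(map))
    df$attr <- as.vector(a / max(a, 1e-12))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mv)) +
      ggplot2::geom_line(ggplot2::aes(colour = .data$attr)) +
      ggplot2::scale_colour_gradient(low = "grey60", high = "red")
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~lead, ncol = 2) +
    ggplot2::labs(x = "time (s)", y = "mV") +
    ggplot2::theme_minimal()
}

#' @export
tidy.inter_method_result <- function(x, ...) x$scores

#' @export
glance.inter_method_result <- function(x, ...) {
  tibble::tibble(class = x$class, n_records = dplyr::n_distinct(x$scores$record_id),
                 n_methods = nrow(x$mean_matrix), n_skipped = x$n_skipped,
                 kind = x$kind)
}

#' @export
tidy.self_consistency_result <- function(x, ...) x$summary

#' @export
tidy.randomization_trajectory <- function(x, ...) x$trajectory

#' @export
glance.randomization_trajectory <- function(x, ...) {
  tibble::tibble(class = x$class, n_steps = max(x$trajectory$step),
                 final_auroc = if (nrow(x$auroc) > 0) x$auroc$auroc[nrow(x$auroc)] else NA_real_)
}

#' @export
tidy.perturbation_trajectory <- function(x, ...) tibble::as_tibble(x)
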