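#' Plot a peak list as a stem spectrum
#'
#' @param peaks Peak tibble (`mz`, `intensity`).
#' @param ladder Optional `ladder_call`; its rung positions are marked.
#' @param xlim Optional m/z limits.
#' @return A ggplot object.
#' @export
plot_peaks <- function(peaks, ladder = NULL, xlim = NULL) {
  p <- ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity),
                          linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Da)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(ladder)) {
    rungs <- tidy(ladder)
    p <- p + ggplot2::geom_vline(
      data = rungs,
      ggplot2::aes(xintercept = .data$theoretical_mh,
                   colour = .data$present),
      linetype = "dashed", alpha = 0.5
    ) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "steelblue", `FALSE` = "firebrick"),
        name = "rung present"
      )
  }
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim)
  p
}

#' @describeIn plot_peaks Autoplot method: ladder rungs over their 57-Da grid.
#' @param object A `ladder_call`.
#' @param ... Unused.
#' @method autoplot ladder_call
#' @export
autoplot.ladder_call <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$theoretical_mh,
                                  fill = .data$present)) +
    ggplot2::geom_point(shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "white"),
      name = "rung present"
    ) +
    ggplot2::labs(x = "glycine multiplicity n", y = "MH+ (Da)",
                  title = sprintf("57-Da ladder, k_max = %d", object$k_max)) +
    ggplot2::theme_minimal()
}

#' Bar chart of dimer bridge classes
#'
#' @param object A `dimer_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dimer_report
#' @export
autoplot.dimer_report <- function(object, ...) {
  d <- tibble::tibble(
    class = factor(c("intact", "neutral", "repulsive"),
                   levels = c("intact", "neutral", "repulsive")),
    n = unname(object$counts[c("intact", "neutral", "repulsive")])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n,
                                  fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(intact = "steelblue",
                                          neutral = "grey70",
                                          repulsive = "firebrick")) +
    ggplot2::labs(
      x = NULL, y = "bridges",
      title = sprintf("%s / %s: compatibility score %d",
                      object$partner_a, object$partner_b, object$score)
    ) +
    ggplot2::theme_minimal()
}
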