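#' @export
autoplot.proximity_screen <- function(object, ...) {
  dat <- tidy(object)
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$z, y = -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "z (observed vs degree-preserving null)",
                  y = expression(-log[10]~p),
                  colour = paste0("p ≤ ", alpha)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.disease_signature <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lfc, y = -log10(.data$adj_p),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(object$adj_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue"),
                                 na.value = "grey70") +
    ggplot2::labs(x = expression(log[2]~fold~change),
                  y = expression(-log[10]~adjusted~p)) +
    ggplot2::theme_minimal()
}

#' Plot a null model's reference distribution against an observed proximity
#'
#' @param null A `null_model` from [build_null()].
#' @param observed Optional observed proximity to mark.
#' @param metric Which metric column to plot (defaults to the first).
#' @return A ggplot object.
#' @export
plot_null <- function(null, observed = NULL, metric = NULL) {
  stopifnot(inherits(null, "null_model"))
  metric <- metric %||% null$metric[[1L]]
  dat <- tibble(proximity = null$samples[, metric])
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$proximity)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::labs(x = paste0("null proximity (", metric, ")"), y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick",
                                 linewidth = 1)
  }
  p
}
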