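# ggplot2 views of the result types.

#' Plot a Betti curve
#'
#' Step plot of `beta0` and `beta1` along the filtration.
#'
#' @param object a [betti_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot betti_curve
#' @export
autoplot.betti_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$dimension <- factor(df$dimension,
                         labels = paste0("beta", sort(unique(df$dimension))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$betti,
                                   colour = .data$dimension)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "filtration threshold f (1 - |rho|)",
                  y = "Betti number", colour = NULL,
                  title = attr(object, "pathway_id"),
                  subtitle = attr(object, "condition")) +
    ggplot2::theme_minimal()
}

#' Plot a persistence barcode
#'
#' One horizontal segment per bar; essential bars run to the right edge.
#'
#' @param object a `pph_barcode` from [persistence_pairs()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pph_barcode
#' @export
autoplot.pph_barcode <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_minimal() +
             ggplot2::labs(title = "empty barcode"))
  }
  df$bar <- factor(order(order(df$birth, df$death)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$bar)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$death,
                                       yend = .data$bar,
                                       linetype = .data$essential),
                          linewidth = 1) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "11")) +
    ggplot2::labs(x = "filtration threshold f", y = NULL,
                  linetype = "essential",
                  title = sprintf("dimension %d barcode", df$dimension[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a persistence landscape
#'
#' One line per landscape level `lambda_k`.
#'
#' @param object a [landscape()].
#' @param max_levels show at most this many dominant levels (default 15).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot persistence_landscape
#' @export
autoplot.persistence_landscape <- function(object, max_levels = 15, ...) {
  df <- tidy.persistence_landscape(object)
  df <- df[df$level <= max_levels, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = factor(.data$level),
                                   group = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t", y = expression(lambda[k](t)), colour = "level",
                  title = sprintf("dimension %s landscape",
                                  object$dimension)) +
    ggplot2::theme_minimal()
}
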