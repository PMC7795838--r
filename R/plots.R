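# ggplot2 displays for the main result types.

#' Radar chart of normalized lip-shape profiles
#'
#' One closed polygon per group over the six traits (DI, BL, BW, WL, A,
#' Se), drawn on polar coordinates in the style of per-population lip
#' radar charts.
#'
#' @param object A `radar_summary` ([summarize_population()] result).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radar_summary <- function(object, ...) {
  grp <- setdiff(names(object), c("trait", "mean", "sd", "n"))
  df <- dplyr::mutate(object, .angle = as.integer(.data$trait))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$mean))
  if (length(grp) == 1L) {
    p <- p + ggplot2::geom_polygon(
      ggplot2::aes(group = .data[[grp]], colour = .data[[grp]]),
      fill = NA, linewidth = 0.7
    )
  } else {
    p <- p + ggplot2::geom_polygon(ggplot2::aes(group = 1),
                                   fill = NA, colour = "steelblue",
                                   linewidth = 0.7)
  }
  p +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = NULL, y = "normalized value") +
    ggplot2::theme_minimal()
}

#' Evanno panel: mean ln P(D) and delta K across K
#'
#' @param object An `evanno_table`.
#' @param ... Unused.
#' @return A ggplot (two facets: mean ln P(D) with across-run SD bars,
#'   and delta K).
#' @export
autoplot.evanno_table <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(k = object$k, value = object$mean_lnp,
                   lo = object$mean_lnp - object$sd_lnp,
                   hi = object$mean_lnp + object$sd_lnp,
                   metric = "mean ln P(D)"),
    tibble::tibble(k = object$k, value = object$delta_k,
                   lo = NA_real_, hi = NA_real_, metric = "delta K")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "K", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked-bar admixture membership plot
#'
#' Individuals as unit-width stacked bars of cluster proportions, grouped
#' by population (populations separated by facet strips), ordered as in
#' [membership_table()].
#'
#' @param object A `membership_table` (or pass an `admixture_fit` through
#'   [membership_table()] first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.membership_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$individual, .data$order),
    y = .data$proportion, fill = .data$cluster
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~ .data$population, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "assignment proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' @rdname autoplot.membership_table
#' @export
autoplot.admixture_fit <- function(object, ...) {
  autoplot(membership_table(object), ...)
}
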