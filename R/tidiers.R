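# broom-style tidiers and plots for path_fit objects.

#' Tidy a fitted warped path model
#'
#' @param x A `path_fit` object.
#' @param ... Unused.
#' @return One row per edge: `hypothesis`, `term` (`source -> target`),
#'   `estimate`, `std.error`, `statistic`, `p.value`, `effect_size`.
#' @export
tidy.path_fit <- function(x, ...) {
  e <- x$edges
  tibble::tibble(
    hypothesis = e$hypothesis,
    term = paste(e$source, "->", e$target),
    estimate = e$beta,
    std.error = if ("se" %in% names(e)) e$se else NA_real_,
    statistic = if ("t" %in% names(e)) e$t else NA_real_,
    p.value = if ("p" %in% names(e)) e$p else NA_real_,
    effect_size = e$effect_size
  )
}

#' Glance at a fitted warped path model
#'
#' @param x A `path_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the ten fit/quality indices plus `n`,
#'   `n_edges` and `B`.
#' @export
glance.path_fit <- function(x, ...) {
  ix <- setNames(x$indices$value, x$indices$index)
  dplyr::bind_cols(
    tibble::as_tibble(as.list(ix)),
    tibble::tibble(n = x$n, n_edges = nrow(x$edges), B = x$B)
  )
}

#' Coefficient plot of a fitted warped path model
#'
#' Dot-and-interval plot of the standardized path coefficients with
#' approximate 95% bootstrap intervals (estimate +/- 1.96 SE) when
#' inference is available.
#'
#' @param object A `path_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.path_fit <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = rev(d$term))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term))
  if (!all(is.na(d$std.error))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2, colour = "grey50")
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(colour = "#b2182b", size = 2) +
    ggplot2::labs(x = "Standardized path coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
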