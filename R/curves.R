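# Fitted relationship curves and their shape classification.

#' Extract the fitted warp curve of an edge
#'
#' Evaluates the edge's fitted warp polynomial on a grid over the observed
#' standardized range of the source variable, for export or plotting, and
#' classifies its shape from the sign pattern of the fitted derivatives.
#'
#' @param fit A `path_fit` object.
#' @param source,target Variable names identifying the edge.
#' @param n_points Grid size.
#' @return A tibble with columns `x` and `y_hat`, with attributes `shape`
#'   (see [classify_curve_shape()]) and `edge`.
#' @export
relationship_curve <- function(fit, source, target, n_points = 101) {
  stopifnot(inherits(fit, "path_fit"))
  i <- which(fit$edges$source == source & fit$edges$target == target)
  if (!length(i)) {
    abort(sprintf("No fitted edge %s -> %s.", source, target),
          class = "obesipath_state_error")
  }
  i <- i[1]
  w <- fit$warped[[i]]
  if (is.null(w)) {
    abort("Edge has not been fitted.", class = "obesipath_state_error")
  }
  x_obs <- fit$data[[source]]
  grid <- seq(min(x_obs), max(x_obs), length.out = n_points)
  coefs <- w$coefs
  y_hat <- drop(outer(grid, 0:(length(coefs) - 1), `^`) %*% coefs)
  shape <- classify_curve_shape(grid, y_hat, coefs)
  out <- tibble::tibble(x = grid, y_hat = y_hat)
  attr(out, "shape") <- shape
  attr(out, "edge") <- paste(source, "->", target)
  out
}

#' All fitted relationship curves of a model
#'
#' @param fit A `path_fit` object.
#' @param n_points Grid size per edge.
#' @return A long tibble with columns `hypothesis`, `source`, `target`,
#'   `shape`, `x`, `y_hat`.
#' @export
relationship_curves <- function(fit, n_points = 101) {
  purrr::map_dfr(seq_len(nrow(fit$edges)), function(i) {
    cv <- relationship_curve(fit, fit$edges$source[i], fit$edges$target[i],
                             n_points)
    tibble::tibble(hypothesis = fit$edges$hypothesis[i],
                   source = fit$edges$source[i],
                   target = fit$edges$target[i],
                   shape = attr(cv, "shape"),
                   x = cv$x, y_hat = cv$y_hat)
  })
}

#' Classify the shape of a fitted polynomial curve
#'
#' Labels a fitted warp curve as one of `linear`, `U`, `inverted-U`, `S`,
#' `inverted-S`, `J` or `exponential-like` from the sign pattern of its
#' first and second derivatives over the observed range:
#'
#' * curves whose deviation from their best linear approximation (over the
#'   central 80% of the range) stays below 30% of their own spread are
#'   `linear`;
#' * two interior stationary points (a full cubic): `S` when the leading
#'   coefficient is positive, `inverted-S` when negative;
#' * one interior stationary point: an interior minimum is `U` (or `J`
#'   when the two arms are strongly asymmetric, rise at least 4 times the
#'   fall); an interior maximum is `inverted-U`;
#' * monotone with an interior inflection: increasing curves are `S`
#'   (acceleration then deceleration) or `J` (deceleration then
#'   acceleration); decreasing curves are `inverted-S`;
#' * monotone and uniformly convex or concave: `exponential-like`.
#'
#' @param x Grid of x values (ascending).
#' @param y Fitted values on the grid.
#' @param coefs Polynomial coefficients (intercept first); optional, used
#'   for the leading-sign rule.
#' @return A single character label.
#' @export
classify_curve_shape <- function(x, y, coefs = NULL) {
  rng <- diff(range(y))
  if (rng == 0) return("linear")
  # Linearity screen on the central 80% of the range (polynomial overfit
  # concentrates at the extremes): relative SD of the deviation from the
  # best linear approximation below 0.3 reads as linear.
  k <- length(x)
  tr <- ceiling(0.1 * k):floor(0.9 * k)
  lin <- stats::lm.fit(cbind(1, x[tr]), y[tr])
  s <- sd(y[tr])
  if (s == 0 || sd(lin$residuals) < 0.3 * s) return("linear")

  dy <- diff(y) / diff(x)
  d2y <- diff(dy) / diff(x[-1])
  margin <- 0.02 * (length(dy) - 1)
  interior <- function(k, len) k > 1 + margin & k < len - margin
  sc1 <- which(dy[-1] * dy[-length(dy)] < 0)
  sc1 <- sc1[interior(sc1, length(dy))]
  sc2 <- which(d2y[-1] * d2y[-length(d2y)] < 0)
  sc2 <- sc2[interior(sc2, length(d2y))]
  leading <- if (!is.null(coefs)) tail(coefs, 1) else NA_real_

  if (length(sc1) >= 2) {
    if (is.finite(leading) && leading < 0) return("inverted-S")
    return("S")
  }
  if (length(sc1) == 1) {
    k <- sc1[1]
    if (dy[k] < 0) {                      # interior minimum
      y_min <- min(y)
      fall <- y[1] - y_min
      rise <- y[length(y)] - y_min
      if (fall > 0 && rise / fall >= 4) return("J")
      if (rise > 0 && fall / rise >= 4) return("J")
      return("U")
    }
    return("inverted-U")                  # interior maximum
  }
  increasing <- y[length(y)] > y[1]
  if (length(sc2) >= 1) {
    k <- sc2[1]
    if (increasing) {
      if (d2y[k] > 0) return("S") else return("J")
    }
    return("inverted-S")
  }
  "exponential-like"
}

#' Plot a fitted relationship curve
#'
#' @inheritParams relationship_curve
#' @param points Overlay the observed standardized data.
#' @return A ggplot object.
#' @export
plot_relationship_curve <- function(fit, source, target, points = TRUE) {
  cv <- relationship_curve(fit, source, target)
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$x, y = .data$y_hat))
  if (points) {
    obs <- tibble::tibble(x = fit$data[[source]], y = fit$data[[target]])
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 alpha = 0.3, colour = "grey40")
  }
  p +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(
      x = paste0(source, " (standardized)"),
      y = paste0(target, " (fitted warp)"),
      title = attr(cv, "edge"),
      subtitle = paste("shape:", attr(cv, "shape"))
    ) +
    ggplot2::theme_minimal()
}
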