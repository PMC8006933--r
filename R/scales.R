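# ATOP / BAOP instrument scoring.
#
# Both instruments are scored by the same three steps: negate the reversed
# items, sum all items, then add a fixed offset that shifts the attainable
# range onto [0, 2 * offset].

#' Define a summated Likert scale
#'
#' @param n_items Number of items.
#' @param reversed_items 1-based indices of reverse-scored items.
#' @param offset Constant added after summation (defaults to
#'   `n_items * max(abs(admissible_responses))`, which maps the attainable
#'   range onto `[0, 2 * offset]`).
#' @param admissible_responses Integer responses a subject may give. The
#'   bundled instruments use the 6-point scale -3..-1, +1..+3; set
#'   `allow_zero = TRUE` to admit a neutral 0.
#' @param allow_zero Admit 0 as a response.
#' @param name Instrument label.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(n_items, reversed_items, offset = NULL,
                             admissible_responses = c(-3:-1, 1:3),
                             allow_zero = FALSE, name = "scale") {
  if (allow_zero) admissible_responses <- sort(union(admissible_responses, 0L))
  if (length(reversed_items) && (any(reversed_items < 1) ||
                                 any(reversed_items > n_items))) {
    abort("`reversed_items` must lie in 1..n_items.",
          class = "obesipath_invalid_scale")
  }
  offset <- offset %||% (n_items * max(abs(admissible_responses)))
  structure(
    list(n_items = as.integer(n_items),
         reversed_items = as.integer(reversed_items),
         offset = as.integer(offset),
         admissible_responses = as.integer(admissible_responses),
         name = name),
    class = "scale_definition"
  )
}

#' @rdname scale_definition
#' @details `atop_scale()` is the 20-item Attitudes Toward Obese Persons
#'   instrument (reversed items 2-6, 10-12, 14-16, 19, 20; offset 60; scores
#'   0-120, higher = more positive attitudes). `baop_scale()` is the 8-item
#'   Beliefs About Obese Persons instrument (reversed items 1, 3-6, 8;
#'   offset 24; scores 0-48, higher = stronger belief that obesity is not
#'   under volitional control).
#' @export
atop_scale <- function(allow_zero = FALSE) {
  scale_definition(20L, c(2:6, 10:12, 14:16, 19:20),
                   allow_zero = allow_zero, name = "ATOP")
}

#' @rdname scale_definition
#' @export
baop_scale <- function(allow_zero = FALSE) {
  scale_definition(8L, c(1L, 3:6, 8L), allow_zero = allow_zero, name = "BAOP")
}

#' Score one response vector on a scale definition
#'
#' @param responses Integer vector of length `definition$n_items`.
#' @param definition A [scale_definition()].
#' @return Integer score (`sum after reversal + offset`).
#' @export
score_scale <- function(responses, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  if (length(responses) != definition$n_items) {
    abort(sprintf("%s expects %d responses, got %d.", definition$name,
                  definition$n_items, length(responses)),
          class = "obesipath_shape_error")
  }
  if (any(!responses %in% definition$admissible_responses)) {
    abort(sprintf("%s responses must be in {%s}.", definition$name,
                  paste(definition$admissible_responses, collapse = ", ")),
          class = "obesipath_invalid_response")
  }
  signs <- rep(1L, definition$n_items)
  signs[definition$reversed_items] <- -1L
  as.integer(sum(as.integer(responses) * signs) + definition$offset)
}

#' @rdname score_scale
#' @export
score_atop <- function(responses, allow_zero = FALSE) {
  score_scale(responses, atop_scale(allow_zero))
}

#' @rdname score_scale
#' @export
score_baop <- function(responses, allow_zero = FALSE) {
  score_scale(responses, baop_scale(allow_zero))
}

#' Score ATOP and BAOP item columns of a cohort table
#'
#' Expects item columns `atop_1` ... `atop_20` and `baop_1` ... `baop_8`;
#' appends `atop_score` and `baop_score`.
#'
#' @param data A data frame with the item columns.
#' @param atop,baop Scale definitions (bundled instruments by default).
#' @return The input as a tibble with score columns appended.
#' @export
score_scales <- function(data, atop = atop_scale(), baop = baop_scale()) {
  atop_cols <- paste0("atop_", seq_len(atop$n_items))
  baop_cols <- paste0("baop_", seq_len(baop$n_items))
  require_columns(data, c(atop_cols, baop_cols))
  out <- tibble::as_tibble(data)
  out$atop_score <- apply(as.matrix(out[atop_cols]), 1, score_scale,
                          definition = atop)
  out$baop_score <- apply(as.matrix(out[baop_cols]), 1, score_scale,
                          definition = baop)
  out
}
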