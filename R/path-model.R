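# Path-model specification: a directed edge list over observed variables,
# each edge carrying a warp mode and an expected sign.

WARP_MODES <- c("linear", "quadratic", "s_curve")

#' Specify a path model
#'
#' A path model is an ordered edge list over observed (single-indicator)
#' variables. Each edge names a source and a target column, the warp mode
#' used to transform the predictor (`linear`, `quadratic` or `s_curve` =
#' cubic), and an expected sign (`+`, `-` or `any`; metadata only — it never
#' influences estimation). Estimation is per endogenous equation, so the
#' edge list may contain feedback patterns across equations; duplicate
#' edges are rejected.
#'
#' @param edges A data frame with columns `source`, `target`, optionally
#'   `hypothesis`, `mode` and `expected_sign`.
#' @return A `path_model` object (validated tibble of edges).
#' @export
path_model <- function(edges) {
  edges <- tibble::as_tibble(edges)
  require_columns(edges, c("source", "target"))
  if (!"hypothesis" %in% names(edges)) {
    edges$hypothesis <- paste0("E", seq_len(nrow(edges)))
  }
  if (!"mode" %in% names(edges)) edges$mode <- "s_curve"
  if (!"expected_sign" %in% names(edges)) edges$expected_sign <- "any"
  if (any(!edges$mode %in% WARP_MODES)) {
    abort(sprintf("Warp modes must be one of: %s.",
                  paste(WARP_MODES, collapse = ", ")),
          class = "obesipath_model_error")
  }
  if (any(!edges$expected_sign %in% c("+", "-", "any"))) {
    abort("Expected signs must be '+', '-' or 'any'.",
          class = "obesipath_model_error")
  }
  if (any(edges$source == edges$target)) {
    abort("Self-loops are not allowed.", class = "obesipath_model_error")
  }
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) {
    abort("Duplicate edges are not allowed.", class = "obesipath_model_error")
  }
  edges <- edges[, c("hypothesis", "source", "target", "mode",
                     "expected_sign")]
  class(edges) <- c("path_model", class(edges))
  edges
}

#' Default structural model of body-weight drivers
#'
#' The fifteen hypothesised relationships shipped with the package:
#' socioeconomic variables (income band, marital status, gender, age,
#' university education), attitudes (ATOP) and beliefs (BAOP) about
#' obesity, body-image dissatisfaction, dieting, weight perception, and
#' elicited risk/loss aversion, arranged around BMI. Binary variables use
#' linear warps; continuous edges default to the cubic `s_curve` except the
#' risk-aversion edge, which is quadratic (an inverted-U relationship with
#' BMI). Expected signs are recorded as metadata.
#'
#' @return A [path_model()] with 15 edges and 5 endogenous equations.
#' @export
default_path_model <- function() {
  path_model(tibble::tribble(
    ~hypothesis, ~source,              ~target,      ~mode,       ~expected_sign,
    "H1",        "income_low",         "bmi",        "linear",    "+",
    "H2",        "married",            "bmi",        "linear",    "+",
    "H3",        "female",             "bmi",        "linear",    "+",
    "H4",        "age",                "bmi",        "s_curve",   "+",
    "H5",        "university",         "bmi",        "linear",    "-",
    "H6",        "atop_score",         "bmi",        "s_curve",   "+",
    "H7",        "baop_score",         "atop_score", "s_curve",   "+",
    "H8",        "baop_score",         "bmi",        "s_curve",   "+",
    "H9",        "bmi",                "bid_degree", "s_curve",   "+",
    "H10",       "diet",               "bmi",        "linear",    "+",
    "H11",       "bid_degree",         "diet",       "s_curve",   "+",
    "H12",       "correct_perception", "bmi",        "linear",    "-",
    "H13",       "sigma",              "bmi",        "quadratic", "+",
    "H14",       "lambda",             "bmi",        "s_curve",   "+",
    "H15",       "sigma",              "lambda",     "s_curve",   "-"
  ))
}

#' Read / write a path-model specification file
#'
#' Models are stored as YAML (or JSON) edge lists with fields `hypothesis`,
#' `source`, `target`, `mode` and `expected_sign`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param model A [path_model()].
#' @export
read_path_model <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    dplyr::bind_rows(lapply(yaml::read_yaml(path), tibble::as_tibble))
  }
  path_model(raw)
}

#' @rdname read_path_model
#' @export
write_path_model <- function(model, path) {
  stopifnot(inherits(model, "path_model"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(model), path, dataframe = "rows")
  } else {
    yaml::write_yaml(lapply(seq_len(nrow(model)), function(i)
      as.list(model[i, ])), path)
  }
  invisible(path)
}

model_variables <- function(model) unique(c(model$source, model$target))
model_targets <- function(model) unique(model$target)
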