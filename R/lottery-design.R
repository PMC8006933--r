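# Three-series multiple-price-list lottery design.
#
# The bundled default follows the canonical three-series structure used in
# field elicitations of prospect-theory parameters: series 1 and 2 are
# all-gain menus in which Plan A is fixed and Plan B's high payoff escalates
# down the rows (so Plan B's attractiveness is monotone increasing and any
# fixed parameter triple implies a unique switch row); series 3 mixes gains
# and losses at 50/50 odds in both plans, which makes the loss-aversion
# inequalities independent of the probability-weighting parameter. Payoffs
# are read in euros; the scale is irrelevant to choices under a power value
# function.

#' Bundled three-series lottery design
#'
#' Returns the default 35-row design: 14 rows in series 1, 14 in series 2
#' and 7 mixed gain/loss rows in series 3. Each row pits Plan A
#' `(x_a with prob p_a, else y_a)` against Plan B `(x_b with prob p_b,
#' else y_b)`.
#'
#' @return A tibble with columns `series`, `row`, `x_a`, `y_a`, `p_a`,
#'   `x_b`, `y_b`, `p_b`.
#' @export
default_lottery_design <- function() {
  s1_b <- c(68, 75, 83, 93, 106, 125, 150, 185, 220, 300, 400, 600, 1000, 1700)
  s2_b <- c(54, 56, 58, 60, 62, 65, 68, 72, 77, 83, 90, 100, 110, 130)
  d <- dplyr::bind_rows(
    tibble::tibble(series = 1L, row = 1:14,
                   x_a = 40, y_a = 10, p_a = 0.3,
                   x_b = s1_b, y_b = 5, p_b = 0.1),
    tibble::tibble(series = 2L, row = 1:14,
                   x_a = 40, y_a = 30, p_a = 0.9,
                   x_b = s2_b, y_b = 5, p_b = 0.7),
    tibble::tibble(series = 3L, row = 1:7,
                   x_a = c(25, 4, 1, 1, 1, 1, 1),
                   y_a = c(-4, -4, -4, -4, -8, -8, -8), p_a = 0.5,
                   x_b = 30,
                   y_b = c(-21, -21, -21, -16, -16, -14, -11), p_b = 0.5)
  )
  validate_lottery_design(d)
}

#' Validate a lottery design table
#'
#' Checks the structural invariants the switching-point inversion relies on:
#' probabilities in `[0, 1]`; series 1 and 2 all-gain; every series-3 row at
#' `p = 0.5` in both plans with Plan B's loss strictly deeper than Plan A's.
#'
#' @param design A design tibble (see [default_lottery_design()]).
#' @return The design, invisibly coerced to a tibble, or an error.
#' @export
validate_lottery_design <- function(design) {
  require_columns(design, c("series", "row", "x_a", "y_a", "p_a",
                            "x_b", "y_b", "p_b"))
  design <- tibble::as_tibble(design)
  probs <- c(design$p_a, design$p_b)
  if (any(probs < 0 | probs > 1)) {
    abort("Design probabilities must lie in [0, 1].",
          class = "obesipath_invalid_design")
  }
  gains <- design[design$series %in% c(1L, 2L), ]
  if (any(c(gains$x_a, gains$y_a, gains$x_b, gains$y_b) < 0)) {
    abort("Series 1 and 2 payoffs must be non-negative.",
          class = "obesipath_invalid_design")
  }
  s3 <- design[design$series == 3L, ]
  if (nrow(s3) && any(s3$p_a != 0.5 | s3$p_b != 0.5)) {
    abort("Every series-3 row must have p = 0.5 in both plans.",
          class = "obesipath_invalid_design")
  }
  if (nrow(s3) && any(abs(s3$y_b) <= abs(s3$y_a))) {
    abort("Series-3 Plan B losses must be strictly deeper than Plan A's.",
          class = "obesipath_invalid_design")
  }
  design
}

#' Read / write a lottery design file
#'
#' Designs are stored as YAML (or JSON) with one record per row carrying
#' `series`, `row` and the six payoff/probability fields.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param design A design tibble.
#' @return `read_lottery_design()` returns a validated design tibble;
#'   `write_lottery_design()` returns `path` invisibly.
#' @export
read_lottery_design <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.data.frame(raw)) raw <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  raw$series <- as.integer(raw$series)
  raw$row <- as.integer(raw$row)
  validate_lottery_design(raw)
}

#' @rdname read_lottery_design
#' @export
write_lottery_design <- function(design, path) {
  design <- validate_lottery_design(design)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(design, path, dataframe = "rows", digits = NA)
  } else {
    yaml::write_yaml(lapply(seq_len(nrow(design)), function(i)
      as.list(design[i, ])), path)
  }
  invisible(path)
}

series_lengths <- function(design) {
  vapply(split(design$row, design$series), length, integer(1))
}
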