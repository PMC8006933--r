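# BMI, weight-status categories, Stunkard figure-rating measures.

#' Weight-status category levels
#'
#' Ordered labels shared by BMI classification and the Stunkard figure
#' mapping; the integer rank (underweight = 1 ... obese = 4) underlies the
#' weight-perception score.
#'
#' @export
weight_status_levels <- c("underweight", "normal", "overweight", "obese")

#' Compute body mass index
#'
#' BMI = weight / height^2 in kg/m^2.
#'
#' @param weight Body weight in kilograms (> 0).
#' @param height Standing height in metres (> 0).
#' @return Numeric vector of BMI values.
#' @examples
#' compute_bmi(70, 1.70)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    abort("`weight` and `height` must be finite and positive.",
          class = "obesipath_invalid_measurement")
  }
  weight / height^2
}

#' Classify BMI into weight-status categories
#'
#' WHO cut-offs at 18.5, 25 and 30 kg/m^2, with half-open lower-inclusive
#' intervals: `[18.5, 25)` is normal, `[25, 30)` overweight, `[30, Inf)`
#' obese.
#'
#' @param bmi Numeric BMI values (> 0).
#' @return Factor with levels [weight_status_levels].
#' @examples
#' classify_bmi(c(17.5, 22, 25.17, 31))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be finite and positive.",
          class = "obesipath_invalid_measurement")
  }
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = weight_status_levels)
}

#' Map a Stunkard silhouette to a weight-status category
#'
#' The nine-figure rating scale collapses to the four BMI categories:
#' figures 1-2 underweight, 3-4 normal, 5-7 overweight, 8-9 obese.
#'
#' @param figure Integer silhouette number(s) in 1..9.
#' @return Factor with levels [weight_status_levels].
#' @export
stunkard_category <- function(figure) {
  check_figure(figure)
  idx <- c(1, 1, 2, 2, 3, 3, 3, 4, 4)[figure]
  factor(weight_status_levels[idx], levels = weight_status_levels)
}

check_figure <- function(figure, arg = "figure") {
  if (any(!is.finite(figure)) || any(figure != round(figure)) ||
      any(figure < 1) || any(figure > 9)) {
    abort(sprintf("`%s` must be an integer silhouette in 1..9.", arg),
          class = "obesipath_invalid_figure")
  }
  invisible(figure)
}

#' Body-image dissatisfaction from current and preferred silhouettes
#'
#' BID is the signed discrepancy current - preferred; a positive value means
#' the respondent desires a thinner figure. The degree of dissatisfaction is
#' `abs(bid)`; the signed value is retained.
#'
#' @param current,preferred Integer silhouettes in 1..9.
#' @return A tibble with columns `bid`, `bid_degree` and `bid_group`
#'   (factor: satisfied / desires_thinner / desires_heavier).
#' @examples
#' body_image_dissatisfaction(7, 4)
#' @export
body_image_dissatisfaction <- function(current, preferred) {
  check_figure(current, "current")
  check_figure(preferred, "preferred")
  bid <- as.integer(current - preferred)
  group <- dplyr::case_when(
    bid > 0 ~ "desires_thinner",
    bid < 0 ~ "desires_heavier",
    TRUE    ~ "satisfied"
  )
  tibble::tibble(
    bid = bid,
    bid_degree = abs(bid),
    bid_group = factor(group, levels = c("satisfied", "desires_thinner",
                                         "desires_heavier"))
  )
}

#' Weight-perception score
#'
#' Compares the weight category implied by the chosen "current" silhouette
#' with the measured BMI category, on the rank scale underweight = 1 ...
#' obese = 4. Negative (positive) scores mean the respondent perceives
#' themselves thinner (heavier) than measured; zero is correct perception.
#'
#' @param current_figure Integer silhouette in 1..9.
#' @param bmi Measured BMI in kg/m^2.
#' @return Integer vector of perception scores in -3..3.
#' @export
weight_perception <- function(current_figure, bmi) {
  perceived <- as.integer(stunkard_category(current_figure))
  measured <- as.integer(classify_bmi(bmi))
  as.integer(perceived - measured)
}

#' Add anthropometric and body-image variables to a cohort table
#'
#' Data-frame-first wrapper computing `bmi`, `bmi_category`, `bid`,
#' `bid_degree`, `bid_group`, `perception_score` and `correct_perception`
#' from the raw survey columns `weight_kg`, `height_m`, `stunkard_current`
#' and `stunkard_preferred`.
#'
#' @param data A data frame of subject records.
#' @return The input as a tibble with the derived columns appended.
#' @export
add_anthropometrics <- function(data) {
  require_columns(data, c("weight_kg", "height_m",
                          "stunkard_current", "stunkard_preferred"))
  out <- tibble::as_tibble(data)
  out$bmi <- compute_bmi(out$weight_kg, out$height_m)
  out$bmi_category <- classify_bmi(out$bmi)
  bid <- body_image_dissatisfaction(out$stunkard_current, out$stunkard_preferred)
  out <- dplyr::bind_cols(out, bid)
  out$perception_score <- weight_perception(out$stunkard_current, out$bmi)
  out$correct_perception <- as.integer(out$perception_score == 0L)
  out
}

require_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "obesipath_missing_column")
  }
  invisible(data)
}
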