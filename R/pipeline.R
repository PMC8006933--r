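# Pipeline orchestration: simulate -> score -> fit, with report tables and
# run manifests.

#' Significance stars
#'
#' Three-level scheme: `***` p < 0.01, `**` p < 0.05, `*` p < 0.1,
#' otherwise `n.s.`.
#'
#' @param p Numeric p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p)  ~ "",
    p < 0.01  ~ "***",
    p < 0.05  ~ "**",
    p < 0.1   ~ "*",
    TRUE      ~ "n.s."
  )
}

#' Cohen effect-size labels
#'
#' Bands at 0.02 / 0.15 / 0.35 for small / medium / large effects; values
#' below 0.02 are labelled negligible.
#'
#' @param effect_size Numeric effect sizes (`|beta x corr|`).
#' @return Factor of labels.
#' @export
effect_size_label <- function(effect_size) {
  cut(effect_size, breaks = c(-Inf, 0.02, 0.15, 0.35, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE)
}

#' Score a raw cohort table
#'
#' Applies the full scoring chain to a raw survey table: anthropometrics
#' and body image ([add_anthropometrics()]), ATOP/BAOP instrument scores
#' ([score_scales()]) and prospect-theory elicitation ([elicit_pt()]).
#'
#' @param data Raw subject records (see [generate_cohort()] for the column
#'   contract).
#' @param design Lottery design behind the choice columns.
#' @param atop,baop Scale definitions.
#' @param drop_invalid Drop subjects whose lottery choices are non-monotone
#'   or inconsistent (they are counted in a warning); if `FALSE` they are
#'   kept with `NA` parameters.
#' @return A scored tibble with all derived variables appended.
#' @export
score_cohort <- function(data, design = default_lottery_design(),
                         atop = atop_scale(), baop = baop_scale(),
                         drop_invalid = TRUE) {
  out <- add_anthropometrics(data)
  out <- score_scales(out, atop = atop, baop = baop)
  out <- elicit_pt(out, design = design)
  if (drop_invalid && any(!out$pt_valid)) {
    out <- out[out$pt_valid, ]
  }
  out
}

#' Descriptive-statistics table of a scored cohort
#'
#' A survey-style descriptive summary: percentage shares of the categorical
#' characteristics, then Mean / Min / Max / Std. Dev. of the continuous
#' derived variables.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @return A tibble with columns `variable`, `percent`, `mean`, `min`,
#'   `max`, `sd` (percent populated for shares, moments for continuous
#'   variables).
#' @export
descriptive_table <- function(scored) {
  share_vars <- c("Gender (Female = 1)" = "female",
                  "Marital status (Married = 1)" = "married",
                  "Education (University = 1)" = "university",
                  "Income Levels (<1,500 = 1)" = "income_low",
                  "Number of respondents on Diet" = "diet")
  share_vars <- share_vars[share_vars %in% names(scored)]
  shares <- purrr::imap_dfr(share_vars, function(v, label) {
    tibble::tibble(variable = label,
                   percent = 100 * mean(scored[[v]], na.rm = TRUE),
                   mean = NA_real_, min = NA_real_, max = NA_real_,
                   sd = NA_real_)
  })
  cont_vars <- c("Age" = "age",
                 "Average risk aversion coefficient" = "sigma",
                 "Average loss aversion coefficient" = "lambda",
                 "Body mass index" = "bmi",
                 "Degree of body image dissatisfaction" = "bid_degree",
                 "Belief about Obese People (BAOP)" = "baop_score",
                 "Attitude toward Obese Persons (ATOP)" = "atop_score")
  cont_vars <- cont_vars[cont_vars %in% names(scored)]
  moments <- purrr::imap_dfr(cont_vars, function(v, label) {
    x <- scored[[v]]
    tibble::tibble(variable = label, percent = NA_real_,
                   mean = mean(x, na.rm = TRUE), min = min(x, na.rm = TRUE),
                   max = max(x, na.rm = TRUE), sd = sd(x[!is.na(x)]))
  })
  dplyr::bind_rows(shares, moments)
}

#' Hypothesis (edge) report table of a fitted path model
#'
#' One row per edge in the layout of a structural-model results table:
#' hypothesis id, relationship, expected sign, standardized coefficient,
#' bootstrap standard error, significance stars, effect size with its
#' Cohen band, and whether the estimated sign matches the expectation.
#'
#' @param fit A `path_fit` object.
#' @return A tibble.
#' @export
edge_table <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  e <- fit$edges
  tibble::tibble(
    hypothesis = e$hypothesis,
    relationship = paste(e$source, "->", e$target),
    expected_sign = e$expected_sign,
    parameter = e$beta,
    std_error = if ("se" %in% names(e)) e$se else NA_real_,
    p_value = if ("p" %in% names(e)) e$p else NA_real_,
    significance = significance_stars(if ("p" %in% names(e)) e$p else NA),
    effect_size = e$effect_size,
    effect_label = effect_size_label(e$effect_size),
    sign_matches_expected = dplyr::case_when(
      e$expected_sign == "any" ~ NA,
      e$expected_sign == "+" ~ e$beta > 0,
      TRUE ~ e$beta < 0
    )
  )
}

write_manifest <- function(path, config) {
  config$written_by <- paste0("obesipath ",
                              as.character(utils::packageVersion("obesipath")))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Run the simulation stage
#'
#' Generates a synthetic cohort and writes `subjects.csv`, `truth.json`,
#' `design.yaml` and a `manifest.json` echoing the fully resolved
#' configuration and seed under `out_dir`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @return The cohort, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  ensure_dir(out_dir)
  cohort <- generate_cohort(config)
  export_fixture(cohort, out_dir)
  manifest <- config[vapply(config, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  manifest$stage <- "simulate"
  manifest$edges <- config$edges
  write_manifest(file.path(out_dir, "manifest.json"), manifest)
  invisible(cohort)
}

#' Run the scoring stage
#'
#' Reads (or takes) a raw subject table, applies the scoring chain, and
#' writes `scored.csv`, `descriptives.csv` and a manifest. Subjects with
#' non-monotone lottery choices are excluded and counted.
#'
#' @param subjects A data frame or path to a subjects CSV.
#' @param out_dir Output directory.
#' @param design Lottery design (tibble or path to a design file).
#' @return The scored tibble, invisibly.
#' @export
run_score <- function(subjects, out_dir,
                      design = default_lottery_design()) {
  ensure_dir(out_dir)
  if (is.character(subjects)) {
    subjects <- readr::read_csv(subjects, show_col_types = FALSE)
  }
  if (is.character(design)) design <- read_lottery_design(design)
  n_in <- nrow(subjects)
  scored <- score_cohort(subjects, design = design)
  readr::write_csv(scored, file.path(out_dir, "scored.csv"))
  readr::write_csv(descriptive_table(scored),
                   file.path(out_dir, "descriptives.csv"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 list(stage = "score", n_input = n_in,
                      n_scored = nrow(scored),
                      n_excluded = n_in - nrow(scored)))
  invisible(scored)
}

#' Run the path-analysis stage
#'
#' Fits the warped path model with bootstrap inference and writes the
#' hypothesis table (`edge_table.csv`), the ten fit indices
#' (`fit_indices.csv`), the per-edge fitted curves (`curves.csv`) and a
#' manifest.
#'
#' @param scored A scored data frame or path to a scored CSV.
#' @param out_dir Output directory.
#' @param model A [path_model()] (or path to a model file).
#' @param B Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return The `path_fit`, invisibly.
#' @export
run_fit <- function(scored, out_dir, model = default_path_model(),
                    B = 5000, seed = 1) {
  ensure_dir(out_dir)
  if (is.character(scored)) {
    scored <- readr::read_csv(scored, show_col_types = FALSE)
  }
  if (is.character(model)) model <- read_path_model(model)
  fit <- fit_path_model(scored, model, B = B, seed = seed)
  readr::write_csv(edge_table(fit), file.path(out_dir, "edge_table.csv"))
  readr::write_csv(fit$indices, file.path(out_dir, "fit_indices.csv"))
  readr::write_csv(relationship_curves(fit), file.path(out_dir, "curves.csv"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 list(stage = "fit", n = fit$n, B = B, seed = seed,
                      model = as.data.frame(model)))
  invisible(fit)
}
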