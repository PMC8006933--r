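# Seed-reproducible synthetic survey cohorts with known structural truth.
#
# The generator emulates the record layout and the structural relations the
# analysis assumes: demographics drawn from configured mixtures, BMI built
# from configured structural equations on standardized latents (cubic in
# age, linear in the binary covariates, attitude/belief terms), body-image
# dissatisfaction from BMI, silhouette choices category-consistent with BMI
# up to a configurable misperception rate, Likert item vectors whose scored
# totals track the latent attitude/belief levels, and lottery choices
# simulated from per-subject true prospect-theory parameters.

truth_form_fns <- list(
  linear = function(x) x,
  quadratic = function(x) -(x^2),        # inverted-U orientation
  cubic = function(x) x^3 - 1.5 * x,     # rise-fall-rise on the std scale
  exponential = function(x) exp(x)
)

apply_form <- function(x, form) {
  f <- truth_form_fns[[form]]
  if (is.null(f)) {
    abort(sprintf("Unknown generating form '%s'.", form),
          class = "obesipath_config_error")
  }
  z <- f(zscore_safe(x))
  zscore_safe(z)
}

zscore_safe <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Default generating structural edges
#'
#' The per-edge true standardized coefficients and functional forms used by
#' [generate_cohort()]: linear effects for the binary covariates, a
#' rise-fall-rise cubic for age, convex (exponential) maps for the
#' belief-to-attitude and BMI-to-dissatisfaction edges, an inverted-U
#' quadratic for risk aversion, and modest cubic effects elsewhere.
#'
#' @return A tibble with columns `source`, `target`, `coef`, `form`.
#' @export
default_truth_edges <- function() {
  tibble::tribble(
    ~source,       ~target,      ~coef,  ~form,
    "income_low",  "bmi",         0.12,  "linear",
    "married",     "bmi",         0.14,  "linear",
    "female",      "bmi",        -0.21,  "linear",
    "age",         "bmi",         0.18,  "cubic",
    "university",  "bmi",        -0.10,  "linear",
    "atop_score",  "bmi",         0.26,  "cubic",
    "baop_score",  "atop_score",  0.33,  "exponential",
    "baop_score",  "bmi",         0.14,  "cubic",
    "bmi",         "bid_degree",  0.69,  "exponential",
    "diet",        "bmi",         0.25,  "linear",
    "bid_degree",  "diet",        0.20,  "exponential",
    "sigma",       "bmi",         0.16,  "quadratic",
    "lambda",      "bmi",        -0.09,  "cubic",
    "sigma",       "lambda",     -0.21,  "cubic"
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults imitate the marginals of an adult urban survey population:
#' 70% female, 69% married, 36% university-educated, 32% in the low income
#' band, 24% on a diet; age with mean 45.8 and SD 11.22 truncated to
#' [20, 70]; BMI centred at 25.17 with SD 4.21; prospect-theory parameters
#' centred at sigma 0.58 (SD 0.37), lambda 3.67 (SD 3.88), gamma 0.7
#' (SD 0.15). Only first and second moments of these marginals are
#' emulated.
#'
#' @param n_subjects Number of respondents (>= 10).
#' @param seed Integer seed; every draw of the generator flows from it.
#' @param share_female,share_married,share_university,share_income_low,share_diet
#'   Mixture shares in [0, 1].
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param bmi_mean,bmi_sd BMI location/scale on the kg/m^2 scale.
#' @param sigma_mean,sigma_sd,lambda_mean,lambda_sd,gamma_mean,gamma_sd
#'   Population distribution of the prospect-theory parameters (normals,
#'   clipped to sigma [0.05, 1.5], lambda [0.05, 11.79], gamma [0.2, 1]).
#' @param edges Generating structural edges ([default_truth_edges()]).
#' @param noise_bmi Residual SD of the standardized BMI equation; `NULL`
#'   scales the residual so the latent has roughly unit variance.
#' @param misperception_noise Probability that a subject's current
#'   silhouette is drawn one weight category away from the measured one.
#' @param choice_noise Logistic temperature of the lottery choices
#'   (0 = deterministic).
#' @param item_jitter Half-width of the uniform jitter applied when
#'   quantizing latent scale levels to Likert items.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 172, seed = 1,
                          share_female = 0.70, share_married = 0.69,
                          share_university = 0.36, share_income_low = 0.32,
                          share_diet = 0.24,
                          age_mean = 45.8, age_sd = 11.22,
                          age_range = c(20, 70),
                          bmi_mean = 25.17, bmi_sd = 4.21,
                          sigma_mean = 0.58, sigma_sd = 0.37,
                          lambda_mean = 3.67, lambda_sd = 3.88,
                          gamma_mean = 0.7, gamma_sd = 0.15,
                          edges = default_truth_edges(),
                          noise_bmi = NULL,
                          misperception_noise = 0.1,
                          choice_noise = 0.005,
                          item_jitter = 1.5) {
  cfg <- as.list(environment())
  shares <- c(share_female, share_married, share_university,
              share_income_low, share_diet)
  if (any(!is.finite(shares)) || any(shares < 0 | shares > 1)) {
    abort("All mixture shares must lie in [0, 1].",
          class = "obesipath_config_error")
  }
  if (!is.finite(n_subjects) || n_subjects < 10) {
    abort("`n_subjects` must be at least 10.",
          class = "obesipath_config_error")
  }
  if (misperception_noise < 0 || misperception_noise > 1) {
    abort("`misperception_noise` must lie in [0, 1].",
          class = "obesipath_config_error")
  }
  if (choice_noise < 0 || (!is.null(noise_bmi) && noise_bmi < 0)) {
    abort("Noise scales must be non-negative.",
          class = "obesipath_config_error")
  }
  structure(cfg, class = "cohort_config")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

edge_terms <- function(edges, target, inputs) {
  sel <- edges[edges$target == target, ]
  if (!nrow(sel)) return(list(value = 0, ssq = 0))
  terms <- purrr::map2(sel$source, sel$form, function(src, form) {
    apply_form(inputs[[src]], form)
  })
  value <- Reduce(`+`, purrr::map2(terms, sel$coef, `*`))
  list(value = value, ssq = sum(sel$coef^2))
}

#' Generate a synthetic survey cohort
#'
#' Draws a full subject-level survey table (demographics, anthropometry,
#' Stunkard silhouettes, ATOP/BAOP item responses, 35 lottery choices)
#' together with the ground truth behind it (per-edge generating
#' coefficients and forms, per-subject true prospect-theory parameters and
#' latent attitude/belief levels). Runs with the same configuration are
#' byte-identical.
#'
#' @param config A [cohort_config()].
#' @return A list with class `obesipath_cohort`: `$subjects` (tibble, one
#'   row per respondent) and `$truth` (list).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  edges <- config$edges

  female <- rbinom(n, 1, config$share_female)
  married <- rbinom(n, 1, config$share_married)
  university <- rbinom(n, 1, config$share_university)
  income_low <- rbinom(n, 1, config$share_income_low)
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  diet_propensity <- rnorm(n)

  sigma <- pmin(pmax(rnorm(n, config$sigma_mean, config$sigma_sd), 0.05), 1.5)
  lam_eq <- edge_terms(edges, "lambda", list(sigma = sigma))
  lambda_z <- lam_eq$value +
    sqrt(max(0.05, 1 - lam_eq$ssq)) * rnorm(n)
  lambda <- pmin(pmax(config$lambda_mean + config$lambda_sd *
                        zscore_safe(lambda_z), 0.05), 11.79)
  gamma <- pmin(pmax(rnorm(n, config$gamma_mean, config$gamma_sd), 0.2), 1)

  baop_latent <- rnorm(n)
  atop_eq <- edge_terms(edges, "atop_score", list(baop_score = baop_latent))
  atop_latent <- atop_eq$value + sqrt(max(0.05, 1 - atop_eq$ssq)) * rnorm(n)

  bmi_inputs <- list(income_low = income_low, married = married,
                     female = female, age = age, university = university,
                     atop_score = atop_latent, baop_score = baop_latent,
                     diet = diet_propensity, sigma = sigma, lambda = lambda,
                     correct_perception = rnorm(n))
  bmi_eq <- edge_terms(edges, "bmi", bmi_inputs)
  res_sd <- config$noise_bmi %||% sqrt(max(0.05, 1 - bmi_eq$ssq))
  bmi_z <- bmi_eq$value + res_sd * rnorm(n)
  bmi <- pmin(pmax(config$bmi_mean + config$bmi_sd * zscore_safe(bmi_z),
                   16), 47)

  height <- pmin(pmax(rnorm(n, 1.66, 0.08), 1.45), 1.95)
  weight <- round(bmi * height^2, 1)
  height <- round(height, 2)
  bmi_measured <- weight / height^2

  bid_eq <- edge_terms(edges, "bid_degree", list(bmi = bmi_z))
  bid_latent <- bid_eq$value + sqrt(max(0.05, 1 - bid_eq$ssq)) * rnorm(n)
  bid_target <- pmin(pmax(round(1.0 + 1.2 * bid_latent), -3L), 6L)

  cat_measured <- as.integer(classify_bmi(bmi_measured))
  shift <- rbinom(n, 1, config$misperception_noise) *
    sample(c(-1L, 1L), n, replace = TRUE)
  cat_perceived <- pmin(pmax(cat_measured + shift, 1L), 4L)
  figure_sets <- list(1:2, 3:4, 5:7, 8:9)
  current <- vapply(cat_perceived, function(k) {
    s <- figure_sets[[k]]
    s[sample.int(length(s), 1)]
  }, integer(1))
  preferred <- pmin(pmax(current - bid_target, 1L), 9L)

  diet_eq <- edge_terms(edges, "diet",
                        list(bid_degree = abs(current - preferred) + 0.01 * rnorm(n)))
  diet_latent <- diet_eq$value + 0.6 * diet_propensity + 0.35 * rnorm(n)
  diet <- as.integer(diet_latent >= quantile(diet_latent,
                                             1 - config$share_diet))

  atop_target <- pmin(pmax(round(65.33 + 14.93 * zscore_safe(atop_latent)),
                           0L), 120L)
  baop_target <- pmin(pmax(round(21.65 + 4.31 * zscore_safe(baop_latent)),
                           0L), 48L)
  atop_items <- items_from_target(atop_target, atop_scale(),
                                  config$item_jitter)
  baop_items <- items_from_target(baop_target, baop_scale(),
                                  config$item_jitter)

  choices <- t(choose_from_gap(
    utility_gap_matrix(default_lottery_design(), sigma, lambda, gamma),
    config$choice_noise))

  subjects <- tibble::tibble(
    id = seq_len(n),
    weight_kg = weight, height_m = height, age = round(age, 1),
    female = female, married = married, university = university,
    income_low = income_low, diet = diet,
    stunkard_current = current, stunkard_preferred = preferred
  )
  subjects <- dplyr::bind_cols(subjects, atop_items, baop_items,
                               tibble::as_tibble(choices))

  truth <- list(
    edges = edges,
    config = config[setdiff(names(config), "edges")],
    subjects = tibble::tibble(
      id = seq_len(n), sigma = sigma, lambda = lambda, gamma = gamma,
      atop_latent = atop_latent, baop_latent = baop_latent, bmi_z = bmi_z
    )
  )
  structure(list(subjects = subjects, truth = truth),
            class = "obesipath_cohort")
}

# Quantize a target total score into admissible per-item Likert responses
# (pre-reversal), so that scoring the items approximately recovers the
# target. `targets` are on the offset score scale of `definition`.
items_from_target <- function(targets, definition, jitter = 1.5) {
  n <- length(targets)
  k <- definition$n_items
  adm <- definition$admissible_responses
  per_item <- (targets - definition$offset) / k
  vals <- matrix(round(rep(per_item, each = k) +
                         runif(n * k, -jitter, jitter)), k, n)
  vals <- pmin(pmax(vals, min(adm)), max(adm))
  if (!0L %in% adm) {
    zero <- vals == 0
    vals[zero] <- sample(c(-1L, 1L), sum(zero), replace = TRUE)
  }
  signs <- rep(1L, k)
  signs[definition$reversed_items] <- -1L
  raw <- vals * signs                    # undo the scoring reversal
  out <- tibble::as_tibble(t(raw), .name_repair = "minimal")
  names(out) <- paste0(tolower(definition$name), "_", seq_len(k))
  out
}

#' Export a cohort fixture to disk
#'
#' Writes `subjects.csv`, `truth.json` and `design.yaml` under `dir`; the
#' files round-trip through [readr::read_csv()], [jsonlite::fromJSON()]
#' and [read_lottery_design()].
#'
#' @param cohort An `obesipath_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param design The lottery design used for the choices.
#' @return Named character vector of the paths written, invisibly.
#' @export
export_fixture <- function(cohort, dir,
                           design = default_lottery_design()) {
  stopifnot(inherits(cohort, "obesipath_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             truth = file.path(dir, "truth.json"),
             design = file.path(dir, "design.yaml"))
  readr::write_csv(cohort$subjects, paths[["subjects"]])
  truth <- cohort$truth
  truth$config <- truth$config[vapply(truth$config, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  write_lottery_design(design, paths[["design"]])
  invisible(paths)
}
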