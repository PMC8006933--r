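test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_subjects = 40, seed = 21)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_fixture(c1, d1); export_fixture(c2, d2)
  expect_identical(readLines(file.path(d1, "subjects.csv")),
                   readLines(file.path(d2, "subjects.csv")))
  c3 <- generate_cohort(cohort_config(n_subjects = 40, seed = 22))
  expect_false(identical(c1$subjects$weight_kg, c3$subjects$weight_kg))
})

test_that("zero misperception noise yields correct weight perception for all", {
  co <- generate_cohort(cohort_config(n_subjects = 60, seed = 31,
                                      misperception_noise = 0))
  sc <- add_anthropometrics(co$subjects)
  expect_true(all(sc$perception_score == 0L))
})

test_that("generated scale scores stay within instrument bounds", {
  for (sd_seed in c(1, 2)) {
    co <- generate_cohort(cohort_config(n_subjects = 50, seed = sd_seed,
                                        item_jitter = 3))
    sc <- score_scales(co$subjects)
    expect_true(all(sc$atop_score >= 0 & sc$atop_score <= 120))
    expect_true(all(sc$baop_score >= 0 & sc$baop_score <= 48))
  }
})

test_that("fixtures round-trip through the pipeline readers", {
  co <- generate_cohort(cohort_config(n_subjects = 172, seed = 41))
  expect_equal(nrow(co$subjects), 172)
  dir <- withr::local_tempdir()
  paths <- export_fixture(co, dir)
  back <- readr::read_csv(paths[["subjects"]], show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(co$subjects))
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_named(truth, c("edges", "config", "subjects"))
  expect_equal(truth$subjects$sigma, co$truth$subjects$sigma,
               tolerance = 1e-12)
  expect_equal(tibble::as_tibble(truth$edges), co$truth$edges)
  d <- read_lottery_design(paths[["design"]])
  expect_equal(as.data.frame(d), as.data.frame(default_lottery_design()))
})

test_that("null structural effects give centred path estimates", {
  edges0 <- default_truth_edges()
  edges0$coef <- 0
  co <- generate_cohort(cohort_config(n_subjects = 800, seed = 51,
                                      edges = edges0,
                                      misperception_noise = 0))
  dat <- tibble::tibble(age = co$subjects$age,
                        female = co$subjects$female,
                        bmi = compute_bmi(co$subjects$weight_kg,
                                          co$subjects$height_m))
  m <- path_model(tibble::tibble(source = c("age", "female"), target = "bmi",
                                 mode = c("linear", "linear")))
  fit <- fit_path_model(dat, m)
  expect_lt(max(abs(fit$edges$beta)), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(share_female = 1.2),
               class = "obesipath_config_error")
  expect_error(cohort_config(n_subjects = 5),
               class = "obesipath_config_error")
  expect_error(cohort_config(choice_noise = -0.1),
               class = "obesipath_config_error")
  expect_error(generate_cohort(cohort_config(
    edges = tibble::tibble(source = "age", target = "bmi", coef = 1,
                           form = "spline"))),
               class = "obesipath_config_error")
})

test_that("cohort marginals track the configured mixtures", {
  co <- generate_cohort(cohort_config(n_subjects = 2000, seed = 61))
  s <- co$subjects
  expect_equal(mean(s$female), 0.70, tolerance = 0.05)
  expect_equal(mean(s$married), 0.69, tolerance = 0.05)
  expect_equal(mean(s$diet), 0.24, tolerance = 0.03)
  expect_equal(mean(s$age), 45.8, tolerance = 1.5)
  bmi <- compute_bmi(s$weight_kg, s$height_m)
  expect_equal(mean(bmi), 25.17, tolerance = 0.8)
  expect_equal(mean(co$truth$subjects$sigma), 0.58, tolerance = 0.1)
})
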