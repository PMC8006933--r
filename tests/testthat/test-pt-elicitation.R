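test_that("prospect values reduce to expected value and match closed forms", {
  expect_equal(prospect_value(10, 0, 0.5), 5.0)
  expect_equal(prospect_value(10, 0, 0.5, sigma = 0.5), sqrt(10) / 2,
               tolerance = 1e-12)
  expect_equal(prospect_value(-4, 0, 1, sigma = 1, lambda = 2.25), -9.0)
  # sigma = lambda = gamma = 1 is expected value on arbitrary prospects
  set.seed(2)
  for (r in 1:20) {
    x <- runif(1, -50, 50); y <- runif(1, -50, 50); p <- runif(1)
    expect_equal(prospect_value(x, y, p), p * x + (1 - p) * y,
                 tolerance = 1e-10)
  }
  expect_error(prospect_value(1, 0, 1.2), class = "obesipath_invalid_probability")
  expect_error(prospect_value(1, 0, 0.5, sigma = -1),
               class = "obesipath_invalid_parameter")
})

test_that("prospect value is increasing in x and decreasing in lambda for losses", {
  xs <- seq(-20, 20, by = 0.5)
  v <- prospect_value(xs, 0, 0.6, sigma = 0.7, lambda = 2, gamma = 0.8)
  expect_true(all(diff(v) > 0))
  lams <- seq(0.5, 5, by = 0.25)
  vl <- vapply(lams, function(l)
    prospect_value(-10, 2, 0.5, sigma = 0.7, lambda = l), numeric(1))
  expect_true(all(diff(vl) < 0))
})

test_that("series-3 preference ordering is invariant to gamma", {
  d3 <- default_lottery_design()
  d3 <- d3[d3$series == 3L, ]
  for (sig in c(0.4, 0.8, 1.2)) for (lam in c(0.5, 2, 5)) {
    prefs <- vapply(c(0.3, 0.6, 1), function(gam) {
      ua <- prospect_value(d3$x_a, d3$y_a, d3$p_a, sigma = sig,
                           lambda = lam, gamma = gam)
      ub <- prospect_value(d3$x_b, d3$y_b, d3$p_b, sigma = sig,
                           lambda = lam, gamma = gam)
      paste((ub > ua) * 1L, collapse = "")
    }, character(1))
    expect_length(unique(prefs), 1)
  }
})

test_that("simulated choices match brute-force row evaluation and are monotone", {
  d <- default_lottery_design()
  ch <- simulate_choices(d, pt_params(0.6, 3, 0.7), noise = 0)
  expect_equal(unname(ch), brute_force_choices(d, 0.6, 3, 0.7))
  # monotone single switch for a grid of interior parameter triples
  for (sig in seq(0.3, 1.3, by = 0.2)) for (gam in c(0.4, 0.7, 1)) {
    ch <- simulate_choices(d, pt_params(sig, 2, gam), noise = 0)
    expect_silent(infer_switchpoints(ch, d))
  }
  # identical plans are resolved to Plan A
  tie <- tibble::tibble(series = 1L, row = 1:2, x_a = c(40, 40),
                        y_a = 10, p_a = 0.3, x_b = c(40, 80), y_b = 10,
                        p_b = 0.3)
  ch <- simulate_choices(tie, pt_params(1, 1, 1), noise = 0)
  expect_equal(unname(ch), c(0L, 1L))
})

test_that("switch points are located and multiple switches rejected", {
  d <- default_lottery_design()
  expect_equal(unname(infer_switchpoints(rep(0L, 35), d)), c(15L, 15L, 8L))
  v <- c(rep(0L, 5), rep(1L, 9), rep(0L, 14), rep(0L, 7))
  expect_equal(unname(infer_switchpoints(v, d)), c(6L, 15L, 8L))
  v2 <- rep(0L, 35); v2[15:16] <- c(1L, 0L); v2[17] <- 1L
  expect_error(infer_switchpoints(c(v2[1:14], 1L, 0L, 1L, rep(1L, 11),
                                    rep(0L, 7)), d),
               class = "obesipath_multiple_switch")
  expect_error(infer_switchpoints(rep(0L, 10), d),
               class = "obesipath_shape_error")
})

test_that("noiseless round trip recovers parameters within reported intervals", {
  d <- default_lottery_design()
  for (sig in c(0.45, 0.75, 1.05)) for (gam in c(0.5, 0.8)) {
    for (lam in c(0.8, 2.5)) {
      e <- estimate_pt(simulate_choices(d, pt_params(sig, lam, gam), 0), d)
      expect_lte(e$sigma_lo, sig); expect_gte(e$sigma_hi, sig)
      expect_lte(e$gamma_lo, gam); expect_gte(e$gamma_hi, gam)
      expect_lte(e$lambda_lo, lam); expect_gte(e$lambda_hi, lam)
    }
  }
})

test_that("grid-search oracle agrees with the interval inversion", {
  d <- default_lottery_design()
  for (tr in list(c(0.6, 0.7, 1.3), c(0.9, 0.55, 0.6))) {
    ch <- simulate_choices(d, pt_params(tr[1], tr[3], tr[2]), 0)
    orc <- pt_grid_oracle(unname(ch), d, step = 0.02)
    expect_equal(orc$consistency, 1)
    e <- estimate_pt(ch, d)
    # the consistency-maximizing grid point lies in the reported region
    expect_gte(orc$par[["sigma"]], e$sigma_lo - 0.02)
    expect_lte(orc$par[["sigma"]], e$sigma_hi + 0.02)
    expect_gte(orc$par[["lambda"]], e$lambda_lo - 0.02)
    expect_lte(orc$par[["lambda"]], e$lambda_hi + 0.02)
  }
})

test_that("expected-value choices classify as not loss averse with unit interval", {
  d <- default_lottery_design()
  e <- estimate_pt(simulate_choices(d, pt_params(1, 1, 1), 0), d)
  expect_lte(e$sigma_lo, 1); expect_gte(e$sigma_hi, 1)
  expect_lte(e$lambda_lo, 1); expect_gte(e$lambda_hi, 1)
  expect_equal(as.character(e$loss_category), "not_loss_averse")
})

test_that("a never-switch series 3 yields a one-sided lambda interval", {
  d <- default_lottery_design()
  ch <- simulate_choices(d, pt_params(0.7, 11, 0.7), 0)
  s <- infer_switchpoints(ch, d)
  expect_equal(s[["s3"]], 8L)
  e <- estimate_pt_params(s, d)
  d3 <- d[d$series == 3L, ]
  thr <- (d3$x_b^e$sigma - d3$x_a^e$sigma) /
    (abs(d3$y_b)^e$sigma - abs(d3$y_a)^e$sigma)
  expect_gt(e$lambda_lo, thr[6])   # above the second-largest cell boundary
  expect_equal(e$lambda_hi, 12)
})

test_that("parameter categorization thresholds sit exactly at one", {
  ct <- categorize_pt(c(0.58, 1, 1.2), c(3.67, 0.99, 1))
  expect_equal(as.character(ct$risk_category),
               c("risk_averse", "risk_neutral", "risk_loving"))
  expect_equal(as.character(ct$loss_category),
               c("loss_averse", "not_loss_averse", "loss_averse"))
})

test_that("elicit_pt excludes non-monotone subjects with a warning", {
  d <- default_lottery_design()
  good <- simulate_choices(d, pt_params(0.7, 2, 0.8), 0)
  bad <- good; bad[2] <- 1L; bad[4] <- 0L; bad[3] <- 1L
  tab <- tibble::as_tibble(rbind(good, good, bad))
  names(tab) <- paste0("choice_", 1:35)
  expect_warning(out <- elicit_pt(tab, d), "1 subject")
  expect_equal(out$pt_valid, c(TRUE, TRUE, FALSE))
  expect_true(is.na(out$sigma[3]))
  expect_equal(out$sigma[1], out$sigma[2])
})

test_that("lottery designs round-trip through yaml and json", {
  d <- default_lottery_design()
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_lottery_design(d, f)
    d2 <- read_lottery_design(f)
    expect_equal(as.data.frame(d2), as.data.frame(d))
  }
  bad <- d; bad$p_b[1] <- 1.4
  expect_error(validate_lottery_design(bad),
               class = "obesipath_invalid_design")
})
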