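test_that("standardization hits closed forms, is idempotent, rejects constants", {
  out <- standardize(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(out$a, c(-1, 0, 1))
  again <- standardize(out)
  expect_equal(again$a, out$a, tolerance = 1e-12)
  expect_error(standardize(tibble::tibble(a = rep(2, 5))),
               regexp = "'a'", class = "obesipath_degenerate_variable")
})

test_that("warping is affine-invariant in linear mode and exact on cubic truth", {
  set.seed(3)
  x <- zx <- scale(rnorm(50))[, 1]
  y <- scale(2 * x + 1)[, 1]
  expect_equal(warp_edge(x, y, "linear"), zx, tolerance = 1e-12)
  # noiseless cubic: the s_curve warp reproduces y exactly (R^2 = 1)
  y3 <- x^3
  w <- warp_edge(x, y3, "s_curve")
  expect_equal(abs(cor(w, y3)), 1, tolerance = 1e-10)
  # sign-flipped truth keeps a negative downstream coefficient
  yneg <- -x + rnorm(50, 0, 0.1)
  wneg <- warp_edge(x, yneg, "s_curve")
  expect_lt(cor(wneg, yneg) * sign(cor(wneg, x)), 0)
  fitneg <- fit_path_model(tibble::tibble(x = x, y = yneg),
                           path_model(tibble::tibble(source = "x",
                                                     target = "y")))
  expect_lt(fitneg$edges$beta, 0)
  expect_error(warp_edge(x, y[-1]), class = "obesipath_shape_error")
})

test_that("linear-mode estimates equal textbook OLS via normal equations", {
  set.seed(4)
  for (r in 1:25) {
    n <- sample(30:120, 1)
    dat <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    dat$y <- 0.4 * dat$x1 - 0.2 * dat$x2 + rnorm(n)
    m <- path_model(tibble::tibble(source = c("x1", "x2", "x3"),
                                   target = "y", mode = "linear"))
    fit <- fit_path_model(dat, m)
    expect_equal(fit$edges$beta, unname(ols_oracle(dat, c("x1", "x2", "x3"), "y")),
                 tolerance = 1e-10)
  }
})

test_that("single-predictor equations give effect size beta squared", {
  set.seed(5)
  dat <- tibble::tibble(x = rnorm(80))
  dat$y <- 0.5 * dat$x + rnorm(80)
  fit <- fit_path_model(dat, path_model(tibble::tibble(source = "x",
                                                       target = "y",
                                                       mode = "linear")))
  expect_equal(fit$edges$effect_size, fit$edges$beta^2, tolerance = 1e-12)
})

test_that("s_curve fits converge to the linear truth in large samples", {
  set.seed(6)
  n <- 2e4
  dat <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  dat$y <- 0.5 * dat$x1 - 0.3 * dat$x2 +
    rnorm(n, 0, sqrt(1 - 0.25 - 0.09))
  m <- path_model(tibble::tibble(source = c("x1", "x2"), target = "y",
                                 mode = "s_curve"))
  fit <- fit_path_model(dat, m)
  expect_equal(fit$edges$beta, c(0.5, -0.3), tolerance = 0.02)
})

test_that("VIFs match the precision-matrix diagonal and flag duplication", {
  set.seed(7)
  X <- tibble::tibble(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  X$c <- 0.6 * X$a + 0.4 * X$b + rnorm(200, 0, 0.5)
  expect_equal(unname(vif(X)), unname(vif_oracle(X)), tolerance = 1e-10)
  expect_equal(unname(vif(X[c("a", "b")])), unname(vif_oracle(X[c("a", "b")])),
               tolerance = 1e-10)
  Xd <- X; Xd$d <- Xd$a + rnorm(200, 0, 0.001)
  expect_gt(max(vif(Xd)), 3.3)
  Xp <- X; Xp$dup <- Xp$a
  expect_error(vif(Xp), regexp = "dup|a", class = "obesipath_collinearity")
  expect_error(vif(tibble::tibble(a = rnorm(3), b = rnorm(3), c = rnorm(3))),
               class = "obesipath_shape_error")
})

test_that("fit indices obey their defining identities", {
  set.seed(8)
  n <- 150
  dat <- tibble::tibble(x1 = rnorm(n))
  dat$x2 <- 0.5 * dat$x1 + rnorm(n, 0, 0.87)
  dat$y <- 0.4 * dat$x1 + 0.3 * dat$x2 + rnorm(n, 0, 0.8)
  dat$z <- 0.5 * dat$y + rnorm(n, 0, 0.8)
  m <- path_model(tibble::tibble(source = c("x1", "x2", "y"),
                                 target = c("y", "y", "z"),
                                 mode = "linear"))
  fit <- fit_path_model(dat, m)
  ix <- setNames(fit$indices$value, fit$indices$index)
  expect_equal(ix[["apc"]], mean(abs(fit$edges$beta)))
  expect_equal(ix[["ars"]], mean(fit$equations$r2))
  expect_equal(ix[["aars"]], mean(fit$equations$adj_r2))
  expect_identical(ix[["gof"]], sqrt(ix[["ars"]]))
  expect_true(all(ix[c("spr", "rscr", "ssr", "nlbcdr")] >= 0 &
                    ix[c("spr", "rscr", "ssr", "nlbcdr")] <= 1))
  # sign-consistent, non-suppressed edges give spr = ssr = 1
  expect_equal(ix[["spr"]], 1)
  expect_equal(ix[["ssr"]], 1)
  # two-edge average: apc is the arithmetic mean of |beta|
  m2 <- path_model(tibble::tibble(source = c("x1", "x2"), target = "y",
                                  mode = "linear"))
  f2 <- fit_path_model(dat, m2)
  expect_equal(f2$indices$value[f2$indices$index == "apc"],
               mean(abs(f2$edges$beta)))
})

test_that("indices are invariant to row order and variable relabeling", {
  set.seed(9)
  n <- 120
  dat <- tibble::tibble(a = rnorm(n))
  dat$b <- 0.5 * (dat$a^3 - 1.5 * dat$a) / sd(dat$a^3 - 1.5 * dat$a) +
    rnorm(n, 0, 0.8)
  m <- path_model(tibble::tibble(source = "a", target = "b"))
  f1 <- fit_path_model(dat, m)
  f2 <- fit_path_model(dat[sample(n), ], m)
  expect_equal(f1$indices$value, f2$indices$value, tolerance = 1e-10)
  dat2 <- setNames(dat, c("u", "v"))
  m2 <- path_model(tibble::tibble(source = "u", target = "v"))
  f3 <- fit_path_model(dat2, m2)
  expect_equal(f1$indices$value, f3$indices$value, tolerance = 1e-12)
})

test_that("bootstrap inference is seed-deterministic and degrades p with se", {
  set.seed(10)
  dat <- tibble::tibble(x = rnorm(60))
  dat$y <- 0.6 * dat$x + rnorm(60, 0, 0.7)
  m <- path_model(tibble::tibble(source = "x", target = "y", mode = "linear"))
  f1 <- fit_path_model(dat, m, B = 200, seed = 99)
  f2 <- fit_path_model(dat, m, B = 200, seed = 99)
  expect_identical(f1$edges$p, f2$edges$p)
  f3 <- fit_path_model(dat, m, B = 200, seed = 100)
  expect_false(identical(f1$edges$p, f3$edges$p))
  expect_error(fit_path_model(dat, m, B = 50),
               class = "obesipath_config_error")
  # p -> 0 as se -> 0 under the declared t mapping
  expect_lt(2 * pt(-abs(0.4 / 1e-6), df = 199), 1e-12)
})

test_that("missing model variables raise a specification error", {
  dat <- tibble::tibble(x = rnorm(20), y = rnorm(20))
  m <- path_model(tibble::tibble(source = "x", target = "nope"))
  expect_error(fit_path_model(dat, m), regexp = "nope",
               class = "obesipath_model_error")
})

test_that("fitted curves classify into the expected shape families", {
  set.seed(11)
  n <- 400
  x <- rnorm(n)
  fit_shape <- function(y, mode) {
    d <- tibble::tibble(x = x, y = y)
    f <- fit_path_model(d, path_model(tibble::tibble(source = "x",
                                                     target = "y",
                                                     mode = mode)))
    attr(relationship_curve(f, "x", "y"), "shape")
  }
  expect_equal(fit_shape(0.6 * x + rnorm(n, 0, 0.5), "s_curve"), "linear")
  expect_equal(fit_shape((x^3 - 1.5 * x) + rnorm(n, 0, 0.3), "s_curve"), "S")
  expect_equal(fit_shape(-(x^3 - 1.5 * x) + rnorm(n, 0, 0.3), "s_curve"),
               "inverted-S")
  expect_equal(fit_shape(x^2 + rnorm(n, 0, 0.3), "quadratic"), "U")
  expect_equal(fit_shape(-(x^2) + rnorm(n, 0, 0.3), "quadratic"),
               "inverted-U")
  expect_true(fit_shape(exp(x) + rnorm(n, 0, 0.2), "s_curve") %in%
                c("exponential-like", "J"))
  # derivative-sign contract: negative-leading cubic with two interior
  # stationary points is inverted-S
  g <- seq(-2, 2, length.out = 201)
  expect_equal(classify_curve_shape(g, -(g^3) + 1.5 * g, c(0, 1.5, 0, -1)),
               "inverted-S")
  expect_equal(classify_curve_shape(g, g^3 - 1.5 * g, c(0, -1.5, 0, 1)), "S")
  expect_equal(classify_curve_shape(g, 0.3 * g, c(0, 0.3)), "linear")
  expect_equal(classify_curve_shape(g, -(g^2), c(0, 0, -1)), "inverted-U")
  expect_error(relationship_curve(
    fit_path_model(tibble::tibble(x = x, y = x + rnorm(n)),
                   path_model(tibble::tibble(source = "x", target = "y"))),
    "x", "nope"), class = "obesipath_state_error")
})

test_that("binary predictors are forced to a linear warp", {
  set.seed(12)
  d <- tibble::tibble(g = rep(0:1, 50))
  d$y <- 0.4 * d$g + rnorm(100, 0, 0.9)
  m <- path_model(tibble::tibble(source = "g", target = "y", mode = "s_curve"))
  expect_message(fit <- fit_path_model(d, m), "linear")
  expect_equal(fit$edges$mode, "linear")
})
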