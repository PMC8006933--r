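# Warped path estimation: per-edge polynomial transforms of standardized
# predictors followed by per-equation least squares, with bootstrap
# inference.

#' Standardize numeric columns
#'
#' Centres each column to mean 0 and scales to standard deviation 1
#' (denominator `n - 1`). Zero-variance columns raise an error naming the
#' column.
#'
#' @param data A data frame.
#' @param cols Columns to standardize (default: all numeric columns).
#' @return A tibble with the selected columns standardized.
#' @export
standardize <- function(data, cols = NULL) {
  out <- tibble::as_tibble(data)
  if (is.null(cols)) {
    cols <- names(out)[vapply(out, is.numeric, logical(1))]
  } else {
    require_columns(out, cols)
  }
  if (nrow(out) < 3) {
    abort("Standardization needs at least 3 rows.",
          class = "obesipath_shape_error")
  }
  for (cl in cols) {
    s <- sd(out[[cl]])
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Column '%s' has zero variance.", cl),
            class = "obesipath_degenerate_variable")
    }
    out[[cl]] <- (out[[cl]] - mean(out[[cl]])) / s
  }
  out
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

warp_degree <- function(mode) {
  switch(mode, linear = 1L, quadratic = 2L, s_curve = 3L,
         abort(sprintf("Unknown warp mode '%s'.", mode),
               class = "obesipath_model_error"))
}

# Core warp: least-squares polynomial fit of y on x, x replaced by the
# fitted values, restandardized and sign-aligned with x so that monotone
# decreasing relationships keep a negative downstream path coefficient.
# Returns list(w, coefs); NULL w on degenerate input handled by caller.
warp_xy <- function(x, y, degree) {
  if (degree == 1L) {
    w <- zscore(x)
    if (is.null(w)) return(NULL)
    vx <- var(x)
    b1 <- if (vx > 0) cov(x, y) / vx else 0
    b0 <- mean(y) - b1 * mean(x)
    return(list(w = w, coefs = c(b0, b1)))
  }
  V <- stats::poly(x, degree = degree, raw = TRUE, simple = TRUE)
  V <- cbind(1, V)
  fit <- tryCatch(qr.coef(qr(V), y), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) return(NULL)
  fitted <- drop(V %*% fit)
  w <- zscore(fitted)
  if (is.null(w)) return(NULL)
  ali <- cor(w, x)
  if (is.finite(ali) && ali < 0) w <- -w
  list(w = w, coefs = fit)
}

#' Warp a predictor against a criterion
#'
#' Fits a polynomial of the given mode (`linear` = degree 1, `quadratic` =
#' 2, `s_curve` = 3) of `y` on `x` by least squares, replaces `x` by the
#' fitted function evaluated at `x`, restandardizes, and orients the result
#' to correlate positively with the original `x` (so the sign of a
#' downstream path coefficient reflects the direction of the relationship).
#' Degenerate fits fall back to the linear mode with a warning.
#'
#' @param x,y Equal-length numeric vectors (standardized predictors and
#'   criterion).
#' @param mode One of `"linear"`, `"quadratic"`, `"s_curve"`.
#' @return The transformed, restandardized predictor.
#' @export
warp_edge <- function(x, y, mode = "s_curve") {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
          class = "obesipath_shape_error")
  }
  degree <- warp_degree(mode)
  if (length(x) <= degree + 1) {
    abort("Need more observations than polynomial degree + 1.",
          class = "obesipath_shape_error")
  }
  res <- warp_xy(x, y, degree)
  if (is.null(res)) {
    warn(sprintf("Degenerate %s warp; falling back to linear.", mode))
    res <- warp_xy(x, y, 1L)
    if (is.null(res)) {
      abort("Predictor has zero variance.",
            class = "obesipath_degenerate_variable")
    }
  }
  res$w
}

# Resolve per-edge warp modes: variables with <= 2 distinct values cannot
# support a polynomial warp and are forced to linear.
resolve_modes <- function(data, model, quiet = FALSE) {
  binary <- vapply(model$source, function(v)
    length(unique(data[[v]])) <= 2, logical(1))
  forced <- binary & model$mode != "linear"
  if (any(forced) && !quiet) {
    rlang::inform(sprintf(
      "Forcing linear warp for binary predictor(s): %s.",
      paste(unique(model$source[forced]), collapse = ", ")))
  }
  unname(ifelse(binary, "linear", model$mode))
}

# Equation structure computed once per model + data set.
build_structure <- function(data, model, quiet = FALSE) {
  vars <- model_variables(model)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(paste0("Model variable(s) absent from data: ",
                 paste(missing, collapse = ", ")),
          class = "obesipath_model_error")
  }
  modes <- resolve_modes(data, model, quiet = quiet)
  eqs <- lapply(model_targets(model), function(tg) {
    sel <- which(model$target == tg)
    list(target = tg, edges = sel, sources = model$source[sel],
         modes = modes[sel])
  })
  list(vars = vars, modes = modes, equations = eqs)
}

# Point fit on a standardized data matrix. Returns per-edge betas and
# correlations plus per-equation R-squared, or signals collinearity.
fit_core <- function(Z, model, struct, kappa_max = 1e8) {
  n <- nrow(Z)
  n_edges <- nrow(model)
  beta <- corr <- numeric(n_edges)
  r2 <- adj_r2 <- numeric(length(struct$equations))
  warped <- vector("list", n_edges)
  for (q in seq_along(struct$equations)) {
    eq <- struct$equations[[q]]
    y <- Z[, eq$target]
    k <- length(eq$sources)
    W <- matrix(0, n, k)
    for (j in seq_len(k)) {
      res <- warp_xy(Z[, eq$sources[j]], y, warp_degree(eq$modes[j]))
      if (is.null(res)) res <- warp_xy(Z[, eq$sources[j]], y, 1L)
      if (is.null(res)) {
        abort(sprintf("Degenerate predictor '%s'.", eq$sources[j]),
              class = "obesipath_degenerate_variable")
      }
      W[, j] <- res$w
      warped[[eq$edges[j]]] <- res
    }
    X <- cbind(1, W)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      abort(sprintf("Warped predictor block for '%s' is collinear.",
                    eq$target),
            class = "obesipath_collinearity")
    }
    d <- abs(diag(qr.R(qx)))
    if (max(d) / min(d) > kappa_max) {
      abort(sprintf("Warped predictor block for '%s' is near-collinear.",
                    eq$target),
            class = "obesipath_collinearity")
    }
    b <- qr.coef(qx, y)
    fitted <- drop(X %*% b)
    rss <- sum((y - fitted)^2)
    tss <- sum((y - mean(y))^2)
    r2[q] <- 1 - rss / tss
    adj_r2[q] <- 1 - (1 - r2[q]) * (n - 1) / (n - k - 1)
    beta[eq$edges] <- b[-1]
    corr[eq$edges] <- vapply(seq_len(k), function(j) cor(W[, j], y),
                             numeric(1))
  }
  list(beta = beta, corr = corr, r2 = r2, adj_r2 = adj_r2, warped = warped)
}

#' Fit a warped path model
#'
#' Standardizes all model variables, warps each edge's predictor against
#' its criterion per the edge's mode, and estimates every endogenous
#' equation by ordinary least squares on the warped, restandardized
#' predictors. With `B >= 100`, rows are resampled with replacement `B`
#' times, the model refit on each resample, and per-edge standard errors
#' and two-tailed p-values computed from a t statistic with `B - 1`
#' degrees of freedom; the bootstrap also supplies p-values for the APC /
#' ARS / AARS fit indices.
#'
#' @param data A data frame containing every model variable.
#' @param model A [path_model()]; defaults to [default_path_model()].
#' @param B Number of bootstrap resamples (0 = point estimates only;
#'   otherwise at least 100; 5000 gives the conventional t with 4999 df).
#' @param seed Optional integer seed for the bootstrap.
#' @return A `path_fit` object: tibbles of per-edge estimates
#'   (`$edges`), per-equation summaries (`$equations`) and the ten fit /
#'   quality indices (`$indices`), plus the standardized data and resolved
#'   model. Supports [tidy()], [glance()], [autoplot()],
#'   [relationship_curve()] and [edge_table()].
#' @export
fit_path_model <- function(data, model = default_path_model(), B = 0,
                           seed = NULL) {
  stopifnot(inherits(model, "path_model"))
  if (B != 0 && B < 100) {
    abort("`B` must be 0 or at least 100.", class = "obesipath_config_error")
  }
  data <- tibble::as_tibble(data)
  struct <- build_structure(data, model, quiet = FALSE)
  n <- nrow(data)
  max_k <- max(vapply(struct$equations, function(e) length(e$sources),
                      integer(1)))
  if (n <= max_k + 1) {
    abort("Need more rows than the largest equation's in-degree + 1.",
          class = "obesipath_shape_error")
  }
  Zt <- standardize(data[struct$vars])
  Z <- as.matrix(Zt)
  core <- fit_core(Z, model, struct)

  edges <- tibble::as_tibble(model)
  edges$mode <- struct$modes
  edges$beta <- core$beta
  edges$bivariate_corr <- core$corr
  edges$effect_size <- abs(core$beta * core$corr)
  equations <- tibble::tibble(
    target = vapply(struct$equations, `[[`, character(1), "target"),
    n_predictors = vapply(struct$equations, function(e) length(e$sources),
                          integer(1)),
    r2 = core$r2, adj_r2 = core$adj_r2
  )

  fit <- structure(
    list(edges = edges, equations = equations, data = Zt, model = model,
         struct = struct, warped = core$warped, n = n, B = B, seed = seed),
    class = "path_fit")

  if (B >= 100) {
    boot <- bootstrap_inference(data, model, B = B, seed = seed,
                                .struct = struct)
    fit$edges$se <- boot$edges$se
    fit$edges$t <- boot$edges$t
    fit$edges$p <- boot$edges$p
    fit$boot_index_p <- boot$index_p
  }
  fit$indices <- fit_indices(fit)
  fit
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Warped path model: %d edges, %d equations, n = %d%s\n",
              nrow(x$edges), nrow(x$equations), x$n,
              if (x$B >= 100) sprintf(", bootstrap B = %d", x$B) else ""))
  print(tidy(x))
  invisible(x)
}

#' Bootstrap inference for a warped path model
#'
#' Resamples rows with replacement, refits the full warped model on each
#' resample, and reports per-edge standard errors (bootstrap SD) and
#' two-tailed p-values from `t = beta / se` with `B - 1` degrees of
#' freedom. Resamples in which any model variable degenerates to zero
#' variance are redrawn (at most 10 retries each). Results are reproducible
#' under `seed`.
#'
#' @inheritParams fit_path_model
#' @param .struct Internal: a prebuilt model structure.
#' @return A list with `$edges` (tibble: source, target, se, t, p),
#'   `$index_p` (bootstrap p-values for APC/ARS/AARS) and `$draws`
#'   (B x n_edges matrix of bootstrap betas).
#' @export
bootstrap_inference <- function(data, model = default_path_model(), B = 5000,
                                seed = NULL, .struct = NULL) {
  stopifnot(inherits(model, "path_model"))
  if (B < 100) {
    abort("`B` must be at least 100.", class = "obesipath_config_error")
  }
  data <- tibble::as_tibble(data)
  struct <- .struct %||% build_structure(data, model, quiet = TRUE)
  X <- as.matrix(data[struct$vars])
  n <- nrow(X)
  point <- fit_core(as.matrix(standardize(data[struct$vars])), model, struct)
  if (!is.null(seed)) set.seed(seed)

  n_edges <- nrow(model)
  draws <- matrix(NA_real_, B, n_edges)
  r2_draws <- matrix(NA_real_, B, length(struct$equations))
  adj_draws <- matrix(NA_real_, B, length(struct$equations))
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try_i in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      sds <- apply(Xb, 2, sd)
      if (any(!is.finite(sds) | sds == 0)) next
      Zb <- sweep(sweep(Xb, 2, colMeans(Xb)), 2, sds, "/")
      colnames(Zb) <- struct$vars
      res <- tryCatch(fit_core(Zb, model, struct),
                      obesipath_collinearity = function(e) NULL,
                      obesipath_degenerate_variable = function(e) NULL)
      if (!is.null(res)) { ok <- TRUE; break }
    }
    if (!ok) {
      abort("Bootstrap resampling failed 10 times in a row.",
            class = "obesipath_bootstrap_error")
    }
    draws[b, ] <- res$beta
    r2_draws[b, ] <- res$r2
    adj_draws[b, ] <- res$adj_r2
  }

  se <- apply(draws, 2, sd)
  tval <- point$beta / se
  p <- 2 * pt(-abs(tval), df = B - 1)
  index_p <- c(
    apc = boot_index_p(mean(abs(point$beta)), apply(abs(draws), 1, mean), B),
    ars = boot_index_p(mean(point$r2), rowMeans(r2_draws), B),
    aars = boot_index_p(mean(point$adj_r2), rowMeans(adj_draws), B)
  )
  list(edges = tibble::tibble(source = model$source, target = model$target,
                              se = se, t = tval, p = p),
       index_p = index_p, draws = draws)
}

boot_index_p <- function(value, draws, B) {
  s <- sd(draws)
  if (!is.finite(s) || s == 0) return(0)
  2 * pt(-abs(value / s), df = B - 1)
}
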