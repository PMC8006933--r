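# Switching-point inversion: from observed lottery choices to (sigma,
# lambda, gamma) with interval bounds.
#
# Series 1 and 2 jointly identify (sigma, gamma): at a given gamma, the
# utility gap u(B) - u(A) of any all-gain row crosses zero exactly once in
# sigma > 0 (the gap is a four-term exponential sum in sigma whose
# coefficients sum to zero per plan, so sigma = 0 is always a root and at
# most one positive root remains). The observed switch row therefore pins
# sigma between the roots of the adjacent rows, tracing two indifference
# curves sigma(gamma); their crossing is the point estimate and the region
# where the two per-series sigma-intervals intersect gives the bounds.
# Series 3 (50/50 mixed rows) then brackets lambda through the row-wise
# thresholds c_r(sigma) = (x_b^s - x_a^s) / (|y_b|^s - |y_a|^s): Plan A is
# preferred exactly when lambda >= c_r.

SIGMA_BOX <- c(0.05, 2)
GAMMA_BOX <- c(0.05, 1)
LAMBDA_BOX <- c(0, 12)

#' Infer per-series switching points from a choice vector
#'
#' The switch point of a series is the 1-based row of the first Plan-B
#' choice, or `n + 1` if the subject never switched. Vectors that are not
#' of the form A...A B...B within every series are flagged as
#' multiple-switch errors and should be excluded (not repaired).
#'
#' @param choices Integer vector of 0/1 choices over the design rows
#'   (0 = Plan A, 1 = Plan B).
#' @param design The lottery design the choices refer to.
#' @return A named integer vector `c(s1, s2, s3)`.
#' @export
infer_switchpoints <- function(choices, design = default_lottery_design()) {
  design <- validate_lottery_design(design)
  if (length(choices) != nrow(design)) {
    abort(sprintf("Expected %d choices, got %d.", nrow(design),
                  length(choices)),
          class = "obesipath_shape_error")
  }
  if (any(!choices %in% c(0L, 1L))) {
    abort("Choices must be coded 0 (Plan A) or 1 (Plan B).",
          class = "obesipath_invalid_response")
  }
  parts <- split(as.integer(choices), design$series)
  s <- vapply(seq_along(parts), function(k) {
    v <- parts[[k]]
    first_b <- match(1L, v)
    if (is.na(first_b)) return(length(v) + 1L)
    if (any(v[first_b:length(v)] == 0L)) {
      abort(sprintf("Series %s switches more than once.", names(parts)[k]),
            class = "obesipath_multiple_switch")
    }
    first_b
  }, integer(1))
  setNames(s, paste0("s", names(parts)))
}

# One positive root of the all-gain utility gap in sigma at fixed gamma,
# clipped to the sigma box. Returns the box edge when the gap does not
# change sign inside it.
sigma_root <- function(drow, gamma, box = SIGMA_BOX) {
  g <- function(s) {
    wa <- prelec_weight(drow$p_a, gamma)
    wb <- prelec_weight(drow$p_b, gamma)
    (wb * drow$x_b^s + (1 - wb) * drow$y_b^s) -
      (wa * drow$x_a^s + (1 - wa) * drow$y_a^s)
  }
  glo <- g(box[1]); ghi <- g(box[2])
  if (glo >= 0) return(box[1])
  if (ghi <= 0) return(box[2])
  stats::uniroot(g, box, tol = 1e-8)$root
}

# Sigma interval implied by one all-gain series at a fixed gamma. The root
# decreases with the row (Plan B strengthens down the menu), so switching
# at row s brackets sigma in [root(s), root(s - 1)], with censored menus
# clipped to the box.
series_sigma_interval <- function(series_rows, s, gamma, box = SIGMA_BOX) {
  n <- length(series_rows)
  lo <- if (s <= n) sigma_root(series_rows[[s]], gamma, box) else box[1]
  hi <- if (s >= 2) sigma_root(series_rows[[s - 1]], gamma, box) else box[2]
  c(lo, hi)
}

design_rows <- function(d) lapply(seq_len(nrow(d)), function(i)
  lapply(as.list(d[i, ]), as.numeric))

# Series-3 lambda threshold for each row at a given sigma: Plan A is
# preferred exactly when lambda >= c_r(sigma).
lambda_thresholds <- function(s3_design, sigma) {
  (s3_design$x_b^sigma - s3_design$x_a^sigma) /
    (abs(s3_design$y_b)^sigma - abs(s3_design$y_a)^sigma)
}

#' Estimate prospect-theory parameters from switching points
#'
#' Inverts the three observed switch rows to point estimates and interval
#' bounds for `(sigma, gamma, lambda)`. The `(sigma, gamma)` point solves
#' the pair of indifference equations at the series-1 and series-2 switch
#' rows (nested bisection); bounds come from the adjacent-row inequalities
#' scanned over the admissible `gamma` range, with censored (never-switch /
#' immediate-switch) menus yielding one-sided intervals clipped to
#' `sigma` in `[0.05, 2]` and `gamma` in `[0.05, 1]`. `lambda` is bracketed
#' by the series-3 row thresholds; its point estimate is the interval
#' midpoint at the `sigma` point (with the boundary-cell convention for
#' censored rows) and its bounds are taken over the whole `sigma` interval,
#' clipped to `[0, 12]`.
#'
#' @param switchpoints Named vector `c(s1, s2, s3)` from
#'   [infer_switchpoints()].
#' @param design The lottery design.
#' @param gamma_step Grid step for the feasibility scan over `gamma`.
#' @return A one-row tibble with `sigma`, `sigma_lo`, `sigma_hi`, `gamma`,
#'   `gamma_lo`, `gamma_hi`, `lambda`, `lambda_lo`, `lambda_hi`, the switch
#'   rows, and `risk_category` / `loss_category`.
#' @export
estimate_pt_params <- function(switchpoints, design = default_lottery_design(),
                               gamma_step = 0.01) {
  design <- validate_lottery_design(design)
  d1 <- design_rows(design[design$series == 1L, ])
  d2 <- design_rows(design[design$series == 2L, ])
  d3 <- design[design$series == 3L, ]
  s1 <- switchpoints[["s1"]]; s2 <- switchpoints[["s2"]]
  s3 <- switchpoints[["s3"]]

  gamma_grid <- seq(GAMMA_BOX[1], GAMMA_BOX[2], by = gamma_step)
  iv1 <- vapply(gamma_grid, function(g) series_sigma_interval(d1, s1, g),
                numeric(2))
  iv2 <- vapply(gamma_grid, function(g) series_sigma_interval(d2, s2, g),
                numeric(2))
  lo_env <- pmax(iv1[1, ], iv2[1, ])
  hi_env <- pmin(iv1[2, ], iv2[2, ])
  feasible <- lo_env <= hi_env
  if (!any(feasible)) {
    abort("No (sigma, gamma) region is consistent with the observed switch rows.",
          class = "obesipath_inconsistent_choices")
  }

  joint_interval <- function(g) {
    i1 <- series_sigma_interval(d1, s1, g)
    i2 <- series_sigma_interval(d2, s2, g)
    c(max(i1[1], i2[1]), min(i1[2], i2[2]))
  }
  feasible_at <- function(g) { iv <- joint_interval(g); iv[1] <= iv[2] }

  # Refine the gamma feasibility boundaries beyond grid resolution.
  idx <- which(feasible)
  g_lo <- gamma_grid[min(idx)]; g_hi <- gamma_grid[max(idx)]
  g_lo <- refine_boundary(feasible_at, g_lo, g_lo - gamma_step, GAMMA_BOX[1])
  g_hi <- refine_boundary(feasible_at, g_hi, g_hi + gamma_step, GAMMA_BOX[2])

  # Sigma bounds: extremes of the feasible envelope, polished locally so the
  # reported interval is conservative at grid resolution.
  sig_lo <- min(lo_env[feasible])
  sig_hi <- max(hi_env[feasible])
  sig_lo <- polish_extreme(function(g) joint_interval(g)[1],
                           gamma_grid[idx[which.min(lo_env[idx])]],
                           gamma_step, c(g_lo, g_hi), maximize = FALSE,
                           fallback = sig_lo)
  sig_hi <- polish_extreme(function(g) joint_interval(g)[2],
                           gamma_grid[idx[which.max(hi_env[idx])]],
                           gamma_step, c(g_lo, g_hi), maximize = TRUE,
                           fallback = sig_hi)

  # Point estimate: crossing of the two switch-row indifference curves.
  n1 <- length(d1); n2 <- length(d2)
  interior <- s1 >= 2 && s1 <= n1 && s2 >= 2 && s2 <= n2
  if (interior) {
    h <- function(g) sigma_root(d1[[s1]], g) - sigma_root(d2[[s2]], g)
    # The switch-row roots are the lower envelope values already computed
    # on the grid: reuse them for the crossing search.
    hg <- iv1[1, feasible] - iv2[1, feasible]
    sign_change <- which(hg[-1] * hg[-length(hg)] <= 0)
    if (length(sign_change)) {
      gg <- gamma_grid[feasible]
      k <- sign_change[1]
      gamma_hat <- if (hg[k] == 0) gg[k] else
        stats::uniroot(h, c(gg[k], gg[k + 1]), tol = 1e-8)$root
      sigma_hat <- (sigma_root(d1[[s1]], gamma_hat) +
                      sigma_root(d2[[s2]], gamma_hat)) / 2
    } else {
      k <- which.min(abs(hg))
      gamma_hat <- gamma_grid[feasible][k]
      sigma_hat <- (sigma_root(d1[[s1]], gamma_hat) +
                      sigma_root(d2[[s2]], gamma_hat)) / 2
    }
  } else {
    # Censored menu(s): midpoint of the clipped feasible box.
    gamma_hat <- (g_lo + g_hi) / 2
    sigma_hat <- (sig_lo + sig_hi) / 2
  }
  sigma_hat <- min(max(sigma_hat, sig_lo), sig_hi)
  gamma_hat <- min(max(gamma_hat, g_lo), g_hi)

  lam <- estimate_lambda(d3, s3, sigma_hat, c(sig_lo, sig_hi))

  out <- tibble::tibble(
    sigma = sigma_hat, sigma_lo = sig_lo, sigma_hi = sig_hi,
    gamma = gamma_hat, gamma_lo = g_lo, gamma_hi = g_hi,
    lambda = lam[["lambda"]], lambda_lo = lam[["lo"]], lambda_hi = lam[["hi"]],
    s1 = as.integer(s1), s2 = as.integer(s2), s3 = as.integer(s3)
  )
  dplyr::bind_cols(out, categorize_pt(out$sigma, out$lambda))
}

# Bisection from a known-feasible point toward a known-infeasible one.
refine_boundary <- function(feasible_at, good, bad, box_edge, iters = 12) {
  if (bad < min(box_edge, good) || bad > max(box_edge, good)) return(good)
  for (i in seq_len(iters)) {
    mid <- (good + bad) / 2
    if (feasible_at(mid)) good <- mid else bad <- mid
  }
  good
}

polish_extreme <- function(f, g0, step, range_g, maximize, fallback) {
  lo <- max(range_g[1], g0 - step); hi <- min(range_g[2], g0 + step)
  if (hi <= lo) return(fallback)
  opt <- try(stats::optimize(f, c(lo, hi), maximum = maximize, tol = 1e-7),
             silent = TRUE)
  if (inherits(opt, "try-error")) return(fallback)
  val <- if (maximize) opt$objective else opt$objective
  if (maximize) max(fallback, val) else min(fallback, val)
}

estimate_lambda <- function(d3, s3, sigma_hat, sigma_range) {
  n3 <- nrow(d3)
  thr_hat <- lambda_thresholds(d3, sigma_hat)
  # Bounds over the whole sigma interval so the bracket is conservative.
  sig_grid <- unique(c(seq(sigma_range[1], sigma_range[2], length.out = 25),
                       sigma_hat))
  thr_mat <- vapply(sig_grid, function(s) lambda_thresholds(d3, s),
                    numeric(n3))
  thr_mat <- matrix(thr_mat, nrow = n3)
  if (s3 >= 2 && s3 <= n3) {
    lo <- min(thr_mat[s3 - 1, ]); hi <- max(thr_mat[s3, ])
    lam <- (thr_hat[s3 - 1] + thr_hat[s3]) / 2
  } else if (s3 == 1) {
    # Immediate switch: lambda below the first threshold.
    lo <- LAMBDA_BOX[1]; hi <- max(thr_mat[1, ])
    width <- if (n3 >= 2) thr_hat[2] - thr_hat[1] else thr_hat[1]
    lam <- thr_hat[1] - width / 2
  } else {
    # Never switched: lambda above the last threshold.
    lo <- min(thr_mat[n3, ]); hi <- LAMBDA_BOX[2]
    width <- if (n3 >= 2) thr_hat[n3] - thr_hat[n3 - 1] else thr_hat[n3]
    lam <- thr_hat[n3] + width / 2
  }
  lo <- min(max(lo, LAMBDA_BOX[1]), LAMBDA_BOX[2])
  hi <- min(max(hi, LAMBDA_BOX[1]), LAMBDA_BOX[2])
  lam <- min(max(lam, lo), hi)
  c(lambda = lam, lo = lo, hi = hi)
}

#' Estimate prospect-theory parameters from a raw choice vector
#'
#' Convenience wrapper: [infer_switchpoints()] then [estimate_pt_params()].
#'
#' @inheritParams infer_switchpoints
#' @inheritParams estimate_pt_params
#' @export
estimate_pt <- function(choices, design = default_lottery_design(), ...) {
  estimate_pt_params(infer_switchpoints(choices, design), design, ...)
}

#' Elicit prospect-theory parameters for every subject in a cohort table
#'
#' Reads the binary choice columns `choice_1` ... `choice_n` (0 = Plan A,
#' 1 = Plan B), inverts each subject's switching points, and appends the
#' parameter estimates, interval bounds and risk/loss categories. Subjects
#' with non-monotone (multiple-switch) or mutually inconsistent choices are
#' not repaired: their estimates are `NA`, `pt_valid` is `FALSE`, and a
#' warning reports how many records were affected.
#'
#' @param data A data frame with the choice columns.
#' @param design The lottery design the choices refer to.
#' @return The input as a tibble with elicitation columns appended.
#' @export
elicit_pt <- function(data, design = default_lottery_design()) {
  design <- validate_lottery_design(design)
  cols <- paste0("choice_", seq_len(nrow(design)))
  require_columns(data, cols)
  out <- tibble::as_tibble(data)
  ch <- as.matrix(out[cols])
  res <- purrr::map(seq_len(nrow(ch)), function(i) {
    tryCatch(estimate_pt(ch[i, ], design),
             obesipath_multiple_switch = function(e) NULL,
             obesipath_inconsistent_choices = function(e) NULL)
  })
  bad <- vapply(res, is.null, logical(1))
  if (any(bad)) {
    warn(sprintf(
      "%d subject(s) had non-monotone or inconsistent lottery choices; estimates set to NA.",
      sum(bad)))
    na_row <- estimate_pt(rep(0L, nrow(design)), design)
    na_row[1, ] <- lapply(na_row, function(x) x[NA_integer_])
    res[bad] <- list(na_row)
  }
  est <- dplyr::bind_rows(res)
  est$pt_valid <- !bad
  dplyr::bind_cols(out, est)
}
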