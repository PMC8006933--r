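# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Textbook OLS on standardized columns via the normal equations.
ols_oracle <- function(data, predictors, response) {
  Z <- scale(as.matrix(data[c(predictors, response)]))
  X <- Z[, predictors, drop = FALSE]
  y <- Z[, response]
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# VIFs from the diagonal of the inverse correlation matrix.
vif_oracle <- function(block) {
  diag(solve(stats::cor(as.matrix(block))))
}

# Row-by-row brute-force prospect evaluation (scalar loop, no shared code
# with utility_gap_matrix's vectorized path beyond prospect_value itself).
brute_force_choices <- function(design, sigma, lambda, gamma) {
  vapply(seq_len(nrow(design)), function(i) {
    ua <- brute_pt(design$x_a[i], design$y_a[i], design$p_a[i],
                   sigma, lambda, gamma)
    ub <- brute_pt(design$x_b[i], design$y_b[i], design$p_b[i],
                   sigma, lambda, gamma)
    as.integer(ub > ua)
  }, integer(1))
}

brute_pt <- function(x, y, p, sigma, lambda, gamma) {
  v <- function(z) if (z >= 0) z^sigma else -lambda * (-z)^sigma
  w <- function(q) if (q <= 0) 0 else if (q >= 1) 1 else exp(-(-log(q))^gamma)
  if (x * y < 0) w(p) * v(x) + w(1 - p) * v(y)
  else w(p) * v(x) + (1 - w(p)) * v(y)
}

# Grid search maximizing choice consistency over the parameter cube
# [0.05, 2]^3 at step `step`, exploiting that series 1/2 depend only on
# (sigma, gamma) and series 3 only on (sigma, lambda).
pt_grid_oracle <- function(choices, design, step = 0.01) {
  sig_grid <- seq(0.05, 2, by = step)
  gam_grid <- seq(0.05, 2, by = step)
  lam_grid <- seq(0.05, 2, by = step)
  gains <- design[design$series %in% c(1L, 2L), ]
  obs_g <- choices[design$series %in% c(1L, 2L)]
  s3 <- design[design$series == 3L, ]
  obs_3 <- choices[design$series == 3L]

  best <- -1; best_par <- NULL
  for (gam in gam_grid) {
    wa <- exp(-(-log(gains$p_a))^gam)
    wb <- exp(-(-log(gains$p_b))^gam)
    for (sig in sig_grid) {
      ua <- wa * gains$x_a^sig + (1 - wa) * gains$y_a^sig
      ub <- wb * gains$x_b^sig + (1 - wb) * gains$y_b^sig
      hit_g <- sum((ub > ua) == (obs_g == 1L))
      if (hit_g + length(obs_3) <= best) next
      thr <- (s3$x_b^sig - s3$x_a^sig) /
        (abs(s3$y_b)^sig - abs(s3$y_a)^sig)
      hit_3 <- max(vapply(lam_grid, function(l)
        sum((l < thr) == (obs_3 == 1L)), numeric(1)))
      if (hit_g + hit_3 > best) {
        lam_best <- lam_grid[which.max(vapply(lam_grid, function(l)
          sum((l < thr) == (obs_3 == 1L)), numeric(1)))]
        best <- hit_g + hit_3
        best_par <- c(sigma = sig, gamma = gam, lambda = lam_best)
      }
    }
  }
  list(par = best_par, consistency = best / length(choices))
}
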