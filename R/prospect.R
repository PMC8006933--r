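# Prospect-theory valuation and choice simulation.

#' Prospect-theory parameter triple
#'
#' Convenience constructor with validation: `sigma` is the power of the
#' value function (risk attitude; < 1 concave/risk averse), `lambda` the
#' loss-aversion multiplier applied to losses, and `gamma` the exponent of
#' the Prelec probability-weighting function `w(p) = exp(-(-log p)^gamma)`.
#'
#' @param sigma Value-function curvature, > 0.
#' @param lambda Loss-aversion multiplier, >= 0.
#' @param gamma Probability-weighting exponent, > 0 (1 = no weighting).
#' @return A list with class `pt_params`.
#' @export
pt_params <- function(sigma, lambda = 1, gamma = 1) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be positive.", class = "obesipath_invalid_parameter")
  }
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be non-negative.",
          class = "obesipath_invalid_parameter")
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    abort("`gamma` must be positive.", class = "obesipath_invalid_parameter")
  }
  structure(list(sigma = sigma, lambda = lambda, gamma = gamma),
            class = "pt_params")
}

#' Prelec probability weight
#'
#' `w(p) = exp(-(-log p)^gamma)`, with the limits `w(0) = 0`, `w(1) = 1`.
#'
#' @param p Probability in `[0, 1]`.
#' @param gamma Weighting exponent, > 0.
#' @return Decision weight(s) in `[0, 1]`.
#' @export
prelec_weight <- function(p, gamma = 1) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].", class = "obesipath_invalid_probability")
  }
  k <- max(length(p), length(gamma))
  p <- rep_len(p, k); gamma <- rep_len(gamma, k)
  w <- exp(-(-log(pmin(pmax(p, 0), 1)))^gamma)
  w[p <= 0] <- 0
  w[p >= 1] <- 1
  as.numeric(w)
}

pt_value_fn <- function(z, sigma, lambda) {
  k <- max(length(z), length(sigma), length(lambda))
  z <- rep_len(z, k); sigma <- rep_len(sigma, k); lambda <- rep_len(lambda, k)
  out <- numeric(k)
  pos <- z >= 0
  out[pos] <- z[pos]^sigma[pos]
  out[!pos] <- -lambda[!pos] * (-z[!pos])^sigma[!pos]
  out
}

#' Prospect value of a binary lottery
#'
#' Values the prospect "`x` with probability `p`, else `y`" under the
#' power/loss-aversion value function and Prelec weighting. For prospects
#' whose outcomes share a sign, the decision weight `w(p)` is applied to
#' the stated probability of `x` with `1 - w(p)` on `y`; for mixed
#' gain/loss prospects both outcomes are weighted separately
#' (`w(p) v(x) + w(1 - p) v(y)`), the convention under which 50/50 mixed
#' menus rank independently of `gamma`. With `sigma = lambda = gamma = 1`
#' the value reduces exactly to the expected value.
#'
#' @param x,y Outcomes (currency units; may be negative).
#' @param p Probability of `x`, in `[0, 1]`.
#' @param params A [pt_params()] triple (or `sigma`, `lambda`, `gamma`
#'   given directly).
#' @param sigma,lambda,gamma Parameter values used when `params` is `NULL`.
#' @return Numeric prospect value(s).
#' @examples
#' prospect_value(10, 0, 0.5)                      # expected value: 5
#' prospect_value(10, 0, 0.5, sigma = 0.5)         # sqrt(10) / 2
#' @export
prospect_value <- function(x, y, p, params = NULL,
                           sigma = 1, lambda = 1, gamma = 1) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "pt_params"))
    sigma <- params$sigma; lambda <- params$lambda; gamma <- params$gamma
  }
  pt_params(sigma, lambda, gamma)  # validation only
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].", class = "obesipath_invalid_probability")
  }
  k <- max(length(x), length(y), length(p), length(sigma), length(lambda),
           length(gamma))
  x <- rep_len(x, k); y <- rep_len(y, k); p <- rep_len(p, k)
  vx <- pt_value_fn(x, sigma, lambda)
  vy <- pt_value_fn(y, sigma, lambda)
  wx <- prelec_weight(p, gamma)
  mixed <- (x * y) < 0
  wy <- 1 - wx
  if (any(mixed)) {
    wy_m <- prelec_weight(1 - p, gamma)
    wy[mixed] <- wy_m[mixed]
  }
  as.numeric(wx * vx + wy * vy)
}

# Utility difference u(B) - u(A) for every design row, vectorized over
# subjects: returns an n_rows x n_subjects matrix.
utility_gap_matrix <- function(design, sigma, lambda, gamma) {
  n <- length(sigma)
  gap <- matrix(0, nrow(design), n)
  for (i in seq_len(nrow(design))) {
    ua <- prospect_value(design$x_a[i], design$y_a[i], design$p_a[i],
                         sigma = sigma, lambda = lambda, gamma = gamma)
    ub <- prospect_value(design$x_b[i], design$y_b[i], design$p_b[i],
                         sigma = sigma, lambda = lambda, gamma = gamma)
    gap[i, ] <- ub - ua
  }
  gap
}

#' Simulate lottery choices under prospect theory
#'
#' With `noise = 0`, each row is the deterministic argmax of prospect value,
#' with indifference resolved to Plan A (the safer plan); with `noise > 0`,
#' Plan B is chosen with logistic probability
#' `plogis((u_B - u_A) / noise)`.
#'
#' @param design A lottery design tibble.
#' @param params A [pt_params()] triple.
#' @param noise Logistic choice temperature, >= 0.
#' @param seed Optional integer seed (only used when `noise > 0`).
#' @return Integer vector of choices over the design rows, 0 = Plan A,
#'   1 = Plan B, named `choice_1` ... `choice_n`.
#' @export
simulate_choices <- function(design, params, noise = 0, seed = NULL) {
  stopifnot(inherits(params, "pt_params"))
  if (!is.finite(noise) || noise < 0) {
    abort("`noise` must be non-negative.", class = "obesipath_config_error")
  }
  design <- validate_lottery_design(design)
  if (!is.null(seed)) set.seed(seed)
  gap <- utility_gap_matrix(design, params$sigma, params$lambda, params$gamma)
  choose_from_gap(gap, noise)[, 1]
}

choose_from_gap <- function(gap, noise) {
  if (noise == 0) {
    ch <- (gap > 0) * 1L
  } else {
    pr <- stats::plogis(gap / noise)
    ch <- matrix(rbinom(length(pr), 1L, as.vector(pr)), nrow(gap), ncol(gap))
  }
  rownames(ch) <- paste0("choice_", seq_len(nrow(ch)))
  ch
}

#' Categorize prospect-theory parameters
#'
#' Risk attitude from `sigma` (averse < 1, neutral = 1, loving > 1) and
#' loss attitude from `lambda` (loss averse when `lambda >= 1`).
#'
#' @param sigma,lambda Parameter vectors.
#' @return A tibble with factor columns `risk_category` and `loss_category`.
#' @export
categorize_pt <- function(sigma, lambda) {
  risk <- dplyr::case_when(
    sigma < 1 ~ "risk_averse",
    sigma > 1 ~ "risk_loving",
    TRUE      ~ "risk_neutral"
  )
  loss <- ifelse(lambda >= 1, "loss_averse", "not_loss_averse")
  tibble::tibble(
    risk_category = factor(risk, levels = c("risk_averse", "risk_neutral",
                                            "risk_loving")),
    loss_category = factor(loss, levels = c("not_loss_averse", "loss_averse"))
  )
}
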