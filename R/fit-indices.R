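# Collinearity diagnostics and the ten model fit / quality indices.

#' Variance inflation factors for a predictor block
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` regresses column `j` on all other
#' columns of the block. A single-column block has VIF 1 by convention.
#'
#' @param block A data frame or matrix of predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(block) {
  M <- as.matrix(block)
  k <- ncol(M)
  if (is.null(colnames(M))) colnames(M) <- paste0("x", seq_len(k))
  if (nrow(M) <= k + 1) {
    abort("Need more rows than predictors + 1.",
          class = "obesipath_shape_error")
  }
  if (k == 1) return(setNames(1, colnames(M)))
  out <- vapply(seq_len(k), function(j) {
    y <- M[, j]
    X <- cbind(1, M[, -j, drop = FALSE])
    b <- qr.coef(qr(X), y)
    b[is.na(b)] <- 0
    res <- y - drop(X %*% b)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) {
      abort(sprintf("Column '%s' is perfectly collinear with the block.",
                    colnames(M)[j]),
            class = "obesipath_collinearity")
    }
    1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(M))
}

#' Full-collinearity VIFs over all model variables
#'
#' Regresses each model variable on every other model variable (whether it
#' appears as predictor or criterion), the standard screen for lateral and
#' full collinearity.
#'
#' @param data A data frame.
#' @param vars Variables to include (default: all numeric columns).
#' @return Named numeric vector of full-collinearity VIFs.
#' @export
full_collinearity_vif <- function(data, vars = NULL) {
  data <- tibble::as_tibble(data)
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  require_columns(data, vars)
  vif(data[vars])
}

index_interpretation <- c(
  apc = "Significant if p < 0.05",
  ars = "Significant if p < 0.05",
  aars = "Significant if p < 0.05",
  avif = "Acceptable if <= 5, ideally <= 3.3",
  afvif = "Acceptable if <= 5, ideally <= 3.3",
  gof = "Small >= 0.1, medium >= 0.25, large >= 0.36",
  spr = "Acceptable if >= 0.7, ideally = 1",
  rscr = "Acceptable if >= 0.9, ideally = 1",
  ssr = "Acceptable if >= 0.7",
  nlbcdr = "Acceptable if >= 0.7"
)

index_label <- c(
  apc = "Average path coefficient (APC)",
  ars = "Average R-squared (ARS)",
  aars = "Average adjusted R-squared (AARS)",
  avif = "Average block VIF (AVIF)",
  afvif = "Average full collinearity VIF (AFVIF)",
  gof = "Tenenhaus GoF (GoF)",
  spr = "Simpson's paradox ratio (SPR)",
  rscr = "R-squared contribution ratio (RSCR)",
  ssr = "Statistical suppression ratio (SSR)",
  nlbcdr = "Non-linear bivariate causality direction ratio (NLBCDR)"
)

#' Model fit and quality indices
#'
#' Computes the ten global indices of a fitted warped path model:
#'
#' * `apc` — mean absolute path coefficient (bootstrap p-value when
#'   available);
#' * `ars`, `aars` — mean (adjusted) R-squared over endogenous equations;
#' * `avif` — mean VIF over warped predictor blocks with at least two
#'   predictors (1 when no such block exists);
#' * `afvif` — mean full-collinearity VIF over all model variables;
#' * `gof` — `sqrt(mean communality x ARS)`; every variable is a single
#'   indicator with communality 1, so `gof = sqrt(ars)` exactly;
#' * `spr` — fraction of edges whose coefficient sign matches the sign of
#'   the warped bivariate correlation (freedom from Simpson's paradox);
#' * `rscr` — positive share of R-squared contributions
#'   `beta x corr` (sum of positive contributions over sum of absolute
#'   contributions);
#' * `ssr` — fraction of edges with `|beta| <= |corr|` (freedom from
#'   statistical suppression);
#' * `nlbcdr` — fraction of edges whose warped bivariate R-squared in the
#'   hypothesised direction weakly exceeds that of the reversed direction,
#'   with half credit on exact ties.
#'
#' @param fit A `path_fit` object.
#' @return A tibble with columns `index`, `label`, `value`, `p_value`
#'   (APC/ARS/AARS only) and `interpretation`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  if (nrow(fit$equations) == 0) {
    abort("Model has no endogenous variable.",
          class = "obesipath_model_error")
  }
  edges <- fit$edges
  Z <- as.matrix(fit$data)

  apc <- mean(abs(edges$beta))
  ars <- mean(fit$equations$r2)
  aars <- mean(fit$equations$adj_r2)

  block_vifs <- purrr::map(fit$struct$equations, function(eq) {
    if (length(eq$sources) < 2) return(NULL)
    W <- vapply(eq$edges, function(e) fit$warped[[e]]$w,
                numeric(nrow(Z)))
    colnames(W) <- eq$sources
    vif(W)
  })
  block_vifs <- unlist(block_vifs)
  avif <- if (length(block_vifs)) mean(block_vifs) else 1
  afvif <- mean(full_collinearity_vif(fit$data, fit$struct$vars))

  gof <- sqrt(ars)

  contribution <- edges$beta * edges$bivariate_corr
  spr <- mean(sign(edges$beta) == sign(edges$bivariate_corr))
  rscr <- if (sum(abs(contribution)) == 0) 1 else
    sum(contribution[contribution > 0]) / sum(abs(contribution))
  ssr <- mean(abs(edges$beta) <= abs(edges$bivariate_corr) + 1e-10)

  r2f <- edges$bivariate_corr^2
  r2r <- vapply(seq_len(nrow(edges)), function(i) {
    x <- Z[, edges$source[i]]
    y <- Z[, edges$target[i]]
    # A binary criterion cannot support a polynomial reverse warp.
    deg <- if (length(unique(y)) <= 2) 1L else warp_degree(edges$mode[i])
    res <- warp_xy(y, x, deg)
    if (is.null(res)) res <- warp_xy(y, x, 1L)
    if (is.null(res)) return(NA_real_)
    cor(res$w, x)^2
  }, numeric(1))
  cmp <- r2f - r2r
  nlbcdr <- mean(ifelse(abs(cmp) < 1e-8, 0.5, as.numeric(cmp > 0)))

  pvals <- fit$boot_index_p %||% c(apc = NA_real_, ars = NA_real_,
                                   aars = NA_real_)
  values <- c(apc = apc, ars = ars, aars = aars, avif = avif, afvif = afvif,
              gof = gof, spr = spr, rscr = rscr, ssr = ssr, nlbcdr = nlbcdr)
  tibble::tibble(
    index = names(values),
    label = unname(index_label[names(values)]),
    value = unname(values),
    p_value = unname(pvals[names(values)]),
    interpretation = unname(index_interpretation[names(values)])
  )
}
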