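# Principal component regression of per-area suspect prevalence on the 13
# fraud-vulnerability factor ranks, with leave-one-out cross-validation.
# Only four areas are observed, so at most 3 components are identifiable and
# coefficients are reported in the autoscaled predictor space.

.pcr_solve <- function(X, y, n_components, autoscale_x = TRUE,
                       center_y = TRUE) {
  cx <- colMeans(X)
  sx <- if (autoscale_x) apply(X, 2, stats::sd) else rep(1, ncol(X))
  keep <- sx > 1e-12
  Xs <- scale(X[, keep, drop = FALSE], center = cx[keep], scale = sx[keep])
  my <- if (center_y) mean(y) else 0
  yc <- y - my
  sv <- svd(Xs)
  rank <- sum(sv$d > max(sv$d, 1e-300) * 1e-10)
  a <- min(n_components, rank)
  if (a < 1) stop("predictor matrix has rank 0", call. = FALSE)
  V <- sv$v[, seq_len(a), drop = FALSE]
  Tm <- Xs %*% V
  b_comp <- solve(crossprod(Tm), crossprod(Tm, yc))
  beta_scaled <- rep(0, ncol(X))
  beta_scaled[keep] <- as.numeric(V %*% b_comp)
  names(beta_scaled) <- colnames(X)
  # coefficients on the original predictor scale, for prediction
  beta_raw <- beta_scaled
  beta_raw[keep] <- beta_scaled[keep] / sx[keep]
  intercept <- my - sum(beta_raw * cx)
  list(beta_scaled = beta_scaled, beta_raw = beta_raw, intercept = intercept,
       rank = rank, n_components = a)
}

.pcr_loo_press <- function(X, y, n_components, autoscale_x = TRUE,
                           center_y = TRUE) {
  n <- nrow(X)
  sum(vapply(seq_len(n), function(i) {
    fit <- .pcr_solve(X[-i, , drop = FALSE], y[-i], n_components,
                      autoscale_x, center_y)
    pred <- fit$intercept + sum(fit$beta_raw * X[i, ])
    (y[i] - pred)^2
  }, 0))
}

#' Fit a principal component regression
#'
#' Regresses the response on the leading principal components of the
#' autoscaled predictor matrix and back-expresses the regression vector per
#' predictor (in autoscaled space, matching how such coefficient vectors are
#' reported). The leave-one-out PRESS is computed by explicitly refitting on
#' each leave-one-out split, with the autoscaling refitted inside every fold;
#' within a fold the component count is capped at the fold's rank. When
#' `n_components` is `NULL` the count minimising the LOO PRESS over
#' `1..max_components` is chosen.
#'
#' @param X numeric matrix or data.frame, rows = observations (areas),
#'   columns = predictors (factor ranks).
#' @param y numeric response (prevalence percentages).
#' @param n_components fixed component count, or `NULL` for PRESS selection.
#' @param max_components upper limit of the candidate counts (default
#'   `min(n - 1, ncol(X))`).
#' @param autoscale_x autoscale predictors (default TRUE).
#' @param center_y centre the response (default TRUE; `y` is not scaled).
#' @return object of class `pcr_model`: `coefficients` (autoscaled space),
#'   `coefficients_raw`, `intercept`, `n_components`, `chosen_by`,
#'   `loo_press` (named vector over candidate counts), `fitted`, `residuals`.
#' @export
fit_pcr <- function(X, y, n_components = NULL, max_components = NULL,
                    autoscale_x = TRUE, center_y = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y dimensions differ", call. = FALSE)
  limit <- min(nrow(X) - 1L, ncol(X))
  if (is.null(max_components)) max_components <- limit
  max_components <- min(max_components, limit)
  if (!is.null(n_components) && n_components > limit) {
    stop("n_components exceeds min(n - 1, n_predictors)", call. = FALSE)
  }
  candidates <- if (is.null(n_components)) {
    seq_len(max_components)
  } else {
    n_components
  }
  press <- vapply(candidates, function(a) {
    .pcr_loo_press(X, y, a, autoscale_x, center_y)
  }, 0)
  names(press) <- candidates
  chosen <- if (is.null(n_components)) {
    candidates[which.min(press)]
  } else {
    n_components
  }
  fit <- .pcr_solve(X, y, chosen, autoscale_x, center_y)
  fitted <- fit$intercept + as.numeric(X %*% fit$beta_raw)
  structure(list(
    coefficients = fit$beta_scaled,
    coefficients_raw = fit$beta_raw,
    intercept = fit$intercept,
    n_components = fit$n_components,
    chosen_by = if (is.null(n_components)) "min_press" else "fixed",
    loo_press = press,
    fitted = fitted,
    residuals = y - fitted
  ), class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("PCR model: %d component(s) (%s), LOO PRESS %.4g\n",
              x$n_components, x$chosen_by,
              x$loo_press[as.character(x$n_components)]))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.pcr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  object$intercept + as.numeric(X %*% object$coefficients_raw)
}

#' Signs of the PCR regression vector
#'
#' Qualitative per-predictor direction of association at the fitted
#' component count (+1, -1 or 0).
#'
#' @param model a `pcr_model`.
#' @return named integer vector of signs.
#' @export
coefficient_signs <- function(model) {
  s <- sign(model$coefficients)
  storage.mode(s) <- "integer"
  s
}

#' Regress suspect prevalence on fraud-vulnerability factor ranks
#'
#' Convenience wrapper: builds the 4-areas-by-13-factors predictor matrix
#' from the rank fixture, takes the exact per-area prevalence percentages as
#' the response, and fits [fit_pcr].
#'
#' @param factors fraud-factor data.frame from [load_fraud_factors].
#' @param prevalence a `prevalence_summary` (or data.frame with `area` and
#'   `percentage`) covering areas E, N, NW, NE.
#' @param n_components passed to [fit_pcr] (default: PRESS selection).
#' @return a `pcr_model` whose coefficients are named by `factor_id`.
#' @export
regress_vulnerability <- function(factors = load_fraud_factors(),
                                  prevalence, n_components = NULL) {
  area_cols <- c(E = "east", N = "north", NW = "northwest", NE = "northeast")
  X <- t(as.matrix(factors[, area_cols]))
  rownames(X) <- names(area_cols)
  colnames(X) <- paste0("factor_", factors$factor_id)
  i <- match(names(area_cols), prevalence$area)
  if (anyNA(i)) stop("prevalence must cover areas E, N, NW, NE", call. = FALSE)
  y <- prevalence$percentage[i]
  fit_pcr(X, y, n_components = n_components)
}
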