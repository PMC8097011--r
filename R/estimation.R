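# exact least squares via QR on the model matrix; classical SEs.
# residuals for the error variance can be overridden (2SLS needs the
# structural residuals, not the second-stage ones).
ols_qr <- function(X, y, terms) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    abort("Design matrix is rank deficient (collinear predictors).",
          class = "collider_rank_error")
  }
  coef <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coef)
  list(qr = qr_x, coef = setNames(as.numeric(coef), terms), fitted = fitted)
}

ols_inference <- function(fit, X, y, resid) {
  n <- length(y)
  k <- ncol(X)
  s2 <- sum(resid^2) / (n - k)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(xtx_inv))
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / tss
  list(se = setNames(se, names(fit$coef)), r_squared = r2)
}

new_collider_fit <- function(model_form, coef, se, r_squared, n) {
  structure(
    list(model_form = model_form, coef = coef, se = se,
         r_squared = r_squared, n = n),
    class = "collider_fit"
  )
}

check_cohort <- function(data, needed, min_n = 3L) {
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "collider_domain_error")
  }
  if (nrow(data) < min_n) {
    abort(sprintf("At least %d observations are required.", min_n),
          class = "collider_domain_error")
  }
  invisible(data)
}

#' Fit the additive regression of the outcome on score and covariate
#'
#' Ordinary least squares of `y` on an intercept, the polygenic score `g`
#' and the environment `e` — the specification in which conditioning on a
#' heritable `e` makes it a collider. Solved exactly from the normal
#' equations via a QR decomposition, with classical homoskedastic
#' standard errors.
#'
#' @param data A data frame with columns `g`, `e`, `y` (typically a
#'   [generate_cohort()] tibble).
#' @return A `collider_fit` object; use [tidy()] for a per-term tibble and
#'   [glance()] for fit statistics.
#' @examples
#' cohort <- generate_cohort(collider_params(lambda_ge = 0.3,
#'   delta_ue = 0.25, kappa_uy = 0.25, n = 5000, seed = 1))
#' tidy(fit_additive(cohort))
#' @export
fit_additive <- function(data) {
  check_cohort(data, c("g", "e", "y"))
  X <- cbind(intercept = 1, g = data$g, e = data$e)
  fit <- ols_qr(X, data$y, c("intercept", "g", "e"))
  inf <- ols_inference(fit, X, data$y, data$y - fit$fitted)
  new_collider_fit("additive", fit$coef, inf$se, inf$r_squared, nrow(data))
}

#' Fit the gene-by-environment interaction regression
#'
#' OLS of `y` on an intercept, `g`, `e` and the product `g*e`. The
#' interaction coefficient is consistently estimated even when `e` is a
#' collider, provided the confounder does not itself moderate the
#' environment's effect; an `E*U` interaction in the generating model
#' biases it.
#'
#' @inheritParams fit_additive
#' @return A `collider_fit` with terms `intercept`, `g`, `e`, `gxe`.
#' @export
fit_interaction <- function(data) {
  check_cohort(data, c("g", "e", "y"), min_n = 4L)
  X <- cbind(intercept = 1, g = data$g, e = data$e, gxe = data$g * data$e)
  fit <- ols_qr(X, data$y, c("intercept", "g", "e", "gxe"))
  inf <- ols_inference(fit, X, data$y, data$y - fit$fitted)
  new_collider_fit("interaction", fit$coef, inf$se, inf$r_squared, nrow(data))
}

#' Two-stage least squares fit using an instrument for the environment
#'
#' Recovers the structural effects of `g` and `e` on `y` when `e` is
#' endogenous, using an instrument `z` that shifts `e` but has no direct
#' path to `y`. First stage: `e` on (intercept, `g`, `z`); second stage:
#' `y` on (intercept, `g`, fitted `e`). Standard errors use the
#' structural residuals `y - X b` evaluated at the observed `e`, the
#' conventional 2SLS variance.
#'
#' @param data A data frame with columns `g`, `e`, `y`, `z`.
#' @return A `collider_fit` with `model_form = "iv"` and terms
#'   `intercept`, `g`, `e`.
#' @examples
#' p <- collider_params(lambda_ge = 0.3, delta_ue = 0.25, kappa_uy = 0.25,
#'                      pi_ze = 0.5, n = 5000, seed = 1)
#' tidy(fit_iv(generate_cohort(p)))
#' @export
fit_iv <- function(data) {
  if (!"z" %in% names(data)) {
    abort("2SLS needs an instrument column `z`; the cohort has none.",
          class = "collider_weak_instrument_error")
  }
  check_cohort(data, c("g", "e", "y", "z"), min_n = 4L)
  X1 <- cbind(intercept = 1, g = data$g, z = data$z)
  # a constant (rank-deficient) instrument is an absent instrument
  first <- tryCatch(
    ols_qr(X1, data$e, c("intercept", "g", "z")),
    collider_rank_error = function(cnd) {
      abort("Instrument `z` carries no variation independent of the other regressors.",
            class = "collider_weak_instrument_error", parent = cnd)
    })
  if (abs(first$coef[["z"]]) < sqrt(.Machine$double.eps)) {
    abort("First-stage coefficient on `z` is numerically zero: the instrument is absent or irrelevant.",
          class = "collider_weak_instrument_error")
  }
  X2 <- cbind(intercept = 1, g = data$g, e = first$fitted)
  second <- ols_qr(X2, data$y, c("intercept", "g", "e"))
  # structural residuals: evaluate at the observed e, not its projection
  X_struct <- cbind(intercept = 1, g = data$g, e = data$e)
  resid <- data$y - drop(X_struct %*% second$coef)
  inf <- ols_inference(second, X2, data$y, resid)
  new_collider_fit("iv", second$coef, inf$se, inf$r_squared, nrow(data))
}

#' @export
print.collider_fit <- function(x, ...) {
  cat(sprintf("<collider_fit> %s model, n = %d, R2 = %.4f\n",
              x$model_form, x$n, x$r_squared))
  print(tidy(x))
  invisible(x)
}

#' @method tidy collider_fit
#' @export
tidy.collider_fit <- function(x, ...) {
  tibble(term = names(x$coef),
         estimate = unname(x$coef),
         std.error = unname(x$se[names(x$coef)]))
}

#' @method glance collider_fit
#' @export
glance.collider_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n, model_form = x$model_form)
}

#' Serialize a fit to long-format rows or JSON
#'
#' `fit_rows()` returns one row per term (`term`, `estimate`, `se`,
#' `model_form`, `replicate`), the long format the grid exporter writes.
#' `fit_json()` returns a JSON string of the whole fit.
#'
#' @param fit A `collider_fit`.
#' @param replicate Replicate index recorded in the rows.
#' @return A tibble (`fit_rows`) or a JSON string (`fit_json`).
#' @export
fit_rows <- function(fit, replicate = 1L) {
  tibble(term = names(fit$coef),
         estimate = unname(fit$coef),
         se = unname(fit$se[names(fit$coef)]),
         model_form = fit$model_form,
         replicate = as.integer(replicate))
}

#' @rdname fit_rows
#' @export
fit_json <- function(fit) {
  jsonlite::toJSON(
    list(model_form = fit$model_form, coef = as.list(fit$coef),
         se = as.list(fit$se), r_squared = fit$r_squared, n = fit$n),
    auto_unbox = TRUE, digits = NA)
}
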