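#' Structural parameters of the collider-bias generative model
#'
#' Defines the linear structural system linking a polygenic score `G`, an
#' unobserved confounder `U`, an optional instrument `Z`, a heritable
#' environment/covariate `E`, and an outcome `Y`:
#'
#' \deqn{E = \lambda G + \delta U + \pi Z + \varepsilon_E, \quad
#'       \mathrm{Var}(\varepsilon_E) = 1 - \lambda^2 - \delta^2 - \pi^2}
#' \deqn{Y = \beta G + \gamma E + \theta\, G E + \kappa U + \phi\, E U +
#'       \varepsilon_Y, \quad \varepsilon_Y \sim N(0, \sigma_Y^2)}
#'
#' `G`, `U` and `Z` are independent standard normals and `E` is scaled to
#' unit variance, so the structural coefficients `lambda_ge`, `delta_ue`
#' and `pi_ze` equal the correlations of `E` with `G`, `U` and `Z`
#' respectively. The gene-environment correlation (rGE) is therefore
#' `lambda_ge` exactly, and confounder strength `r` enters as `delta_ue`
#' on the environment side and `kappa_uy` on the outcome side.
#'
#' @param lambda_ge Structural coefficient of `G` on `E`; equals
#'   `cor(G, E)` (the rGE). In `[0, 0.95]`.
#' @param delta_ue Structural coefficient of `U` on `E`; equals
#'   `cor(U, E)`. In `[0, 0.95]`.
#' @param kappa_uy Structural coefficient of the confounder `U` on `Y`.
#' @param beta_gy Direct effect of `G` on `Y`. Default 0.6.
#' @param gamma_ey Direct effect of `E` on `Y`. Default 0.6.
#' @param theta_gxe Coefficient of the `G*E` product term in `Y`;
#'   0 in additive scenarios, 0.1 in the interaction scenarios.
#' @param phi_exu Coefficient of the `E*U` product term in `Y`; nonzero
#'   only in the confounder-moderation (E-by-U) scenario.
#' @param pi_ze Structural coefficient of the instrument `Z` on `E`;
#'   0 unless an instrumental-variable design is simulated.
#' @param sigma_y Standard deviation of the outcome noise. Default 1.
#' @param n Cohort size (at least 2). Default 10000.
#' @param seed Integer RNG seed; the same `(params, seed)` pair always
#'   yields a bit-identical cohort.
#'
#' @return A validated object of class `collider_params` (a named list).
#' @seealso [generate_cohort()], [population_fit()], [grid_spec()]
#' @examples
#' p <- collider_params(lambda_ge = 0.3, delta_ue = 0.25, kappa_uy = 0.25)
#' p
#' @export
collider_params <- function(lambda_ge = 0, delta_ue = 0, kappa_uy = 0,
                            beta_gy = 0.6, gamma_ey = 0.6,
                            theta_gxe = 0, phi_exu = 0, pi_ze = 0,
                            sigma_y = 1, n = 10000L, seed = 1L) {
  p <- structure(
    list(
      lambda_ge = as.numeric(lambda_ge), delta_ue = as.numeric(delta_ue),
      kappa_uy = as.numeric(kappa_uy), beta_gy = as.numeric(beta_gy),
      gamma_ey = as.numeric(gamma_ey), theta_gxe = as.numeric(theta_gxe),
      phi_exu = as.numeric(phi_exu), pi_ze = as.numeric(pi_ze),
      sigma_y = as.numeric(sigma_y), n = as.integer(n), seed = as.integer(seed)
    ),
    class = "collider_params"
  )
  validate_params(p)
}

#' Validate structural parameters
#'
#' Checks the variance budget `lambda_ge^2 + delta_ue^2 + pi_ze^2 <= 1`
#' (needed so `E` can be standardized to unit variance), finiteness of
#' every field, bounds on the correlation-scale coefficients, `sigma_y > 0`
#' and `n >= 2`.
#'
#' @param p A `collider_params` object (or a plain named list with the
#'   same fields).
#' @return `p`, invisibly unchanged, if valid; otherwise an error of class
#'   `collider_variance_budget_error` or `collider_domain_error`.
#' @export
validate_params <- function(p) {
  num_fields <- c("lambda_ge", "delta_ue", "kappa_uy", "beta_gy", "gamma_ey",
                  "theta_gxe", "phi_exu", "pi_ze", "sigma_y")
  for (f in num_fields) {
    v <- p[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("Field `%s` must be a single finite number.", f),
            class = "collider_domain_error")
    }
  }
  if (is.null(p$n) || length(p$n) != 1L || is.na(p$n) || p$n < 2) {
    abort("Cohort size `n` must be an integer >= 2.",
          class = "collider_domain_error")
  }
  if (is.null(p$seed) || length(p$seed) != 1L || is.na(p$seed)) {
    abort("`seed` must be a single integer.", class = "collider_domain_error")
  }
  for (f in c("lambda_ge", "delta_ue", "pi_ze")) {
    if (p[[f]] < 0 || p[[f]] > 0.95) {
      abort(sprintf("`%s` must lie in [0, 0.95], got %.3f.", f, p[[f]]),
            class = "collider_domain_error")
    }
  }
  if (p$sigma_y <= 0) {
    abort("`sigma_y` must be strictly positive.",
          class = "collider_domain_error")
  }
  budget <- p$lambda_ge^2 + p$delta_ue^2 + p$pi_ze^2
  if (budget > 1) {
    abort(sprintf(paste0(
      "Variance budget exceeded: lambda_ge^2 + delta_ue^2 + pi_ze^2 = %.4f ",
      "> 1, so the environment cannot be scaled to unit variance."), budget),
      class = "collider_variance_budget_error")
  }
  if (!inherits(p, "collider_params")) class(p) <- "collider_params"
  invisible(p)
}

#' @export
print.collider_params <- function(x, ...) {
  cat("<collider_params>\n")
  cat(sprintf("  E  = %.3g G + %.3g U + %.3g Z + noise   (Var(E) = 1)\n",
              x$lambda_ge, x$delta_ue, x$pi_ze))
  cat(sprintf("  Y  = %.3g G + %.3g E + %.3g G:E + %.3g U + %.3g E:U + noise(sd %.3g)\n",
              x$beta_gy, x$gamma_ey, x$theta_gxe, x$kappa_uy, x$phi_exu,
              x$sigma_y))
  cat(sprintf("  n  = %d, seed = %d\n", x$n, x$seed))
  invisible(x)
}

# clone with replaced fields, re-validating
modify_params <- function(p, ...) {
  repl <- list(...)
  for (nm in names(repl)) p[[nm]] <- repl[[nm]]
  p$n <- as.integer(p$n)
  p$seed <- as.integer(p$seed)
  validate_params(p)
  p
}

#' Read structural parameters from a JSON configuration file
#'
#' The file holds a flat JSON object whose keys match the arguments of
#' [collider_params()]; absent keys take their defaults.
#'
#' @param path Path to a JSON file.
#' @return A validated `collider_params`.
#' @export
read_params_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(collider_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(sprintf("Unknown parameter field(s) in %s: %s",
                  path, paste(extra, collapse = ", ")),
          class = "collider_domain_error")
  }
  do.call(collider_params, cfg)
}
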