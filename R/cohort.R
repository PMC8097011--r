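#' Simulate one cohort from the structural model
#'
#' Draws `G`, `U` (and `Z` when `pi_ze > 0`) as independent standard
#' normals, builds the environment as
#' `E = lambda_ge*G + delta_ue*U + pi_ze*Z + noise` with the noise variance
#' chosen so that `Var(E) = 1`, and the outcome as
#' `Y = beta_gy*G + gamma_ey*E + theta_gxe*G*E + kappa_uy*U +
#' phi_exu*E*U + noise(sd = sigma_y)`.
#'
#' The draw is fully determined by `p$seed` and does not disturb the
#' caller's RNG state.
#'
#' @param p A validated [collider_params()] object.
#' @return A tibble of class `collider_cohort` with columns `g`, `u`, `e`,
#'   `y` (and `z` when an instrument is simulated) and the generating
#'   parameters attached as attribute `"params"`.
#' @examples
#' p <- collider_params(lambda_ge = 0.3, delta_ue = 0.25, kappa_uy = 0.25,
#'                      n = 1000, seed = 7)
#' cohort <- generate_cohort(p)
#' cor(cohort$g, cohort$e)  # ~ 0.3 by construction
#' @export
generate_cohort <- function(p) {
  validate_params(p)
  n <- p$n
  sd_e <- sqrt(1 - p$lambda_ge^2 - p$delta_ue^2 - p$pi_ze^2)
  has_z <- p$pi_ze > 0
  cohort <- withr::with_seed(p$seed, {
    g <- rnorm(n)
    u <- rnorm(n)
    z <- if (has_z) rnorm(n) else NULL
    e <- p$lambda_ge * g + p$delta_ue * u + rnorm(n, sd = sd_e)
    if (has_z) e <- e + p$pi_ze * z
    y <- p$beta_gy * g + p$gamma_ey * e + p$theta_gxe * g * e +
      p$kappa_uy * u + p$phi_exu * e * u + rnorm(n, sd = p$sigma_y)
    if (has_z) tibble(g = g, u = u, e = e, y = y, z = z)
    else tibble(g = g, u = u, e = e, y = y)
  })
  attr(cohort, "params") <- p
  class(cohort) <- c("collider_cohort", class(cohort))
  cohort
}

#' Retrieve the generating parameters of a simulated cohort
#'
#' @param cohort A `collider_cohort` tibble.
#' @return The `collider_params` carried by the cohort, or `NULL` for a
#'   plain data frame.
#' @export
cohort_params <- function(cohort) {
  attr(cohort, "params", exact = TRUE)
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with header `g,u,e,y[,z]`; the generating parameters are not
#' serialized, so a round-tripped cohort compares on values only.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
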