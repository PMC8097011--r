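#' Specify a replicated simulation grid
#'
#' A grid crosses gene-environment correlations (rGE) with confounder
#' strengths; each cell is simulated `n_reps` times and fitted with the
#' scenario's estimator. Defaults follow the published design: rGE from 0
#' to 0.5 in steps of 0.05; modest, moderate and strong confounders
#' (0.12, 0.25, 0.38) applied to both the U-E and U-Y paths; direct
#' effects 0.6; a G-by-E coefficient of 0.1 in interaction scenarios.
#'
#' @param scenario One of `"additive"`, `"interaction"`,
#'   `"interaction_exu"` (confounder moderates the environment effect,
#'   `phi_exu` default 0.3) or `"iv"` (instrument with `pi_ze` default
#'   0.5, fitted by 2SLS).
#' @param rge_values Gene-environment correlations to sweep.
#' @param u_strengths Confounder strengths, applied as both `delta_ue`
#'   and `kappa_uy`.
#' @param base_params A [collider_params()] giving effect sizes, noise,
#'   cohort size and base seed; `lambda_ge`, `delta_ue`, `kappa_uy` are
#'   overwritten cell by cell. `NULL` builds scenario defaults.
#' @param n_reps Replicates per cell. Default 200.
#' @return A `collider_grid_spec` list.
#' @examples
#' spec <- grid_spec("additive", n_reps = 20)
#' @export
grid_spec <- function(scenario = c("additive", "interaction",
                                   "interaction_exu", "iv"),
                      rge_values = seq(0, 0.5, by = 0.05),
                      u_strengths = c(0.12, 0.25, 0.38),
                      base_params = NULL,
                      n_reps = 200L) {
  scenario <- match.arg(scenario)
  if (is.null(base_params)) {
    base_params <- collider_params(
      theta_gxe = if (scenario %in% c("interaction", "interaction_exu")) 0.1 else 0,
      phi_exu = if (scenario == "interaction_exu") 0.3 else 0,
      pi_ze = if (scenario == "iv") 0.5 else 0
    )
  }
  validate_params(base_params)
  if (n_reps < 1) {
    abort("`n_reps` must be a positive integer.",
          class = "collider_domain_error")
  }
  if (scenario == "iv" && base_params$pi_ze <= 0) {
    abort("The iv scenario needs `pi_ze > 0` in `base_params`.",
          class = "collider_domain_error")
  }
  spec <- structure(
    list(scenario = scenario,
         rge_values = as.numeric(rge_values),
         u_strengths = as.numeric(u_strengths),
         base_params = base_params,
         n_reps = as.integer(n_reps)),
    class = "collider_grid_spec"
  )
  # every cell must respect the variance budget; fail early, naming the cell
  for (rge in spec$rge_values) {
    for (u in spec$u_strengths) {
      tryCatch(
        modify_params(base_params, lambda_ge = rge, delta_ue = u,
                      kappa_uy = u),
        error = function(cnd) {
          abort(sprintf("Invalid grid cell (rge = %.3g, u = %.3g): %s",
                        rge, u, conditionMessage(cnd)),
                class = class(cnd)[[1]], parent = cnd)
        })
    }
  }
  spec
}

#' @export
print.collider_grid_spec <- function(x, ...) {
  cat(sprintf("<collider_grid_spec> %s scenario\n", x$scenario))
  cat(sprintf("  rGE: %s\n", paste(x$rge_values, collapse = ", ")))
  cat(sprintf("  U strengths: %s\n", paste(x$u_strengths, collapse = ", ")))
  cat(sprintf("  %d replicates of n = %d per cell\n",
              x$n_reps, x$base_params$n))
  invisible(x)
}

u_strength_label <- function(u) {
  dplyr::case_when(
    abs(u - 0.12) < 1e-9 ~ "modest",
    abs(u - 0.25) < 1e-9 ~ "moderate",
    abs(u - 0.38) < 1e-9 ~ "strong",
    .default = sprintf("u=%.3g", u)
  )
}

# deterministic, order-insensitive seed schedule
cell_seed <- function(base_seed, cell_idx, replicate) {
  as.integer((as.double(base_seed) + 100003 * cell_idx + replicate) %%
               2147483647)
}

scenario_fitter <- function(scenario) {
  switch(scenario,
         additive = fit_additive,
         interaction = fit_interaction,
         interaction_exu = fit_interaction,
         iv = fit_iv)
}

scenario_truth <- function(scenario, p) {
  truth <- c(intercept = 0, g = p$beta_gy, e = p$gamma_ey)
  if (scenario %in% c("interaction", "interaction_exu")) {
    truth <- c(truth, gxe = p$theta_gxe)
  }
  truth
}

#' Run a replicated simulation grid
#'
#' For every (rGE, confounder strength) cell, generates `n_reps` cohorts
#' under a deterministic seed schedule, fits the scenario's model and
#' aggregates estimates across replicates. `mean_bias` is the mean
#' estimate minus the generative truth; `r2_inflation` is the mean fitted
#' R-squared minus the share of outcome variance genuinely explained by
#' the modelled effects.
#'
#' @param spec A [grid_spec()].
#' @param progress Emit a per-cell progress message to stderr.
#' @return A tibble of class `collider_grid` with one row per cell and
#'   term: `rge`, `u_strength`, `u_label`, `term`, `truth`,
#'   `mean_estimate`, `sd_estimate`, `mean_bias`, `mean_r2`,
#'   `r2_true_share`, `r2_inflation`, `n_reps`. The spec is attached as
#'   attribute `"spec"`.
#' @examples
#' res <- run_grid(grid_spec("additive", rge_values = c(0, 0.3),
#'                           u_strengths = 0.25,
#'                           base_params = collider_params(n = 500),
#'                           n_reps = 10))
#' dplyr::filter(res, term == "g")
#' @export
run_grid <- function(spec, progress = FALSE) {
  if (!inherits(spec, "collider_grid_spec")) {
    abort("`spec` must be built with grid_spec().",
          class = "collider_domain_error")
  }
  fitter <- scenario_fitter(spec$scenario)
  cells <- tidyr::expand_grid(rge = spec$rge_values, u = spec$u_strengths)
  base_seed <- spec$base_params$seed
  rows <- purrr::pmap(
    list(cells$rge, cells$u, seq_len(nrow(cells))),
    function(rge, u, cell_idx) {
      p <- modify_params(spec$base_params, lambda_ge = rge, delta_ue = u,
                         kappa_uy = u)
      if (progress) {
        message(sprintf("cell %d/%d: rge = %.3g, u = %.3g",
                        cell_idx, nrow(cells), rge, u))
      }
      truth <- scenario_truth(spec$scenario, p)
      reps <- purrr::map(seq_len(spec$n_reps), function(r) {
        p_r <- modify_params(p, seed = cell_seed(base_seed, cell_idx, r))
        fit <- fitter(generate_cohort(p_r))
        c(fit$coef[names(truth)], r2 = fit$r_squared)
      })
      est <- do.call(rbind, reps)[, names(truth), drop = FALSE]
      r2s <- purrr::map_dbl(reps, "r2")
      r2_true <- true_r2_share(p)
      tibble(
        rge = rge, u_strength = u, u_label = u_strength_label(u),
        term = names(truth), truth = unname(truth),
        mean_estimate = unname(colMeans(est)),
        sd_estimate = unname(apply(est, 2, stats::sd)),
        mean_bias = unname(colMeans(est)) - unname(truth),
        mean_r2 = mean(r2s),
        r2_true_share = r2_true,
        r2_inflation = mean(r2s) - r2_true,
        n_reps = spec$n_reps
      )
    })
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  class(out) <- c("collider_grid", class(out))
  out
}

#' Run the confounder-moderated interaction scenario
#'
#' The interaction grid with an active `E*U` product term in the outcome:
#' the setting in which the G-by-E coefficient itself becomes biased, in
#' proportion to the rGE and the confounder strength.
#'
#' @param spec A [grid_spec()] with `scenario = "interaction_exu"` and
#'   `base_params$phi_exu > 0`.
#' @inheritParams run_grid
#' @return A `collider_grid` tibble, as [run_grid()].
#' @export
run_exu_scenario <- function(spec, progress = FALSE) {
  if (!inherits(spec, "collider_grid_spec") ||
      spec$scenario != "interaction_exu") {
    abort("`spec` must be a grid_spec with scenario = \"interaction_exu\".",
          class = "collider_domain_error")
  }
  if (spec$base_params$phi_exu <= 0) {
    abort("The E-by-U scenario needs `phi_exu > 0` in `base_params`.",
          class = "collider_domain_error")
  }
  run_grid(spec, progress = progress)
}

#' Export grid results to CSV
#'
#' Long-format CSV with exactly the columns of the grid tibble; rerunning
#' the same spec and seed reproduces the file byte for byte.
#'
#' @param result A non-empty `collider_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_results <- function(result, path) {
  if (!is.data.frame(result) || nrow(result) == 0) {
    abort("`result` must be a non-empty grid result.",
          class = "collider_domain_error")
  }
  tryCatch(
    readr::write_csv(as_tibble(result), path),
    error = function(cnd) {
      abort(sprintf("Failed to write grid results to '%s': %s",
                    path, conditionMessage(cnd)),
            class = "collider_io_error", parent = cnd)
    })
  invisible(path)
}
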