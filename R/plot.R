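#' Bias curves across the gene-environment correlation
#'
#' One line per confounder strength, per term, showing the mean deviation
#' of the estimate from the generative truth as the rGE grows — the
#' deflation of the polygenic-score coefficient and the inflation of the
#' environment coefficient.
#'
#' @param result A `collider_grid` from [run_grid()].
#' @param terms Terms to display (default `g`, `e`, and `gxe` when
#'   present).
#' @return A ggplot object.
#' @export
plot_bias_curves <- function(result, terms = NULL) {
  if (is.null(terms)) {
    terms <- intersect(c("g", "e", "gxe"), unique(result$term))
  }
  dat <- dplyr::filter(result, .data$term %in% terms)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rge, y = .data$mean_bias,
                                    colour = .data$u_label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "gene-environment correlation (rGE)",
                  y = "mean deviation from generative truth",
                  colour = "confounder U") +
    ggplot2::theme_minimal()
}

#' Explained-variance inflation across the gene-environment correlation
#'
#' Mean fitted R-squared minus the true share of outcome variance
#' explained by the modelled effects, per confounder strength.
#'
#' @inheritParams plot_bias_curves
#' @return A ggplot object.
#' @export
plot_r2_inflation <- function(result) {
  dat <- dplyr::distinct(result, .data$rge, .data$u_strength,
                         .data$u_label, .data$r2_inflation)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rge, y = .data$r2_inflation,
                                    colour = .data$u_label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "gene-environment correlation (rGE)",
                  y = "R-squared inflation",
                  colour = "confounder U") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a grid result
#'
#' @param object A `collider_grid`.
#' @param type `"bias"` for [plot_bias_curves()], `"r2"` for
#'   [plot_r2_inflation()].
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @method autoplot collider_grid
#' @export
autoplot.collider_grid <- function(object, type = c("bias", "r2"), ...) {
  type <- match.arg(type)
  switch(type,
         bias = plot_bias_curves(object, ...),
         r2 = plot_r2_inflation(object, ...))
}
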