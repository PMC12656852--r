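#' Observed-versus-predicted panel for one model
#'
#' Scatter of observed against predicted CH4 with the least-squares
#' regression line (solid) and the y = x identity line (dashed); the
#' standard visual check of how far a model's fit departs from perfect
#' concordance.
#'
#' @param obs,pred numeric vectors in the same emission unit.
#' @param unit axis-label unit string (e.g. `"g/d"`).
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_obs_vs_pred <- function(obs, pred, unit = "g/d", title = NULL) {
  fit <- obs_vs_pred_fit(obs, pred)
  ggplot2::ggplot(fit$data, ggplot2::aes(x = pred, y = obs)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed") +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope) +
    ggplot2::labs(x = paste0("Predicted CH4 (", unit, ")"),
                  y = paste0("Observed CH4 (", unit, ")"),
                  title = title) +
    ggplot2::theme_classic()
}

#' Residual-versus-centered-prediction panel
#'
#' The St-Pierre diagnostic: residuals (observed - predicted) against
#' centered predictions, with the fitted bias line and the zero reference.
#'
#' @param fit a `st_pierre` object from [st_pierre_fit()].
#' @param unit axis-label unit string.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_residuals <- function(fit, unit = "g/d", title = NULL) {
  stopifnot(inherits(fit, "st_pierre"))
  ggplot2::ggplot(fit$data,
                  ggplot2::aes(x = pred_centered, y = residual)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(intercept = fit$intercept$estimate,
                         slope = fit$slope$estimate) +
    ggplot2::labs(x = paste0("Centered predicted CH4 (", unit, ")"),
                  y = paste0("Observed - predicted (", unit, ")"),
                  title = title) +
    ggplot2::theme_classic()
}
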