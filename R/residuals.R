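#' St-Pierre residual bias decomposition
#'
#' Ordinary least squares of the residuals (observed - predicted) on the
#' centered predictions (pred - mean(pred)). Centering makes the intercept
#' the mean bias (in emission units) and the slope the linear bias
#' (dimensionless), with independent t-tests for each. Classical OLS
#' standard errors by default; heteroscedasticity-robust (HC3) by flag.
#'
#' @param obs,pred equal-length numeric vectors, n >= 3, no missing values;
#'   predictions must not be constant.
#' @param robust use HC3 sandwich standard errors instead of classical OLS.
#' @return object of class `st_pierre` with elements `intercept`, `slope`
#'   (each a list with `estimate`, `se`, `p`), `n`, and `data` (tibble of
#'   `pred_centered`, `residual` for plotting).
#' @examples
#' f <- st_pierre_fit(c(10, 12, 14, 18), c(9, 11, 15, 17))
#' f$intercept$estimate  # mean bias
#' @export
st_pierre_fit <- function(obs, pred, robust = FALSE) {
  check_pair(obs, pred, min_n = 3)
  if (var(pred) == 0) {
    stop("slope undefined: zero variance in predictions")
  }
  pc <- pred - mean(pred)
  resid <- obs - pred
  fit <- stats::lm(resid ~ pc)
  est <- stats::coef(fit)
  X <- cbind(1, pc)
  bread <- solve(crossprod(X))
  df <- length(obs) - 2
  if (robust) {
    # HC3 sandwich: leverage-adjusted squared residuals
    h <- stats::hatvalues(fit)
    u2 <- stats::residuals(fit)^2 / (1 - h)^2
    vc <- bread %*% crossprod(X * u2, X) %*% bread
    se <- sqrt(diag(vc))
  } else {
    sigma2 <- sum(stats::residuals(fit)^2) / df
    se <- sqrt(diag(sigma2 * bread))
  }
  p <- 2 * stats::pt(abs(est / se), df = df, lower.tail = FALSE)
  structure(list(
    intercept = list(estimate = unname(est[1]), se = unname(se[1]), p = unname(p[1])),
    slope = list(estimate = unname(est[2]), se = unname(se[2]), p = unname(p[2])),
    n = length(obs),
    robust = robust,
    data = tibble::tibble(pred_centered = pc, residual = resid)
  ), class = "st_pierre")
}

#' @export
print.st_pierre <- function(x, ...) {
  cat(sprintf("St-Pierre residual regression (n = %d%s)\n", x$n,
              if (x$robust) ", HC3 SEs" else ""))
  cat(sprintf("  mean bias (intercept): %8.3f  (se %.3f, p %.4f)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$p))
  cat(sprintf("  linear bias (slope):   %8.3f  (se %.3f, p %.4f)\n",
              x$slope$estimate, x$slope$se, x$slope$p))
  invisible(x)
}

#' Classify prediction bias from the location shift mu
#'
#' Positive mu indicates underprediction (observed mean above predicted),
#' negative mu overprediction; values within `dead_band` of zero are
#' classified as `"none"`.
#'
#' @param mu location-shift statistic from the CCC decomposition.
#' @param dead_band half-width of the zero band (default 0).
#' @return `"underprediction"`, `"overprediction"` or `"none"`.
#' @export
bias_direction <- function(mu, dead_band = 0) {
  stopifnot(is.finite(mu), dead_band >= 0)
  if (mu > dead_band) "underprediction"
  else if (mu < -dead_band) "overprediction"
  else "none"
}

#' Observed-versus-predicted regression
#'
#' Least-squares fit of observed on predicted, the line drawn against the
#' y = x identity in observed-vs-predicted panels. Its slope minus one is
#' exactly the St-Pierre slope, and deviations from (intercept 0, slope 1)
#' visualise mean and linear bias.
#'
#' @param obs,pred equal-length numeric vectors, n >= 2.
#' @return list with `slope`, `intercept`, `n` and `data` (tibble of `obs`,
#'   `pred`) for plotting.
#' @export
obs_vs_pred_fit <- function(obs, pred) {
  check_pair(obs, pred, min_n = 2)
  if (var(pred) == 0) stop("slope undefined: zero variance in predictions")
  fit <- stats::lm(obs ~ pred)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(obs),
       data = tibble::tibble(obs = obs, pred = pred))
}
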