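# Moment helpers: the metric definitions are written in terms of means,
# SDs and Pearson r. "population" uses /n variances, under which the MSPE
# decomposition is an exact identity; "sample" uses /(n-1), matching how
# summary SDs are usually printed in evaluation tables.
ch4_moments <- function(obs, pred, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  check_pair(obs, pred)
  n <- length(obs)
  denom <- if (convention == "population") n else n - 1
  sy <- sqrt(sum((obs - mean(obs))^2) / denom)
  sp <- sqrt(sum((pred - mean(pred))^2) / denom)
  r <- if (sy > 0 && sp > 0) {
    # clamp round-off overshoot for (near-)perfectly correlated vectors
    max(-1, min(1, sum((obs - mean(obs)) * (pred - mean(pred))) / denom / (sy * sp)))
  } else NA_real_
  list(n = n, obs_mean = mean(obs), pred_mean = mean(pred),
       obs_sd = sy, pred_sd = sp, r = r)
}

check_pair <- function(obs, pred, min_n = 2) {
  if (length(obs) != length(pred)) {
    stop("observed and predicted vectors differ in length")
  }
  if (anyNA(obs) || anyNA(pred)) stop("missing values in obs/pred")
  if (length(obs) < min_n) stop("need at least ", min_n, " paired values")
  invisible(TRUE)
}

#' Mean square prediction error
#'
#' `MSPE = mean((obs - pred)^2)`; `RMSPE = sqrt(MSPE)`; `RMSPE%` expresses
#' RMSPE as a percentage of the observed mean.
#'
#' @param obs,pred equal-length numeric vectors without missing values.
#' @return list with `mspe`, `rmspe`, `rmspe_pct`.
#' @examples
#' mspe(c(1, 2, 3), c(2, 3, 4))  # MSPE 1, RMSPE 1
#' @export
mspe <- function(obs, pred) {
  check_pair(obs, pred)
  m <- mean((obs - pred)^2)
  list(mspe = m, rmspe = sqrt(m), rmspe_pct = sqrt(m) / mean(obs) * 100)
}

#' Decompose the MSPE into mean bias, slope bias and random error
#'
#' `ECT = (pred_mean - obs_mean)^2` (overall mean bias), `ER =
#' (sd_pred - r * sd_obs)^2` (regression slope / systematic bias), `ED =
#' (1 - r^2) * sd_obs^2` (random variance). Under the population moment
#' convention the three components sum to the MSPE exactly and the
#' percentages to 100; under the sample convention (as printed in many
#' evaluation tables) the percentages can total slightly more than 100.
#'
#' @inheritParams mspe
#' @param convention `"population"` (exact identity, default) or `"sample"`.
#' @return list with absolute components `ect`, `er`, `ed`, percentages
#'   `ect_pct`, `er_pct`, `ed_pct`, and `mspe`.
#' @export
decompose_mspe <- function(obs, pred, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  mo <- ch4_moments(obs, pred, convention)
  m <- mspe(obs, pred)$mspe
  if (is.na(mo$r)) {
    if (mo$obs_sd == 0 && mo$pred_sd == 0) {
      message("degenerate decomposition: zero variance in obs and pred; ER = ED = 0")
      er <- ed <- 0
    } else if (mo$pred_sd == 0) {
      # constant predictions: no slope term, all observed spread is random
      er <- 0
      ed <- mo$obs_sd^2
    } else {
      er <- mo$pred_sd^2
      ed <- 0
    }
  } else {
    er <- (mo$pred_sd - mo$r * mo$obs_sd)^2
    ed <- (1 - mo$r^2) * mo$obs_sd^2
  }
  ect <- (mo$pred_mean - mo$obs_mean)^2
  pct <- function(x) if (m > 0) x / m * 100 else 0
  list(ect = ect, er = er, ed = ed,
       ect_pct = pct(ect), er_pct = pct(er), ed_pct = pct(ed),
       mspe = m, convention = convention)
}

#' Concordance correlation coefficient from summary statistics
#'
#' Lin's CCC via its accuracy decomposition: the scale shift
#' `nu = sd_obs/sd_pred`, the location shift
#' `mu = (obs_mean - pred_mean)/sqrt(sd_obs * sd_pred)` (positive mu =
#' underprediction, negative = overprediction), the bias-correction factor
#' `Cb = 2/(nu + 1/nu + mu^2)` and `CCC = r * Cb`. This summary-statistic
#' path lets printed evaluation-table rows be re-derived without raw data.
#'
#' @param obs_mean,obs_sd,pred_mean,pred_sd summary statistics (SDs > 0).
#' @param r Pearson correlation between observed and predicted.
#' @return list with `nu`, `mu`, `cb`, `ccc`, `r`.
#' @examples
#' ccc_from_summary(392.87, 91.04, 430.31, 65.10, 0.81)$ccc  # ~0.69
#' @export
ccc_from_summary <- function(obs_mean, obs_sd, pred_mean, pred_sd, r) {
  if (is.na(obs_sd) || is.na(pred_sd) || obs_sd <= 0 || pred_sd <= 0) {
    stop("undefined statistic: CCC needs positive observed and predicted SDs")
  }
  if (abs(r) > 1 + 1e-8) stop("Pearson r must lie in [-1, 1]")
  r <- max(-1, min(1, r))
  nu <- obs_sd / pred_sd
  mu <- (obs_mean - pred_mean) / sqrt(obs_sd * pred_sd)
  cb <- 2 / (nu + 1 / nu + mu^2)
  list(nu = nu, mu = mu, cb = cb, ccc = r * cb, r = r)
}

#' Concordance correlation coefficient from raw vectors
#'
#' Computes the moments under the requested convention and delegates to
#' [ccc_from_summary()], so the two paths agree to machine precision.
#'
#' @inheritParams mspe
#' @param convention moment convention for the SDs; `"sample"` default,
#'   matching printed summary tables.
#' @return list with `nu`, `mu`, `cb`, `ccc`, `r`.
#' @export
ccc_stats <- function(obs, pred, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  mo <- ch4_moments(obs, pred, convention)
  if (is.na(mo$r)) stop("undefined statistic: zero variance in obs or pred")
  ccc_from_summary(mo$obs_mean, mo$obs_sd, mo$pred_mean, mo$pred_sd, mo$r)
}

#' Coefficient of determination between observed and predicted values
#'
#' Two conventions are in circulation for prediction-model R²:
#' `"one_minus_sse_sst"` is `1 - sum((obs-pred)^2)/sum((obs-obs_mean)^2)`
#' (can be negative for a poor model); `"squared_r"` is the squared Pearson
#' correlation (the convention under which published evaluation tables print
#' R² = r²). `squared_r` is undefined (NA) when either vector has zero
#' variance.
#'
#' @inheritParams mspe
#' @param variant which definition to compute.
#' @return scalar R².
#' @export
coefficient_of_determination <- function(obs, pred,
                                         variant = c("one_minus_sse_sst",
                                                     "squared_r")) {
  variant <- match.arg(variant)
  check_pair(obs, pred)
  if (var(obs) == 0) stop("undefined statistic: zero observed variance")
  if (variant == "one_minus_sse_sst") {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  } else {
    if (var(pred) == 0) return(NA_real_)
    cor(obs, pred)^2
  }
}

#' RMSPE-to-observed-SD ratio
#'
#' `RSR = RMSPE / sd_obs`. Values below 1 mean the model predicts better
#' than the observed mean would; models are ranked by ascending RSR.
#'
#' @param rmspe root mean square prediction error.
#' @param obs_sd standard deviation of the observed values (> 0).
#' @return scalar RSR.
#' @examples
#' rsr(64.86, 91.04)  # ~0.71
#' @export
rsr <- function(rmspe, obs_sd) {
  if (is.na(obs_sd) || obs_sd <= 0) stop("undefined statistic: zero observed SD")
  rmspe / obs_sd
}
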