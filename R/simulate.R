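# Variables drawn jointly from the Gaussian copula; the remaining numeric
# fields are derived from them (gei, ndfi, adfi) or generated by the CH4
# mechanism (ch4_g, ch4_mj).
copula_vars <- c("bw", "ndf", "ee", "dmi", "omi", "mei", "omd", "ndfd", "forage")
derived_vars <- c("gei", "ndfi", "adfi", "ch4_g", "ch4_mj")

#' Configuration for the synthetic treatment-mean generator
#'
#' Defaults emulate the published 135-treatment dairy database: per-variable
#' marginal targets (mean, SD, min, max) and missingness rates equal to
#' 1 - n/135 from the published per-variable observation counts; a latent
#' Gaussian copula correlating the intake variables (DMI, OMI, MEI) at
#' `intake_rho`, with each marginal drawn as a range-truncated normal whose
#' latent location and scale are moment-matched so the truncated
#' distribution itself hits the target mean and SD (plain truncation would
#' under-disperse the heavily range-limited variables such as MEI); and a
#' DMI-driven CH4 mechanism — a registry model (default
#' 21, the quadratic DMI equation) plus optional additive NDF/EE modifiers
#' and Gaussian residual noise calibrated so the realized CH4 CV is about
#' 22%, the spread of the emulated database.
#'
#' The derived-variable conventions keep the intake identities realistic
#' without exact collinearity: `ndfi = dmi x ndf/1000 x (1+e)` with 5%
#' relative noise, `adfi = ndfi x 0.576 x (1+e)` (the target ADFI/NDFI
#' ratio) with 21% relative noise, and `gei = dmi x 17.07 MJ/kg x (1+e)`
#' with 17.6% relative noise; the ratio and density noises are set so the
#' derived CVs match the marginal targets. `ch4_mj` is exactly
#' `ch4_g x 0.05565`.
#'
#' @param n_records number of treatment means (default 135).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param intake_rho latent correlation among DMI, OMI and MEI.
#' @param dmi_ch4_target nominal DMI–CH4 correlation target retained in the
#'   config for reference; with a mechanism-generated CH4 the realized
#'   correlation follows from the mechanism and residual SD instead.
#' @param mechanism list: `model_id` (registry id of the true mean
#'   function), `ndf_coef`/`ee_coef` (additive g/d per g/kg deviation from
#'   the target NDF/EE means), `residual_sd` (g/d).
#' @param missing_rates named numeric overrides of the per-variable
#'   missingness fractions (in `[0, 1)`), e.g. `c(dmi = 0)`.
#' @param clip_ch4 clip generated CH4 to its marginal [min, max] range
#'   (default TRUE). Disable to generate from the exact no-bias model,
#'   e.g. for studying test size.
#' @return object of class `ch4_gen_config`.
#' @export
generator_config <- function(n_records = 135, seed = 1, intake_rho = 0.5,
                             dmi_ch4_target = sqrt(0.44),
                             mechanism = list(), missing_rates = NULL,
                             clip_ch4 = TRUE) {
  targets <- utils::read.csv(mv_extdata("variable_targets.csv"))
  targets$missing_rate <- 1 - targets$n / 135
  if (!is.null(missing_rates)) {
    stopifnot(!is.null(names(missing_rates)),
              all(names(missing_rates) %in% targets$name),
              all(missing_rates >= 0 & missing_rates < 1))
    targets$missing_rate[match(names(missing_rates), targets$name)] <-
      unname(missing_rates)
  }
  mech <- utils::modifyList(
    list(model_id = 21, ndf_coef = 0, ee_coef = 0, residual_sd = 85),
    mechanism)
  stopifnot(n_records >= 1, mech$residual_sd > 0,
            intake_rho > -1, intake_rho < 1)
  targets$latent_mu <- NA_real_
  targets$latent_sig <- NA_real_
  for (v in copula_vars) {
    i <- match(v, targets$name)
    lat <- calibrate_truncnorm(targets$mean[i], targets$sd[i],
                               targets$min[i], targets$max[i])
    targets$latent_mu[i] <- lat[["mu"]]
    targets$latent_sig[i] <- lat[["sig"]]
  }
  structure(list(
    n_records = as.integer(n_records),
    seed = as.integer(seed),
    intake_rho = intake_rho,
    dmi_ch4_target = dmi_ch4_target,
    mechanism = mech,
    marginals = tibble::as_tibble(targets),
    derive = list(ge_density = 361.34 / 21.17, ge_density_rel_sd = 0.176,
                  ndfi_rel_sd = 0.05,
                  adf_ndf_ratio = 4.09 / 7.10, adf_ndf_ratio_rel_sd = 0.21),
    clip_ch4 = clip_ch4
  ), class = "ch4_gen_config")
}

#' @export
print.ch4_gen_config <- function(x, ...) {
  cat(sprintf("<ch4_gen_config> n = %d, seed = %d\n", x$n_records, x$seed))
  cat(sprintf("  mechanism: registry model %d + N(0, %g) g/d%s\n",
              x$mechanism$model_id, x$mechanism$residual_sd,
              if (x$clip_ch4) ", range-clipped" else ""))
  cat(sprintf("  copula: intake rho = %g over {dmi, omi, mei}\n", x$intake_rho))
  invisible(x)
}

# truncated-normal moments for latent parameters (mu, sig) on [lo, hi]
truncnorm_moments <- function(mu, sig, lo, hi) {
  a <- (lo - mu) / sig
  b <- (hi - mu) / sig
  Z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sig * (da - db) / Z
  v <- sig^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Latent (mu, sig) whose truncated distribution matches the target mean/sd.
# Truncating a normal at the published min/max shrinks its spread, so the
# latent scale must be wider than the target sd; a target sd above the
# uniform limit (range/sqrt(12)) is approached as closely as attainable.
calibrate_truncnorm <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    ((mo["mean"] - mean) / sd)^2 + ((mo["sd"] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  c(mu = fit$par[1], sig = exp(fit$par[2]))
}

# latent-correlation matrix over the copula variables
copula_correlation <- function(config) {
  p <- length(copula_vars)
  R <- diag(p)
  dimnames(R) <- list(copula_vars, copula_vars)
  intake <- c("dmi", "omi", "mei")
  for (a in intake) for (b in intake) {
    if (a != b) R[a, b] <- config$intake_rho
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("config error: correlation matrix not positive definite")
  R
}

# truncated-normal quantile transform of a uniform draw
qtruncnorm <- function(u, mean, sd, lo, hi) {
  a <- pnorm((lo - mean) / sd)
  b <- pnorm((hi - mean) / sd)
  qnorm(a + u * (b - a)) * sd + mean
}

#' Generate a synthetic treatment-mean CH4 database
#'
#' Draws the base diet/intake variables from a latent Gaussian copula with
#' truncated-normal marginals, derives the intake identities (NDFI, ADFI,
#' GEI) with multiplicative noise, generates CH4 from the configured
#' mechanism (registry model + modifiers + Gaussian residual), sets
#' `ch4_mj = ch4_g x 0.05565` exactly, and finally applies independent
#' per-variable Bernoulli missingness. Fully reproducible from the seed.
#'
#' @param config a [generator_config()].
#' @return database tibble with `study_id`, `treatment_id`, the numeric
#'   variables and `method`; attribute `seed` records the generating seed.
#' @export
generate_ch4_database <- function(config = generator_config()) {
  stopifnot(inherits(config, "ch4_gen_config"))
  n <- config$n_records
  set.seed(config$seed)
  R <- copula_correlation(config)
  Z <- matrix(rnorm(n * ncol(R)), n) %*% chol(R)
  U <- pnorm(Z)
  colnames(U) <- copula_vars
  tg <- config$marginals
  row_of <- function(v) tg[tg$name == v, ]
  db <- tibble::tibble(.rows = n)
  for (v in copula_vars) {
    t <- row_of(v)
    db[[v]] <- qtruncnorm(U[, v], t$latent_mu, t$latent_sig, t$min, t$max)
  }
  dv <- config$derive
  clip <- function(x, v) pmin(pmax(x, row_of(v)$min), row_of(v)$max)
  db$gei <- clip(db$dmi * dv$ge_density *
                   (1 + rnorm(n, 0, dv$ge_density_rel_sd)), "gei")
  ndfi <- db$dmi * db$ndf / 1000 * (1 + rnorm(n, 0, dv$ndfi_rel_sd))
  # dietary plausibility: NDF intake between 20% and 50% of DMI
  db$ndfi <- clip(pmin(pmax(ndfi, 0.2 * db$dmi), 0.5 * db$dmi), "ndfi")
  db$adfi <- clip(db$ndfi * dv$adf_ndf_ratio *
                    (1 + rnorm(n, 0, dv$adf_ndf_ratio_rel_sd)), "adfi")

  mech <- config$mechanism
  model <- ch4_model(mech$model_id)
  mean_fun <- predict(model, db)
  if (model$output_unit == "MJ_d") mean_fun <- mean_fun / CH4_MJ_PER_G
  mean_fun <- mean_fun +
    mech$ndf_coef * (db$ndf - row_of("ndf")$mean) +
    mech$ee_coef * (db$ee - row_of("ee")$mean)
  ch4 <- mean_fun + rnorm(n, 0, mech$residual_sd)
  db$ch4_g <- if (config$clip_ch4) clip(ch4, "ch4_g") else pmax(ch4, 1)
  db$ch4_mj <- db$ch4_g * CH4_MJ_PER_G

  # per-variable independent missingness, after consistency derivation
  for (v in c(copula_vars, derived_vars)) {
    rate <- row_of(v)$missing_rate
    if (rate > 0) db[[v]][runif(n) < rate] <- NA_real_
  }

  # treatments grouped into studies of 1-3 diets
  sizes <- sample(1:3, n, replace = TRUE)
  study <- rep(seq_along(sizes), sizes)[seq_len(n)]
  out <- tibble::tibble(
    study_id = sprintf("S%03d", study),
    treatment_id = paste0("T", stats::ave(study, study, FUN = seq_along))
  )
  out <- cbind(out, db[, ch4_numeric_fields()])
  out$method <- sample(c("chamber", "sf6", "greenfeed"), n, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3))
  out <- tibble::as_tibble(out)
  attr(out, "seed") <- config$seed
  out
}

#' Plant a CH4 outlier in a database
#'
#' Replaces one observed CH4 value with `Q3 + magnitude x IQR` of the
#' current non-missing CH4 values (type-7 quartiles), keeping the g/d and
#' MJ/d columns consistent. With `magnitude` 1.5 the planted value sits
#' exactly on the default IQR fence; values above 1.5 are flagged by
#' [iqr_outlier_mask()], values below are not.
#'
#' @param db database tibble.
#' @param position row index to overwrite.
#' @param magnitude IQR multiples above the third quartile.
#' @return the modified database.
#' @export
plant_outlier <- function(db, position, magnitude) {
  if (nrow(db) == 0) stop("cannot plant an outlier in an empty database")
  if (!is.numeric(position) || length(position) != 1 ||
      position < 1 || position > nrow(db)) {
    stop("bad index: position must be in 1..", nrow(db))
  }
  x <- observed_ch4_g(db)
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 observed CH4 values")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  val <- q[2] + magnitude * (q[2] - q[1])
  db$ch4_g[position] <- val
  if ("ch4_mj" %in% names(db) && !is.na(db$ch4_mj[position])) {
    db$ch4_mj[position] <- val * CH4_MJ_PER_G
  }
  db
}
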