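#' Evaluate one prediction model on a database
#'
#' Subsets the eligible records (all predictors present and observed CH4
#' available in the model's native unit), predicts, and computes the full
#' metric row: observed/predicted means and sample SDs, Pearson r, R² (both
#' the squared-r convention of published evaluation tables and the
#' one-minus-SSE/SST definition), CCC with its nu/mu/Cb components, RMSPE
#' and RMSPE%, the ECT/ER/ED percentages of MSPE, and RSR. All statistics
#' are computed in the model's native output unit.
#'
#' @param model a `ch4_model` or registry id.
#' @param db database tibble.
#' @param convention moment convention for the MSPE decomposition:
#'   `"population"` (exact ECT+ER+ED = MSPE identity, default) or
#'   `"paper_compat"` (sample SDs inside ER/ED, as many published tables
#'   print them, in which case the percentages can sum above 100).
#' @param min_n minimum eligible records (default 3); below this `NULL` is
#'   returned with a warning.
#' @return a one-row tibble, or `NULL` if too few eligible records.
#' @export
evaluate_model <- function(model, db,
                           convention = c("population", "paper_compat"),
                           min_n = 3) {
  convention <- match.arg(convention)
  if (!inherits(model, "ch4_model")) model <- ch4_model(model)
  elig <- eligible_records(model, db)
  n <- sum(elig)
  if (n < min_n) {
    warning("model ", model$id, " skipped: only ", n,
            " eligible record(s), need ", min_n)
    return(NULL)
  }
  sub <- db[elig, , drop = FALSE]
  pred <- predict(model, sub)
  obs <- observed_ch4(sub, model$output_unit)
  err <- mspe(obs, pred)
  dec <- decompose_mspe(obs, pred,
                        if (convention == "population") "population" else "sample")
  mo <- ch4_moments(obs, pred, "sample")
  degenerate <- is.na(mo$r)
  cc <- if (degenerate) NULL else
    ccc_from_summary(mo$obs_mean, mo$obs_sd, mo$pred_mean, mo$pred_sd, mo$r)
  tibble::tibble(
    model_id = model$id,
    label = model$label,
    output_unit = model$output_unit,
    n = n,
    obs_mean = mo$obs_mean, obs_sd = mo$obs_sd,
    pred_mean = mo$pred_mean, pred_sd = mo$pred_sd,
    r = mo$r,
    r2 = if (degenerate) NA_real_ else mo$r^2,
    r2_sse = coefficient_of_determination(obs, pred, "one_minus_sse_sst"),
    ccc = if (degenerate) NA_real_ else cc$ccc,
    nu = if (degenerate) NA_real_ else cc$nu,
    mu = if (degenerate) NA_real_ else cc$mu,
    cb = if (degenerate) NA_real_ else cc$cb,
    mspe = err$mspe, rmspe = err$rmspe, rmspe_pct = err$rmspe_pct,
    ect_pct = dec$ect_pct, er_pct = dec$er_pct, ed_pct = dec$ed_pct,
    rsr = rsr(err$rmspe, mo$obs_sd),
    convention = convention
  )
}

#' Evaluate many models on a database
#'
#' @param db database tibble.
#' @param models registry ids or a list of `ch4_model` objects; default all
#'   registered models.
#' @inheritParams evaluate_model
#' @return tibble with one row per model that had enough eligible records.
#' @export
evaluate_models <- function(db, models = NULL,
                            convention = c("population", "paper_compat"),
                            min_n = 3) {
  convention <- match.arg(convention)
  if (is.null(models)) models <- ch4_models()$model
  if (is.numeric(models)) models <- lapply(models, ch4_model)
  if (inherits(models, "ch4_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    evaluate_model(m, db, convention = convention, min_n = min_n)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) stop("no model had enough eligible records")
  res
}

#' Rank evaluated models by RSR
#'
#' Sorts ascending by RSR with ties broken by ascending model id, optionally
#' keeping only models with `rsr < rsr_max`, and attaches the mean RSR of
#' the retained models as attribute `mean_rsr`.
#'
#' @param results evaluation tibble from [evaluate_models()] (needs columns
#'   `model_id` and `rsr`).
#' @param rsr_max retain only models with RSR strictly below this (default
#'   `Inf`, keep all).
#' @return the ranked tibble with a leading `rank` column.
#' @export
rank_models <- function(results, rsr_max = Inf) {
  keep <- !is.na(results$rsr) & results$rsr < rsr_max
  res <- results[keep, setdiff(names(results), "rank"), drop = FALSE]
  res <- res[order(res$rsr, res$model_id), , drop = FALSE]
  res <- tibble::add_column(res, rank = seq_len(nrow(res)), .before = 1)
  attr(res, "mean_rsr") <- if (nrow(res)) mean(res$rsr) else NA_real_
  res
}

#' Published evaluation summary of the registry models
#'
#' The 15 models with RSR < 1 from a published evaluation of the 40 registry
#' equations against a 135-treatment-mean dairy database: observed and
#' predicted means and SDs, r, R², CCC, mu, RMSPE, RMSPE%, ECT/ER/ED
#' percentages, RSR and n, in the published rank order. The raw database
#' behind these rows is not deposited; the summary statistics let the metric
#' chain (CCC, mu, ECT%, RSR, RMSPE%) be re-derived and checked without it.
#'
#' @return tibble with one row per published model row.
#' @export
published_evaluation <- function() {
  tibble::as_tibble(utils::read.csv(mv_extdata("published_eval_summary.csv")))
}

#' Round an evaluation table for display
#'
#' Rounds all metric columns half-to-even to 2 decimals, mirroring how
#' published evaluation tables are printed; the unrounded table remains the
#' machine output.
#'
#' @param results evaluation tibble.
#' @param digits decimal places (default 2).
#' @return tibble with rounded numeric columns (`n`, ids and labels untouched).
#' @export
round_evaluation <- function(results, digits = 2) {
  num <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                 c("rank", "model_id", "n"))
  for (v in num) results[[v]] <- round(results[[v]], digits)
  results
}
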