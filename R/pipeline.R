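#' Run the full model-evaluation pipeline
#'
#' Load (or simulate) a treatment-mean database, screen observed CH4 for
#' IQR outliers, evaluate the selected registry models, rank them by RSR,
#' and fit St-Pierre residual regressions for the top-k models. Optionally
#' writes the report bundle with [write_report()].
#'
#' @param db database tibble, or a path to a delimited database file, or
#'   `NULL` to simulate one.
#' @param simulate a [generator_config()] used when `db` is `NULL`.
#' @param models registry ids to evaluate (default all 40).
#' @param rsr_max ranking filter passed to [rank_models()].
#' @param convention moment convention passed to [evaluate_models()].
#' @param top_k number of top-ranked models given residual analysis
#'   (default 6, the usual number of panels in published figures).
#' @param outlier_k IQR multiplier for the CH4 screen; `NULL` skips the screen.
#' @param out_dir if non-NULL, write the report bundle here.
#' @return list of class `ch4_report`: `db` (screened database), `removed`,
#'   `evaluation` (full-precision), `ranking` (RSR-ranked, rounded copy in
#'   `ranking_display`), `residual_fits` (named list of `st_pierre` objects),
#'   `residual_summary`, `log` (character), `seed`.
#' @export
run_pipeline <- function(db = NULL, simulate = generator_config(),
                         models = NULL, rsr_max = Inf,
                         convention = c("population", "paper_compat"),
                         top_k = 6, outlier_k = 1.5, out_dir = NULL) {
  convention <- match.arg(convention)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  seed <- NA_integer_
  if (is.null(db)) {
    db <- generate_ch4_database(simulate)
    seed <- simulate$seed
    note("simulated database: n = %d, seed = %d, mechanism model %d",
         nrow(db), seed, simulate$mechanism$model_id)
  } else if (is.character(db)) {
    path <- db
    db <- read_ch4_db(path)
    note("loaded database: %s (n = %d)", path, nrow(db))
  } else {
    db <- tibble::as_tibble(db)
    note("database supplied in memory (n = %d)", nrow(db))
  }
  n_in <- nrow(db)
  removed <- db[0, , drop = FALSE]
  if (!is.null(outlier_k)) {
    scr <- filter_ch4_outliers(db, k = outlier_k)
    removed <- scr$removed
    db <- scr$db
    note("IQR outlier screen (k = %g) on observed CH4: removed %d of %d records",
         outlier_k, nrow(removed), n_in)
  }
  if (is.null(models)) models <- ch4_models()$id
  results <- withCallingHandlers(
    evaluate_models(db, models = models, convention = convention),
    warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (i in seq_len(nrow(results))) {
    note("model %d: n = %d eligible of %d records",
         results$model_id[i], results$n[i], nrow(db))
  }
  ranking <- rank_models(results, rsr_max = rsr_max)
  if (nrow(ranking) == 0) stop("empty report: no model passed rsr_max = ", rsr_max)
  note("ranked %d models; mean RSR of retained models = %.4f",
       nrow(ranking), attr(ranking, "mean_rsr"))

  top <- utils::head(ranking$model_id, top_k)
  fits <- list()
  for (id in top) {
    m <- if (id %in% ch4_models()$id) ch4_model(id) else NULL
    if (is.null(m)) next
    elig <- eligible_records(m, db)
    sub <- db[elig, , drop = FALSE]
    fits[[as.character(id)]] <- st_pierre_fit(observed_ch4(sub, m$output_unit),
                                              predict(m, sub))
  }
  residual_summary <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    tibble::tibble(model_id = as.integer(id), n = f$n,
                   intercept = f$intercept$estimate, intercept_se = f$intercept$se,
                   intercept_p = f$intercept$p,
                   slope = f$slope$estimate, slope_se = f$slope$se,
                   slope_p = f$slope$p)
  }))
  bundle <- structure(list(
    db = db, removed = removed,
    evaluation = results,
    ranking = ranking,
    ranking_display = round_evaluation(ranking),
    residual_fits = fits,
    residual_summary = residual_summary,
    log = log, seed = seed,
    convention = convention
  ), class = "ch4_report")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.ch4_report <- function(x, ...) {
  cat(sprintf("<ch4_report> %d records, %d models evaluated, convention = %s\n",
              nrow(x$db), nrow(x$evaluation), x$convention))
  cat(sprintf("  top of ranking (mean RSR %.2f):\n", attr(x$ranking, "mean_rsr")))
  print(utils::head(x$ranking_display[, c("rank", "model_id", "n", "rmspe_pct",
                                          "ccc", "mu", "rsr")], 6))
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits the ranked evaluation table rounded to 2 decimals
#' (`evaluation.csv`), the full-precision table (`evaluation_full.csv`), the
#' St-Pierre summary (`residual_summary.csv`), per-model residual plot data
#' (`residuals_model<ID>.csv` with `pred_centered`, `residual`), the
#' screened database (`database_used.csv`), and a run log with the seed and
#' per-model eligibility counts (`run_log.txt`).
#'
#' @param bundle a `ch4_report` from [run_pipeline()].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "ch4_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wr <- function(x, file) {
    utils::write.csv(x, file.path(out_dir, file), row.names = FALSE, na = "")
  }
  disp <- bundle$ranking_display
  disp$mean_rsr_retained <- round(attr(bundle$ranking, "mean_rsr"), 2)
  wr(disp, "evaluation.csv")
  wr(bundle$ranking, "evaluation_full.csv")
  if (!is.null(bundle$residual_summary)) {
    wr(bundle$residual_summary, "residual_summary.csv")
  }
  for (id in names(bundle$residual_fits)) {
    wr(bundle$residual_fits[[id]]$data, sprintf("residuals_model%s.csv", id))
  }
  write_ch4_db(bundle$db, file.path(out_dir, "database_used.csv"))
  writeLines(c(sprintf("methaneval %s | R %s",
                       as.character(utils::packageVersion("methaneval")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("seed: %s", bundle$seed),
               bundle$log),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
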