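#' Construct a CH4 prediction model specification
#'
#' A model is an arithmetic expression in the canonical database variables
#' (`dmi`, `gei`, `mei`, `ndfi`, `adfi`, `ndf`, `ee`, `omd`, `forage`, ...)
#' producing emission in `output_unit`. `omd_scale` is an input-scale
#' adapter: the record's OMD (stored in percent) is multiplied by it before
#' the expression is evaluated, so equations whose OMD term is parameterised
#' in g/kg can say so explicitly.
#'
#' @param id integer model id (registry models use 1–40; user models may use
#'   any other id).
#' @param label display label, typically first author and year.
#' @param output_unit `"g_d"` or `"MJ_d"`.
#' @param predictors character vector of required record fields.
#' @param expression the prediction expression as a character string.
#' @param form functional form tag (`"linear"`, `"quadratic"`,
#'   `"exponential"`, `"product"`).
#' @param animal target population tag (`"Dairy"` or `"All"`).
#' @param omd_scale multiplier applied to `omd` before evaluation (10 for
#'   equations whose OMD coefficient expects g/kg).
#' @param alt_label alternative attribution where sources disagree.
#' @param equation the published equation string, kept verbatim for audit.
#' @return an object of class `ch4_model`.
#' @export
new_ch4_model <- function(id, label, output_unit, predictors, expression,
                          form = "linear", animal = "Dairy", omd_scale = 1,
                          alt_label = NA_character_, equation = expression) {
  stopifnot(length(id) == 1, is.character(expression),
            output_unit %in% c("g_d", "MJ_d"), length(predictors) >= 1)
  expr <- str2lang(expression)
  coefs <- suppressWarnings(as.numeric(all.names(expr)))
  coefs <- coefs[is.finite(coefs)]
  structure(list(id = as.integer(id), label = label, alt_label = alt_label,
                 animal = animal, output_unit = output_unit,
                 predictors = predictors, form = form,
                 omd_scale = omd_scale, expression = expression,
                 expr = expr, coefficients = coefs, equation = equation),
            class = "ch4_model")
}

#' @export
print.ch4_model <- function(x, ...) {
  cat(sprintf("<ch4_model %d> %s%s\n", x$id, x$label,
              if (!is.na(x$alt_label)) paste0(" [alt: ", x$alt_label, "]") else ""))
  cat("  ", x$equation, "\n", sep = "")
  cat(sprintf("  unit: %s | form: %s | predictors: %s%s\n",
              sub("_d", "/d", x$output_unit), x$form,
              paste(x$predictors, collapse = ", "),
              if (x$omd_scale != 1) sprintf(" | omd x %g (g/kg)", x$omd_scale) else ""))
  invisible(x)
}

load_registry <- function(path = NULL) {
  if (is.null(path) && !is.null(.mv_env$registry)) return(.mv_env$registry)
  file <- if (is.null(path)) mv_extdata("model_registry.csv") else path
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    new_ch4_model(id = r$id, label = r$label,
                  alt_label = if (is.na(r$alt_label) || r$alt_label == "") NA_character_ else r$alt_label,
                  animal = r$animal, output_unit = r$output_unit,
                  predictors = strsplit(r$predictors, ";")[[1]],
                  form = r$form, omd_scale = r$omd_scale,
                  expression = r$expression, equation = r$equation)
  })
  names(models) <- vapply(models, function(m) as.character(m$id), "")
  ids <- vapply(models, `[[`, 0L, "id")
  if (anyDuplicated(ids)) stop("duplicate model ids in registry")
  if (is.null(path)) .mv_env$registry <- models
  models
}

#' Retrieve one model from the registry
#'
#' @param id registry model id (1–40).
#' @return a `ch4_model` object.
#' @export
ch4_model <- function(id) {
  reg <- load_registry()
  key <- as.character(id)
  if (!key %in% names(reg)) stop("no registry model with id ", id)
  reg[[key]]
}

#' List the registered prediction models
#'
#' Returns the registry (40 published equations) as a tibble in stable id
#' order, optionally filtered. The `model` list-column carries the full
#' `ch4_model` objects.
#'
#' @param predictors_within if given, keep models whose predictor set is a
#'   subset of these fields (e.g. `"dmi"` selects the DMI-only models).
#' @param output_unit if given, keep models with this native output unit.
#' @param filter optional predicate taking a `ch4_model` and returning TRUE/FALSE.
#' @return tibble with columns `id, label, animal, output_unit, form,
#'   predictors, equation, model`.
#' @export
ch4_models <- function(predictors_within = NULL, output_unit = NULL,
                       filter = NULL) {
  reg <- load_registry()
  keep <- vapply(reg, function(m) {
    ok <- TRUE
    if (!is.null(predictors_within)) {
      ok <- ok && all(m$predictors %in% predictors_within)
    }
    if (!is.null(output_unit)) ok <- ok && m$output_unit == output_unit
    if (!is.null(filter)) ok <- ok && isTRUE(filter(m))
    ok
  }, TRUE)
  reg <- unname(reg[keep])
  tibble::tibble(
    id = vapply(reg, `[[`, 0L, "id"),
    label = vapply(reg, `[[`, "", "label"),
    animal = vapply(reg, `[[`, "", "animal"),
    output_unit = vapply(reg, `[[`, "", "output_unit"),
    form = vapply(reg, `[[`, "", "form"),
    predictors = vapply(reg, function(m) paste(m$predictors, collapse = ";"), ""),
    equation = vapply(reg, `[[`, "", "equation"),
    model = unname(reg)
  )
}

#' Predict CH4 emission with a registered model
#'
#' Evaluates the model's equation on each record, in the model's native
#' output unit. All predictors must be present; records missing any
#' predictor raise an error (use [eligible_records()] to subset first).
#'
#' @param object a `ch4_model`.
#' @param newdata database tibble (or a one-row list of named values).
#' @param ... unused.
#' @return numeric vector of predictions in `object$output_unit`.
#' @export
predict.ch4_model <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  for (p in object$predictors) {
    if (!p %in% names(newdata)) {
      stop("record lacks predictor '", p, "' required by model ", object$id)
    }
    if (anyNA(newdata[[p]])) {
      stop("missing values in predictor '", p, "' for model ", object$id,
           "; subset with eligible_records() first")
    }
  }
  env <- as.list(newdata[, intersect(ch4_numeric_fields(), names(newdata))])
  if ("omd" %in% names(env)) env$omd <- env$omd * object$omd_scale
  val <- eval(object$expr, envir = env, enclos = baseenv())
  val <- rep_len(val, nrow(newdata))
  if (any(!is.finite(val))) {
    stop("model ", object$id, " produced non-finite predictions")
  }
  val
}

#' Records eligible for a model's evaluation
#'
#' A record is eligible when every model predictor is present and observed
#' CH4 is available in (or convertible to) the model's native output unit —
#' g/d and MJ/d interconvert, so either observation suffices.
#'
#' @param model a `ch4_model` or registry id.
#' @param db database tibble.
#' @return logical vector, `TRUE` for eligible records.
#' @export
eligible_records <- function(model, db) {
  if (!inherits(model, "ch4_model")) model <- ch4_model(model)
  if (nrow(db) == 0) return(logical(0))
  ok <- rep(TRUE, nrow(db))
  for (p in model$predictors) {
    ok <- ok & if (p %in% names(db)) !is.na(db[[p]]) else FALSE
  }
  ok & !is.na(observed_ch4(db, model$output_unit))
}

# observed CH4 in the requested unit, converting from the other unit
# only where the native observation is absent
observed_ch4 <- function(db, unit) {
  g <- if ("ch4_g" %in% names(db)) db$ch4_g else rep(NA_real_, nrow(db))
  mj <- if ("ch4_mj" %in% names(db)) db$ch4_mj else rep(NA_real_, nrow(db))
  if (unit == "g_d") ifelse(is.na(g), mj / CH4_MJ_PER_G, g)
  else ifelse(is.na(mj), g * CH4_MJ_PER_G, mj)
}

#' Sanity envelope for registry predictions
#'
#' Evaluates every model at given (default Table-1-style mean) inputs and
#' flags predictions outside a plausible dairy range of 100–700 g/d
#' equivalent. Violations are diagnostic, not errors: some historical
#' equations extrapolate badly at modern intake levels.
#'
#' @param inputs named list of mean input values; defaults to the packaged
#'   marginal targets.
#' @return tibble with `id`, `label`, `prediction_g_d`, `within_envelope`.
#' @export
prediction_envelope <- function(inputs = NULL) {
  if (is.null(inputs)) {
    targets <- utils::read.csv(mv_extdata("variable_targets.csv"))
    inputs <- as.list(stats::setNames(targets$mean, targets$name))
  }
  rec <- tibble::as_tibble(inputs)
  reg <- load_registry()
  rows <- lapply(reg, function(m) {
    val <- predict(m, rec)
    g <- if (m$output_unit == "MJ_d") val / CH4_MJ_PER_G else val
    tibble::tibble(id = m$id, label = m$label, prediction_g_d = g,
                   within_envelope = g >= 100 & g <= 700)
  })
  do.call(rbind, rows)
}
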