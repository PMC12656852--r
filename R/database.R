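#' Canonical variables of a treatment-mean CH4 database
#'
#' One row per dietary treatment reported by a source study; any numeric
#' field may be missing. Units follow standard ruminant-nutrition reporting:
#' BW in kg; NDF and EE in g/kg DM; DMI, OMI, NDFI, ADFI in kg/d; GEI and
#' MEI in MJ/d; OMD, NDFD and forage proportion in percent; CH4 in g/d
#' (`ch4_g`) and/or MJ/d (`ch4_mj`).
#'
#' @return tibble with columns `name`, `label`, `unit`.
#' @export
ch4_variables <- function() {
  tibble::tribble(
    ~name,     ~label,                            ~unit,
    "bw",      "body weight",                     "kg",
    "ndf",     "neutral detergent fiber",         "g/kg DM",
    "ee",      "ether extract",                   "g/kg DM",
    "dmi",     "dry matter intake",               "kg/d",
    "omi",     "organic matter intake",           "kg/d",
    "gei",     "gross energy intake",             "MJ/d",
    "mei",     "metabolizable energy intake",     "MJ/d",
    "ndfi",    "NDF intake",                      "kg/d",
    "adfi",    "ADF intake",                      "kg/d",
    "omd",     "organic matter digestibility",    "%",
    "ndfd",    "NDF digestibility",               "%",
    "forage",  "forage proportion of diet DM",    "%",
    "ch4_g",   "enteric methane emission",        "g/d",
    "ch4_mj",  "enteric methane emission",        "MJ/d"
  )
}

ch4_numeric_fields <- function() ch4_variables()$name

ch4_all_fields <- function() {
  c("study_id", "treatment_id", ch4_numeric_fields(), "method")
}

ch4_methods <- c("chamber", "sf6", "greenfeed", "other")

load_alias_map <- function(alias_file = NULL) {
  path <- if (is.null(alias_file)) mv_extdata("header_aliases.csv") else alias_file
  al <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(al$canonical, al$alias)
}

#' Validate a treatment-mean database
#'
#' Checks the record-level invariants: all present numeric values strictly
#' positive, forage within 0–100, digestibilities within (0, 100], and
#' cross-unit CH4 consistency (`|ch4_mj - ch4_g x 0.05565| <= 0.5` MJ/d when
#' both units are reported).
#'
#' @param db a treatment-mean database (data frame).
#' @param ch4_tol cross-unit consistency tolerance in MJ/d.
#' @return `db` invisibly; problems raise errors.
#' @export
validate_ch4_db <- function(db, ch4_tol = 0.5) {
  stopifnot(is.data.frame(db))
  for (v in intersect(ch4_numeric_fields(), names(db))) {
    x <- db[[v]]
    if (!is.numeric(x)) stop("column '", v, "' is not numeric")
    bad <- !is.na(x) & x <= 0
    if (v %in% c("forage") ) bad <- !is.na(x) & (x < 0 | x > 100)
    if (v %in% c("omd", "ndfd")) bad <- !is.na(x) & (x <= 0 | x > 100)
    if (any(bad)) {
      stop("column '", v, "' has ", sum(bad), " out-of-range value(s), e.g. ",
           x[bad][1])
    }
  }
  if (all(c("ch4_g", "ch4_mj") %in% names(db))) {
    both <- !is.na(db$ch4_g) & !is.na(db$ch4_mj)
    dev <- abs(db$ch4_mj[both] - db$ch4_g[both] * CH4_MJ_PER_G)
    if (any(dev > ch4_tol)) {
      stop(sum(dev > ch4_tol), " record(s) report inconsistent CH4 units ",
           "(|MJ/d - g/d x 0.05565| > ", ch4_tol, ")")
    }
  }
  invisible(db)
}

#' Read a treatment-mean CH4 database from delimited text
#'
#' Header names are matched case-insensitively against the canonical
#' vocabulary (`ch4_variables()`) plus a machine-readable alias map; empty
#' cells are missing. A column of CH4 reported in L/d (header `ch4_l` or an
#' alias) is converted to g/d on load via [convert_emission()]. Cells that do
#' not parse as numbers become missing with a warning; the row count of the
#' file is preserved.
#'
#' @param path file path.
#' @param delim field delimiter; `","` (default) or `"\t"`.
#' @param alias_file optional CSV with columns `alias,canonical` replacing
#'   the packaged alias map.
#' @param validate check record invariants after parsing.
#' @return tibble with one row per data row of the file.
#' @export
read_ch4_db <- function(path, delim = ",", alias_file = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) == 0) stop("format error: no header row found in ", path)
  aliases <- load_alias_map(alias_file)
  canon <- tolower(gsub("[^A-Za-z0-9]+", "_", trimws(names(raw))))
  canon <- ifelse(canon %in% names(aliases), unname(aliases[canon]), canon)
  known <- c(ch4_all_fields(), "ch4_l")
  keep <- canon %in% known
  if (!any(keep)) {
    stop("schema error: no recognizable variable columns in ", path)
  }
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]

  out <- tibble::tibble(.rows = nrow(raw))
  out$study_id <- if ("study_id" %in% names(raw)) raw$study_id else NA_character_
  out$treatment_id <- if ("treatment_id" %in% names(raw)) raw$treatment_id else NA_character_
  for (v in c(ch4_numeric_fields(), "ch4_l")) {
    if (!v %in% names(raw)) {
      if (v != "ch4_l") out[[v]] <- NA_real_
      next
    }
    txt <- raw[[v]]
    txt[txt == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & is.na(num)
    if (any(bad)) {
      warning(sum(bad), " unparseable value(s) in column '", v,
              "' set to missing (e.g. \"", txt[bad][1], "\")")
    }
    out[[v]] <- num
  }
  if ("ch4_l" %in% names(out)) {
    from_l <- convert_emission(out$ch4_l, "L_d", "g_d")
    out$ch4_g <- ifelse(is.na(out$ch4_g), from_l, out$ch4_g)
    out$ch4_l <- NULL
  }
  out$method <- if ("method" %in% names(raw)) {
    m <- tolower(trimws(raw$method))
    m[m == ""] <- NA_character_
    ifelse(is.na(m) | m %in% ch4_methods, m, "other")
  } else NA_character_
  if (validate) validate_ch4_db(out)
  out
}

#' Write a treatment-mean CH4 database as delimited text
#'
#' Canonical header, UTF-8, empty cell for missing; round-trips through
#' [read_ch4_db()] at full precision.
#'
#' @param db database tibble.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_ch4_db <- function(db, path, delim = ",") {
  cols <- intersect(ch4_all_fields(), names(db))
  utils::write.table(db[, cols], path, sep = delim, na = "", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Flag outliers by the interquartile-range rule
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]`, the screen applied to
#' observed CH4 when refining an assembled database. Quartiles use linear
#' interpolation between order statistics (R's default type-7 rule), which is
#' fixed so the mask is deterministic; the rule makes the mask invariant
#' under positive affine transforms of the data.
#'
#' @param values numeric vector; `NA` allowed (never flagged).
#' @param k extreme-value multiplier (default 1.5).
#' @return logical vector, `TRUE` where the value is an outlier.
#' @export
iqr_outlier_mask <- function(values, k = 1.5) {
  x <- values[!is.na(values)]
  if (length(x) < 4) {
    stop("insufficient data: need at least 4 non-missing values for the IQR rule")
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  !is.na(values) & (values < lo | values > hi)
}

# observed CH4 in g/d with MJ/d fallback (the outlier-screen variable)
observed_ch4_g <- function(db) {
  g <- if ("ch4_g" %in% names(db)) db$ch4_g else rep(NA_real_, nrow(db))
  mj <- if ("ch4_mj" %in% names(db)) db$ch4_mj else rep(NA_real_, nrow(db))
  ifelse(is.na(g), mj / CH4_MJ_PER_G, g)
}

#' Remove CH4 outliers from a database
#'
#' Applies [iqr_outlier_mask()] to observed CH4 in g/d (falling back to
#' MJ/d / 0.05565 where g/d is absent) and drops flagged records. Other
#' variables can be screened by naming them in `variables`.
#'
#' @param db database tibble.
#' @param k IQR multiplier.
#' @param variables extra variable names to screen per-variable (default none).
#' @return list with `db` (retained records), `removed` (flagged records) and
#'   `mask` (logical flag per input record).
#' @export
filter_ch4_outliers <- function(db, k = 1.5, variables = character()) {
  mask <- iqr_outlier_mask(observed_ch4_g(db), k = k)
  for (v in variables) {
    mask <- mask | iqr_outlier_mask(db[[v]], k = k)
  }
  list(db = db[!mask, , drop = FALSE],
       removed = db[mask, , drop = FALSE],
       mask = mask)
}

#' Per-variable summary statistics of a database
#'
#' One row per variable with at least one value: mean, sample (n-1) SD,
#' min, max, CV (= SD/mean x 100), median (midpoint rule for even n) and the
#' number of non-missing observations. Variables with no data are reported
#' with `n = 0` and missing statistics.
#'
#' @param db database tibble.
#' @return tibble with columns `name, mean, sd, min, max, cv, median, n`.
#' @export
summarize_ch4_db <- function(db) {
  vars <- intersect(ch4_numeric_fields(), names(db))
  rows <- lapply(vars, function(v) {
    x <- db[[v]][!is.na(db[[v]])]
    n <- length(x)
    if (n == 0) {
      return(tibble::tibble(name = v, mean = NA_real_, sd = NA_real_,
                            min = NA_real_, max = NA_real_, cv = NA_real_,
                            median = NA_real_, n = 0L))
    }
    m <- mean(x)
    s <- if (n > 1) stats::sd(x) else 0
    tibble::tibble(name = v, mean = m, sd = s, min = min(x), max = max(x),
                   cv = s / m * 100, median = stats::median(x), n = n)
  })
  do.call(rbind, rows)
}
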