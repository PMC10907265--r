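#' Predictor specification
#'
#' Declares how a raw predictor column is transformed before modelling:
#' `"zscore"` for proportions and other continuous measures, standardized
#' within population; `"log1p_zscore"` for counts/amounts (livestock, land
#' acres, income, education years), natural-log(x + 1) then within-population
#' z-score (these variables legitimately take 0); `"binary"` for 0/1 codings
#' (waged vs subsistence occupation, urban vs rural residence, contraception),
#' left untouched.
#'
#' @param name Column name of the raw predictor.
#' @param transform One of `"zscore"`, `"log1p_zscore"`, `"binary"`.
#' @param note Free-text direction note (e.g. "farming expected positive").
#' @return A `predictor_spec` object.
#' @export
predictor_spec <- function(name, transform = c("zscore", "log1p_zscore", "binary"),
                           note = "") {
  transform <- match.arg(transform)
  structure(list(name = name, transform = transform, note = note),
            class = "predictor_spec")
}

#' @rdname predictor_spec
#' @details `default_predictor_specs()` returns the standard battery of
#'   subsistence and market-integration predictors: activity proportions
#'   (foraging, farming, wage labour), diet-source proportions (farmed,
#'   market), log-scale amounts (livestock, land, income, education), and
#'   binary codings (occupation, residence, contraception).
#' @export
default_predictor_specs <- function() {
  list(
    predictor_spec("prop_foraging",  "zscore", "foraging expected negative"),
    predictor_spec("prop_farming",   "zscore", "farming expected positive"),
    predictor_spec("prop_wage",      "zscore", "wage labour expected negative"),
    predictor_spec("diet_farmed",    "zscore", "farmed diet expected positive"),
    predictor_spec("diet_market",    "zscore", "market diet expected negative"),
    predictor_spec("livestock",      "log1p_zscore", "livestock expected positive"),
    predictor_spec("land",           "log1p_zscore", "land expected positive"),
    predictor_spec("income",         "log1p_zscore", "income direction unclear"),
    predictor_spec("education",      "log1p_zscore", "education expected negative"),
    predictor_spec("occupation_waged", "binary", "waged vs subsistence"),
    predictor_spec("residence_urban",  "binary", "urban vs rural"),
    predictor_spec("contraception",    "binary", "sensitivity control")
  )
}

#' Read a predictor configuration file
#'
#' YAML mapping of column name to transform (and optional note), converted to
#' a list of [predictor_spec()] objects.
#'
#' @param path Path to a YAML file, e.g. `livestock: log1p_zscore`.
#' @return List of `predictor_spec`.
#' @export
read_predictor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    if (is.character(entry)) predictor_spec(nm, entry)
    else predictor_spec(nm, entry$transform, entry$note %||% "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SUBSISTENCE_TYPES <- c("hunter_gatherer", "horticulturalist", "agriculturalist",
                       "pastoralist", "fisher")
MI_LEVELS <- c("low", "medium", "high")

PROPORTION_PREDICTORS <- c("prop_foraging", "prop_farming", "prop_wage",
                           "diet_farmed", "diet_market", "diet_foraged")
AMOUNT_PREDICTORS <- c("livestock", "land", "income", "education")

#' Validate woman-level reproductive records
#'
#' Enforces the hard invariants of the data model: reproductive maturity
#' (age at interview >= 14 years), non-negative integer parity, known
#' population ids, proportion predictors inside \[0, 1\], and non-negative
#' amount predictors. Violations raise an error listing the offending rows;
#' missing predictor cells are allowed and preserved.
#'
#' @param records Data frame with at least `woman_id`, `population_id`,
#'   `age`, `live_births`.
#' @param meta Optional population metadata data frame (`population_id`,
#'   `subsistence_type`, `market_integration`); when supplied, every record's
#'   population must appear in it and categories must come from the closed
#'   vocabularies.
#' @return `records`, invisibly, on success.
#' @export
validate_records <- function(records, meta = NULL) {
  req <- c("woman_id", "population_id", "age", "live_births")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))

  fail <- function(idx, what) {
    if (length(idx)) {
      stop("invalid records (", what, ") at row(s) ",
           paste(utils::head(idx, 10L), collapse = ", "),
           "; woman_id: ",
           paste(utils::head(records$woman_id[idx], 10L), collapse = ", "))
    }
  }
  fail(which(!is.finite(records$age) | records$age < 14), "age below 14 or non-finite")
  y <- records$live_births
  fail(which(!is.finite(y) | y < 0 | y != floor(y)),
       "live_births negative or non-integer")
  if (!is.null(meta)) {
    fail(which(!records$population_id %in% meta$population_id),
         "population_id not in metadata")
    bad_sub <- setdiff(unique(meta$subsistence_type), SUBSISTENCE_TYPES)
    if (length(bad_sub)) stop("unknown subsistence_type: ",
                              paste(bad_sub, collapse = ", "))
    bad_mi <- setdiff(unique(meta$market_integration), MI_LEVELS)
    if (length(bad_mi)) stop("unknown market_integration level: ",
                             paste(bad_mi, collapse = ", "))
  }
  for (p in intersect(PROPORTION_PREDICTORS, names(records))) {
    v <- records[[p]]
    fail(which(!is.na(v) & (v < 0 | v > 1)), paste0(p, " outside [0, 1]"))
  }
  for (p in intersect(AMOUNT_PREDICTORS, names(records))) {
    v <- records[[p]]
    fail(which(!is.na(v) & v < 0), paste0(p, " negative"))
  }
  invisible(records)
}

#' Read reproductive-history records and population metadata
#'
#' Reads the CSV dialect used throughout the package (RFC-4180, UTF-8,
#' header row) and validates all data-model invariants. Missing predictor
#' cells stay `NA`; raw predictor values are kept untouched — transforms
#' are applied later by [standardize_predictors()].
#'
#' @param path Path to the woman-level CSV (columns `woman_id`,
#'   `population_id`, `age`, `live_births`, plus predictor columns).
#' @param meta_path Optional path to the population metadata CSV
#'   (`population_id`, `subsistence_type`, `market_integration`).
#' @return A list of class `fert_data` with elements `records` and `meta`
#'   (`meta` is `NULL` when no metadata file is given).
#' @export
read_records <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e)))
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    tab <- table(records$population_id)
    meta$n_women <- as.integer(tab[match(meta$population_id, names(tab))])
    meta$n_women[is.na(meta$n_women)] <- 0L
  }
  validate_records(records, meta)
  structure(list(records = records, meta = meta), class = "fert_data")
}

#' @rdname read_records
#' @param data A `fert_data` object (or bare records data frame).
#' @param meta_path Destination for the metadata CSV (only used if metadata
#'   is present).
#' @details `write_records()` is the exact inverse of `read_records()`:
#'   writing then re-reading reproduces the table cell for cell.
#' @export
write_records <- function(data, path, meta_path = NULL) {
  records <- if (inherits(data, "fert_data")) data$records else data
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  if (inherits(data, "fert_data") && !is.null(data$meta) && !is.null(meta_path)) {
    m <- data$meta
    m$n_women <- NULL
    utils::write.csv(m, meta_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
  }
  invisible(path)
}

#' @export
print.fert_data <- function(x, ...) {
  r <- x$records
  cat("Reproductive-history dataset:", nrow(r), "women,",
      length(unique(r$population_id)), "populations\n")
  cat("  parity: mean", round(mean(r$live_births), 2),
      " range", paste(range(r$live_births), collapse = "-"), "\n")
  preds <- setdiff(names(r), c("woman_id", "population_id", "age",
                               "live_births", "birth_year"))
  if (length(preds)) cat("  predictor columns:", paste(preds, collapse = ", "), "\n")
  invisible(x)
}

#' Standardize predictors within population
#'
#' Applies each predictor's declared transform and adds a `<name>_z` column.
#' Continuous predictors become z-scores within population (sample SD,
#' denominator n - 1), so effects compare relative variation within sites;
#' `log1p_zscore` predictors are log(x + 1)-transformed first; binary
#' predictors are copied unchanged. Populations where a predictor has fewer
#' than two non-missing values, or zero variance, get `NA` z-scores for that
#' predictor and a warning — they drop out of that predictor's model subset.
#'
#' @param data `fert_data` object or records data frame.
#' @param specs List of [predictor_spec()]; defaults to every spec in
#'   [default_predictor_specs()] whose column is present.
#' @return The input with `<name>_z` columns added.
#' @export
standardize_predictors <- function(data, specs = NULL) {
  records <- if (inherits(data, "fert_data")) data$records else data
  if (is.null(specs)) {
    specs <- Filter(function(s) s$name %in% names(records),
                    default_predictor_specs())
  }
  if (inherits(specs, "predictor_spec")) specs <- list(specs)
  for (sp in specs) {
    if (!sp$name %in% names(records)) {
      stop("predictor column not found: ", sp$name)
    }
    raw <- records[[sp$name]]
    zcol <- paste0(sp$name, "_z")
    if (sp$transform == "binary") {
      records[[zcol]] <- raw
      next
    }
    x <- if (sp$transform == "log1p_zscore") log1p(raw) else raw
    z <- rep(NA_real_, length(x))
    for (pop in unique(records$population_id)) {
      idx <- which(records$population_id == pop & !is.na(x))
      if (length(idx) < 2L) {
        if (length(idx) > 0L) {
          warning("predictor '", sp$name, "': population '", pop,
                  "' has < 2 non-missing values; dropped from this model")
        }
        next
      }
      s <- stats::sd(x[idx])
      if (s == 0) {
        warning("predictor '", sp$name, "': zero variance in population '",
                pop, "'; dropped from this model")
        next
      }
      z[idx] <- (x[idx] - mean(x[idx])) / s
    }
    records[[zcol]] <- z
  }
  if (inherits(data, "fert_data")) {
    data$records <- records
    data
  } else {
    records
  }
}

#' Build the analysis subset for one predictor model
#'
#' The sample varies by model: each predictor is only available for a subset
#' of populations, and women with a missing value are list-wise dropped for
#' that model only (no imputation). Returns the retained records together
#' with per-population counts and reporting facets (subsistence type,
#' market-integration level).
#'
#' @param data `fert_data` (standardized) or records data frame.
#' @param predictor Raw predictor name; its `<name>_z` column must exist
#'   (run [standardize_predictors()] first).
#' @return List of class `model_dataset`: `records` (complete cases on the
#'   predictor), `predictor`, `zcol`, `pop_n` (named per-population counts),
#'   `meta` (metadata rows for retained populations, or `NULL`).
#' @export
build_model_subset <- function(data, predictor) {
  records <- if (inherits(data, "fert_data")) data$records else data
  meta <- if (inherits(data, "fert_data")) data$meta else NULL
  zcol <- paste0(predictor, "_z")
  if (!zcol %in% names(records)) {
    stop("no standardized column '", zcol, "'; run standardize_predictors() first")
  }
  keep <- !is.na(records[[zcol]])
  if (!any(keep)) stop("no populations provide predictor '", predictor, "'")
  sub <- records[keep, , drop = FALSE]
  dropped <- setdiff(unique(records$population_id), unique(sub$population_id))
  if (length(dropped)) {
    message("predictor '", predictor, "': dropped population(s) with no data: ",
            paste(dropped, collapse = ", "))
  }
  pop_n <- table(sub$population_id)
  if (!is.null(meta)) meta <- meta[meta$population_id %in% names(pop_n), , drop = FALSE]
  structure(list(records = sub, predictor = predictor, zcol = zcol,
                 pop_n = c(pop_n), meta = meta),
            class = "model_dataset")
}

#' @export
print.model_dataset <- function(x, ...) {
  cat("Model subset for predictor '", x$predictor, "': ",
      nrow(x$records), " women in ", length(x$pop_n), " populations\n", sep = "")
  invisible(x)
}
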