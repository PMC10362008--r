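#' Construct a raw battery
#'
#' A raw battery holds an N x D matrix of raw (pre-standardization) scores,
#' a parallel logical mask that is `TRUE` where a value was observed, the
#' participant identifiers, and the measure schema. Masked cells carry no
#' information: the value matrix holds `NA` wherever the mask is `FALSE`.
#'
#' @param values Numeric N x D matrix; `NA` marks missing cells.
#' @param participant_ids Character vector of length N.
#' @param schema A [measure_schema] with D rows, in column order.
#' @param mask Optional logical N x D matrix (`TRUE` = observed). Defaults to
#'   `!is.na(values)`. Cells masked `FALSE` are forced to `NA`.
#' @return An object of class `raw_battery`.
#' @export
raw_battery <- function(values, participant_ids, schema, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(values), dim(mask))) {
    stop("values and mask must have identical dimensions", call. = FALSE)
  }
  if (!inherits(schema, "measure_schema")) schema <- measure_schema(schema)
  if (ncol(values) != nrow(schema)) {
    stop("battery has ", ncol(values), " columns but schema describes ",
         nrow(schema), " measures", call. = FALSE)
  }
  if (length(participant_ids) != nrow(values)) {
    stop("participant_ids length does not match row count", call. = FALSE)
  }
  values[!mask] <- NA_real_
  if (anyNA(values[mask])) {
    stop("mask marks cells observed that hold NA values", call. = FALSE)
  }
  dimnames(values) <- list(NULL, schema$measure_id)
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask,
                 participant_ids = as.character(participant_ids),
                 schema = schema),
            class = c("raw_battery", "ncog_battery"))
}

#' Load a raw battery from a delimited text file
#'
#' Reads a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with one header row, a
#' participant-id column, and one column per schema measure. Empty cells are
#' treated as missing. Columns are reordered to schema order regardless of
#' their order in the file.
#'
#' @param path Path to the delimited file.
#' @param schema A [measure_schema].
#' @param id_col Name of the participant-id column. Default
#'   `"participant_id"`.
#' @return A [raw_battery].
#' @export
load_battery <- function(path, schema, id_col = "participant_id") {
  if (!inherits(schema, "measure_schema")) schema <- measure_schema(schema)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), strip.white = TRUE)
  if (!id_col %in% names(df)) {
    stop("file is missing the participant-id column '", id_col, "'",
         call. = FALSE)
  }
  missing_measures <- setdiff(schema$measure_id, names(df))
  if (length(missing_measures) > 0) {
    stop("file is missing schema measure(s): ",
         paste(missing_measures, collapse = ", "), call. = FALSE)
  }
  ids <- df[[id_col]]
  n <- nrow(df)
  d <- nrow(schema)
  values <- matrix(NA_real_, n, d, dimnames = list(NULL, schema$measure_id))
  for (j in seq_len(d)) {
    col <- schema$measure_id[j]
    raw <- df[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[bad[1]], bad[1], col), call. = FALSE)
    }
    values[, j] <- parsed
  }
  raw_battery(values, ids, schema)
}

#' Apply score-direction conventions
#'
#' Negates every column whose schema entry has `reverse_score = TRUE`, so
#' that higher values reflect better performance on every measure. The
#' operation is an involution: applying it twice restores the input.
#'
#' @param battery A [raw_battery].
#' @return A [raw_battery] with reverse-scored columns negated.
#' @export
apply_direction_conventions <- function(battery) {
  stopifnot(inherits(battery, "raw_battery"))
  rev_cols <- which(battery$schema$reverse_score)
  if (length(rev_cols) > 0) {
    battery$values[, rev_cols] <- -battery$values[, rev_cols]
  }
  battery
}

#' Mask implausible finger-tapping scores
#'
#' Finger-tapping sum scores below `lower` or above `upper` taps most likely
#' reflect recording faults rather than performance; such cells are replaced
#' as missing (masked). Boundary values equal to `lower` or `upper` are
#' retained. The number of replaced cells is recorded in the
#' `"n_replaced"` attribute and reported via `message()`.
#'
#' @param battery A [raw_battery].
#' @param measure_id Identifier of the finger-tapping measure. Default
#'   `"cnb_finger_tapping"`.
#' @param lower,upper Retained range (inclusive). Defaults 10 and 151.
#' @return A [raw_battery] with out-of-range tapping cells masked.
#' @export
finger_tapping_filter <- function(battery, measure_id = "cnb_finger_tapping",
                                  lower = 10, upper = 151) {
  stopifnot(inherits(battery, "raw_battery"))
  if (!measure_id %in% battery$schema$measure_id) {
    stop("schema has no measure '", measure_id, "'", call. = FALSE)
  }
  j <- match(measure_id, battery$schema$measure_id)
  v <- battery$values[, j]
  drop <- battery$mask[, j] & !is.na(v) & (v < lower | v > upper)
  n_replaced <- sum(drop)
  if (n_replaced > 0) {
    battery$values[drop, j] <- NA_real_
    battery$mask[drop, j] <- FALSE
  }
  message(sprintf("finger_tapping_filter: %d cell(s) outside [%g, %g] masked",
                  n_replaced, lower, upper))
  attr(battery, "n_replaced") <- n_replaced
  battery
}

#' Standardize battery columns to z-scores
#'
#' Each column is transformed as (x - mean) / sd, with mean and sample
#' standard deviation (denominator n - 1) computed over unmasked cells only.
#' The mask is preserved. Column means and SDs used are attached as the
#' `"scaling"` attribute (a data frame) for audit.
#'
#' @param battery A [raw_battery].
#' @return An object of class `standardized_battery`, structured like a
#'   [raw_battery] but holding z-scores.
#' @export
zscore_columns <- function(battery) {
  stopifnot(inherits(battery, "raw_battery"))
  values <- battery$values
  mask <- battery$mask
  d <- ncol(values)
  mu <- sd_ <- numeric(d)
  for (j in seq_len(d)) {
    obs <- values[mask[, j], j]
    if (length(obs) < 2) {
      stop("insufficient data: measure '", battery$schema$measure_id[j],
           "' has fewer than 2 observed cells", call. = FALSE)
    }
    mu[j] <- mean(obs)
    sd_[j] <- stats::sd(obs)
    if (sd_[j] == 0) {
      stop("degenerate column: measure '", battery$schema$measure_id[j],
           "' has zero variance", call. = FALSE)
    }
    values[, j] <- (values[, j] - mu[j]) / sd_[j]
  }
  values[!mask] <- NA_real_
  out <- structure(list(values = values, mask = mask,
                        participant_ids = battery$participant_ids,
                        schema = battery$schema),
                   class = c("standardized_battery", "ncog_battery"))
  attr(out, "scaling") <- data.frame(measure_id = battery$schema$measure_id,
                                     mean = mu, sd = sd_,
                                     stringsAsFactors = FALSE)
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: direction conventions (reverse scoring), the
#' finger-tapping plausibility filter (if the schema contains the measure),
#' and column z-scoring. Filtering precedes standardization so that
#' implausible values do not contaminate column means and SDs.
#'
#' @param battery A [raw_battery].
#' @param tapping_measure Identifier of the finger-tapping measure, or `NULL`
#'   to skip the filter. Skipped silently when absent from the schema.
#' @return A `standardized_battery`.
#' @export
preprocess_battery <- function(battery, tapping_measure = "cnb_finger_tapping") {
  b <- apply_direction_conventions(battery)
  if (!is.null(tapping_measure) &&
      tapping_measure %in% b$schema$measure_id) {
    b <- finger_tapping_filter(b, tapping_measure)
  }
  zscore_columns(b)
}

#' Write a standardized battery to CSV with an audit sidecar
#'
#' @param battery A `standardized_battery`.
#' @param path Output CSV path.
#' @param sidecar_path Optional path for a JSON sidecar recording the column
#'   means and SDs used in standardization. Default: `path` with a
#'   `.scaling.json` suffix.
#' @return Invisibly, the battery.
#' @export
write_battery <- function(battery, path,
                          sidecar_path = sub("\\.csv$", ".scaling.json", path)) {
  stopifnot(inherits(battery, "ncog_battery"))
  df <- data.frame(participant_id = battery$participant_ids,
                   battery$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  scaling <- attr(battery, "scaling")
  if (!is.null(scaling) && !is.null(sidecar_path)) {
    jsonlite::write_json(scaling, sidecar_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(battery)
}

#' @export
print.ncog_battery <- function(x, ...) {
  kind <- if (inherits(x, "standardized_battery")) "standardized" else "raw"
  cat(sprintf("<%s battery> %d participants x %d measures, %.1f%% missing\n",
              kind, nrow(x$values), ncol(x$values), 100 * mean(!x$mask)))
  invisible(x)
}
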