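# Soil-survey sample tables: column contract, validation, CSV/GeoJSON I/O.

.continuous_predictors <- c(
  "latitude", "longitude", "organic_matter", "doc", "ph",
  "free_fe", "amorphous_fe", "free_mn", "amorphous_mn", "cec",
  "sand_pct", "clay_pct", "silt_pct"
)
.categorical_predictors <- c("pollution_type", "crop")
.optional_columns <- c("parent_material", "cd", "pb")
.nonnegative_columns <- c(
  "organic_matter", "doc", "free_fe", "amorphous_fe",
  "free_mn", "amorphous_mn", "cec", "sand_pct", "clay_pct", "silt_pct",
  "cd", "pb"
)

#' Predictor columns of a soil-survey table
#'
#' The fifteen predictors used for heavy-metal regression: geographic
#' position (latitude, longitude), pollution type, crop grown, eight soil
#' chemical properties (organic matter g/kg, DOC mg/kg, pH, free and
#' amorphous Fe g/kg, free and amorphous Mn mg/kg, CEC cmol/kg) and the
#' sand/clay/silt texture percentages.
#'
#' @return Character vector of the 15 column names, in canonical order.
#' @export
predictor_columns <- function() {
  c("latitude", "longitude", "pollution_type", "crop",
    "organic_matter", "doc", "ph", "free_fe", "amorphous_fe",
    "free_mn", "amorphous_mn", "cec", "sand_pct", "clay_pct", "silt_pct")
}

required_columns <- function() c("sample_id", predictor_columns())

#' Validate a soil-survey sample table
#'
#' Checks the column contract (sample_id plus the 15 predictors of
#' [predictor_columns()]; `parent_material`, `cd`, `pb` optional) and the
#' row invariants: latitude in \[-90, 90\], longitude in \[-180, 180\],
#' non-negative concentrations and CEC, texture percentages summing to
#' 100 +/- 1, finite predictor values, unique sample ids.
#'
#' @param table A data.frame.
#' @param strict If `TRUE` (default) any invalid row is an error; if
#'   `FALSE` invalid rows are dropped with a warning giving the count.
#' @return The validated table with class `sample_table`. In lenient mode
#'   the attribute `"n_dropped"` records how many rows were removed.
#' @export
validate_sample_table <- function(table, strict = TRUE) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(required_columns(), names(table))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  table$sample_id <- as.character(table$sample_id)
  for (col in .categorical_predictors) table[[col]] <- as.character(table[[col]])
  for (col in intersect(c(.continuous_predictors, "cd", "pb"), names(table))) {
    if (!is.numeric(table[[col]])) {
      stop("column '", col, "' must be numeric")
    }
  }
  if (anyDuplicated(table$sample_id)) {
    stop("duplicate sample_id values: ",
         paste(unique(table$sample_id[duplicated(table$sample_id)]), collapse = ", "))
  }

  bad <- rep(FALSE, nrow(table))
  bad <- bad | !is.finite(table$latitude) | table$latitude < -90 | table$latitude > 90
  bad <- bad | !is.finite(table$longitude) | table$longitude < -180 | table$longitude > 180
  for (col in .continuous_predictors) {
    bad <- bad | !is.finite(table[[col]])
  }
  for (col in intersect(.nonnegative_columns, names(table))) {
    v <- table[[col]]
    bad <- bad | (is.finite(v) & v < 0)
  }
  tex <- table$sand_pct + table$clay_pct + table$silt_pct
  bad <- bad | (is.finite(tex) & abs(tex - 100) > 1)

  if (any(bad)) {
    if (strict) {
      stop("invalid row(s): ", paste(which(bad), collapse = ", "),
           " (coordinate range, negative concentration, or texture sum)")
    }
    warning(sum(bad), " invalid row(s) dropped")
    table <- table[!bad, , drop = FALSE]
    rownames(table) <- NULL
  }
  class(table) <- unique(c("sample_table", class(table)))
  attr(table, "n_dropped") <- if (strict) 0L else sum(bad)
  table
}

#' Read a soil-survey table from CSV
#'
#' Expects a UTF-8 CSV with a header row carrying the exact column names of
#' the sample-table contract (see [validate_sample_table()]).
#'
#' @param path Path to the CSV file.
#' @param strict Passed to [validate_sample_table()]. Unparsable numeric
#'   fields are an error in strict mode (reported with their file line
#'   number) and drop the row in lenient mode.
#' @return A validated `sample_table`.
#' @export
read_sample_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  numeric_cols <- intersect(c(.continuous_predictors, "cd", "pb"), names(raw))
  unparsable <- rep(FALSE, nrow(raw))
  for (col in numeric_cols) {
    txt <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- is.na(val) & !(txt %in% c("", "NA"))
    if (any(bad)) {
      if (strict) {
        stop("unparsable value in column '", col, "' at file line(s) ",
             paste(which(bad) + 1L, collapse = ", "))
      }
      unparsable <- unparsable | bad
    }
    raw[[col]] <- val
  }
  if (any(unparsable)) {
    warning(sum(unparsable), " row(s) with unparsable numeric fields dropped")
    raw <- raw[!unparsable, , drop = FALSE]
  }
  validate_sample_table(raw, strict = strict)
}

#' Write a soil-survey table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every double exactly.
#'
#' @param table A `sample_table` (or coercible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  table <- validate_sample_table(as.data.frame(table), strict = TRUE)
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      txt <- sprintf("%.17g", out[[col]])
      txt[is.na(out[[col]])] <- "NA"
      out[[col]] <- txt
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Export sampling sites as GeoJSON points
#'
#' @param table A `sample_table`.
#' @param path Output path for the GeoJSON document.
#' @return `path`, invisibly.
#' @export
export_sites_geojson <- function(table, path) {
  table <- validate_sample_table(as.data.frame(table), strict = TRUE)
  features <- lapply(seq_len(nrow(table)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        # GeoJSON coordinate order is [longitude, latitude]
        coordinates = c(table$longitude[i], table$latitude[i])
      ),
      properties = list(sample_id = table$sample_id[i])
    )
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.sample_table <- function(x, ...) {
  cat("Soil-survey sample table:", nrow(x), "sites\n")
  has <- intersect(c("parent_material", "cd", "pb"), names(x))
  if (length(has)) cat("Optional columns present:", paste(has, collapse = ", "), "\n")
  NextMethod()
}
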