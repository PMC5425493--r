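# Domain containers: a water-source dataset is a pair of data frames
# (one row per source; one row per analytical result) plus the rejected
# input rows.  Kept as plain data frames so every downstream step is an
# ordinary split/apply.

ANALYTES <- c("arsenic", "uranium")
UNITS <- c("ug_per_L", "pCi_per_L")

#' Column-mapping dialect for survey CSV files
#'
#' Surveys arrive in heterogeneous layouts; a dialect maps the canonical
#' field names onto the column names actually present in a file.  Fields
#' mapped to `NA` are treated as absent and filled with defaults
#' (`sample_date` empty, `method_documented` TRUE, `source_type` empty).
#'
#' @param source_id,lat,lon,region,source_type,analyte,value,censored,
#'   reporting_limit,units,survey_id,sample_date,method_documented Column
#'   names in the input file holding each canonical field.
#' @return A named character vector of class `uws_dialect`.
#' @export
uws_dialect <- function(source_id = "source_id", lat = "lat", lon = "lon",
                        region = "region", source_type = "source_type",
                        analyte = "analyte", value = "value",
                        censored = "censored",
                        reporting_limit = "reporting_limit",
                        units = "units", survey_id = "survey_id",
                        sample_date = "sample_date",
                        method_documented = "method_documented") {
  structure(c(source_id = source_id, lat = lat, lon = lon, region = region,
              source_type = source_type, analyte = analyte, value = value,
              censored = censored, reporting_limit = reporting_limit,
              units = units, survey_id = survey_id,
              sample_date = sample_date,
              method_documented = method_documented),
            class = "uws_dialect")
}

REQUIRED_FIELDS <- c("source_id", "lat", "lon", "region", "analyte",
                     "value", "censored", "reporting_limit", "units",
                     "survey_id")

as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

# Row-level validation of one measurement row (already canonicalised).
# Returns NA_character_ if valid, else a reason code.
validate_measurement_row <- function(row) {
  if (!(row$analyte %in% ANALYTES)) return("unknown_analyte")
  if (!(row$units %in% UNITS)) return("unknown_units")
  if (row$units == "pCi_per_L" && row$analyte != "uranium")
    return("activity_units_for_arsenic")
  if (isTRUE(row$censored)) {
    if (is.na(row$reporting_limit) || row$reporting_limit <= 0)
      return("censored_without_limit")
    if (!is.na(row$value)) return("censored_with_value")
  } else {
    if (is.na(row$value) || row$value < 0) return("missing_or_negative_value")
  }
  NA_character_
}

#' Read water-source records from a survey CSV file
#'
#' Reads a flat CSV with one row per analytical result, groups rows by
#' source, and validates every row against the measurement invariants
#' (a censored result must carry a positive reporting limit and no value;
#' a detected result must carry a non-negative value; activity units are
#' only valid for uranium; coordinates must parse and lie in range).
#' Invalid rows are collected with per-row reason codes rather than
#' aborting the read.
#'
#' @param path Path to the CSV file (UTF-8, header row).
#' @param dialect A [uws_dialect()] mapping canonical fields to columns.
#' @return An object of class `uws_data`: a list with elements
#'   `sources` (one row per distinct source: source_id, lat, lon, region,
#'   source_type), `measurements` (one row per accepted result), and
#'   `rejected` (row number, source_id and reason for each rejected row).
#' @export
read_sources <- function(path, dialect = uws_dialect()) {
  if (!file.exists(path)) stop("sources file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required_cols <- unname(dialect[REQUIRED_FIELDS])
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("input file has a header but no data rows: ", path)
    return(empty_uws_data())
  }

  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.na(col) && col %in% names(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  m <- data.frame(
    source_id = trimws(get_col("source_id")),
    lat = suppressWarnings(as.numeric(get_col("lat"))),
    lon = suppressWarnings(as.numeric(get_col("lon"))),
    region = get_col("region"),
    source_type = get_col("source_type", ""),
    analyte = tolower(trimws(get_col("analyte"))),
    value = suppressWarnings(as.numeric(get_col("value"))),
    censored = as_logical_flag(get_col("censored", "false")),
    reporting_limit = suppressWarnings(
      as.numeric(get_col("reporting_limit"))),
    units = get_col("units"),
    survey_id = get_col("survey_id"),
    sample_date = get_col("sample_date", ""),
    method_documented = as_logical_flag(get_col("method_documented", "true")),
    stringsAsFactors = FALSE
  )

  reasons <- character(nrow(m))
  bad_coord <- is.na(m$lat) | is.na(m$lon) |
    m$lat < -90 | m$lat > 90 | m$lon < -180 | m$lon > 180
  reasons[bad_coord] <- "unparseable_or_out_of_range_coordinates"
  for (i in which(!bad_coord)) {
    r <- validate_measurement_row(m[i, ])
    if (!is.na(r)) reasons[i] <- r
  }
  ok <- !nzchar(reasons)
  rejected <- data.frame(row = which(!ok),
                         source_id = m$source_id[!ok],
                         reason = reasons[!ok],
                         stringsAsFactors = FALSE)
  meas <- m[ok, , drop = FALSE]
  rownames(meas) <- NULL

  # one SourceRecord per distinct id; coordinates/region from first row
  first <- meas[!duplicated(meas$source_id), , drop = FALSE]
  dup_coord <- tapply(meas$lat, meas$source_id,
                      function(z) length(unique(z)) > 1L)
  if (any(unlist(dup_coord)))
    warning("source(s) with conflicting coordinates; first row used: ",
            paste(names(dup_coord)[unlist(dup_coord)], collapse = ", "))
  sources <- data.frame(source_id = first$source_id, lat = first$lat,
                        lon = first$lon, region = first$region,
                        source_type = first$source_type,
                        stringsAsFactors = FALSE)
  rownames(sources) <- NULL
  structure(list(sources = sources,
                 measurements = meas[, c("source_id", "analyte", "value",
                                         "censored", "reporting_limit",
                                         "units", "survey_id", "sample_date",
                                         "method_documented")],
                 rejected = rejected),
            class = "uws_data")
}

empty_uws_data <- function() {
  structure(list(
    sources = data.frame(source_id = character(), lat = numeric(),
                         lon = numeric(), region = character(),
                         source_type = character(), stringsAsFactors = FALSE),
    measurements = data.frame(source_id = character(), analyte = character(),
                              value = numeric(), censored = logical(),
                              reporting_limit = numeric(), units = character(),
                              survey_id = character(),
                              sample_date = character(),
                              method_documented = logical(),
                              stringsAsFactors = FALSE),
    rejected = data.frame(row = integer(), source_id = character(),
                          reason = character(), stringsAsFactors = FALSE)),
    class = "uws_data")
}

#' @export
print.uws_data <- function(x, ...) {
  cat(sprintf("uws_data: %d sources, %d measurements (%d rejected rows)\n",
              nrow(x$sources), nrow(x$measurements), nrow(x$rejected)))
  invisible(x)
}

#' Write a `uws_data` object back to the flat CSV layout
#'
#' Emits one row per measurement with the source columns repeated, in the
#' canonical dialect, so that `read_sources()` on the output reproduces
#' the object (sources with at least one measurement round-trip exactly).
#'
#' @param data A `uws_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sources_csv <- function(data, path) {
  stopifnot(inherits(data, "uws_data"))
  src <- data$sources[match(data$measurements$source_id,
                            data$sources$source_id), , drop = FALSE]
  out <- cbind(data$measurements["source_id"],
               src[, c("lat", "lon", "region", "source_type")],
               data$measurements[, setdiff(names(data$measurements),
                                           "source_id")])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read abandoned-mine locations
#'
#' @param path CSV with columns `mine_id`, `lat`, `lon`.
#' @return Data frame of validated mine sites.
#' @export
read_mines <- function(path) {
  if (!file.exists(path)) stop("mines file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("mine_id", "lat", "lon"), names(raw))
  if (length(missing) > 0L)
    stop("missing required column(s) in mines file: ",
         paste(missing, collapse = ", "))
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  bad <- is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
    lon < -180 | lon > 180
  if (any(bad))
    warning(sum(bad), " mine row(s) with invalid coordinates dropped")
  data.frame(mine_id = as.character(raw$mine_id)[!bad],
             lat = lat[!bad], lon = lon[!bad], stringsAsFactors = FALSE)
}

#' Export per-source summaries as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection of Point features, one per source,
#' with the per-analyte analysis value (observed or reporting limit),
#' censoring flags and MCL exceedance booleans as properties.  GeoJSON
#' coordinate order is `[longitude, latitude]`.
#'
#' @param sources Data frame with `source_id`, `lat`, `lon`, `region`.
#' @param summaries Data frame keyed by `source_id` with columns
#'   `as_value`, `as_censored`, `u_value`, `u_censored`, `exceeds_as`,
#'   `exceeds_u` (missing analytes as `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(sources, summaries, path) {
  stopifnot(all(c("source_id", "lat", "lon") %in% names(sources)))
  idx <- match(sources$source_id, summaries$source_id)
  features <- lapply(seq_len(nrow(sources)), function(i) {
    j <- idx[i]
    prop <- list(source_id = sources$source_id[i],
                 region = if ("region" %in% names(sources))
                   sources$region[i] else NULL)
    for (col in c("as_value", "as_censored", "u_value", "u_censored",
                  "exceeds_as", "exceeds_u")) {
      v <- if (!is.na(j) && col %in% names(summaries))
        summaries[[col]][j] else NA
      prop[[col]] <- if (is.na(v)) NULL else v
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sources$lon[i], sources$lat[i])),
         properties = prop[!vapply(prop, is.null, TRUE)])
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
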