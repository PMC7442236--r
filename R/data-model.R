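#' @title Data model for the three observation streams
#' @description
#' The model consumes three tabular streams, mirroring how stage-structured
#' amphibian populations are monitored in the field:
#' \itemize{
#'   \item larvae: cross-sectional dipnet measurements of known age, with
#'     age 0 anchored at the pond-fill date of the breeding wetland;
#'   \item metamorphs: lengths of individuals caught emigrating from the
#'     wetland, whose age at metamorphosis is latent;
#'   \item adults: mark-recapture capture histories of unknown-age
#'     terrestrial individuals, one length per capture occasion.
#' }
#' All dates are calendar dates (ISO-8601 in CSV files); elapsed times are
#' converted to years with a fixed 365.25-day year.
#' @name data_model
NULL

#' Days per year for all date-to-years conversions
#' @export
DAYS_PER_YEAR <- 365.25

.parse_date <- function(x, what, rows) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) | is.na(x)
  if (any(bad)) {
    stop("unparsable ", what, " in row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  }
  d
}

.parse_num <- function(x, what, rows) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v)
  if (any(bad)) {
    stop("unparsable ", what, " in row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  }
  v
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read larval records from CSV
#'
#' Expects columns `wetland_id, capture_date, pond_fill_date, svl_mm`.
#' Ages in years are derived as
#' `(capture_date - pond_fill_date) / 365.25`, using the pond-fill date as
#' the hatch reference (age 0).
#'
#' @param path Path to a CSV file.
#' @return A data frame with one row per larval record and an added
#'   `age_years` column.
#' @export
read_larval_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .require_cols(df, c("wetland_id", "capture_date", "pond_fill_date",
                      "svl_mm"), path)
  if (nrow(df) == 0) return(empty_larvae())
  rows <- seq_len(nrow(df)) + 1L  # +1 for the header line
  out <- data.frame(
    wetland_id = df$wetland_id,
    capture_date = .parse_date(df$capture_date, "capture_date", rows),
    pond_fill_date = .parse_date(df$pond_fill_date, "pond_fill_date", rows),
    svl_mm = .parse_num(df$svl_mm, "svl_mm", rows),
    stringsAsFactors = FALSE
  )
  out$age_years <- as.numeric(out$capture_date - out$pond_fill_date) /
    DAYS_PER_YEAR
  bad_svl <- out$svl_mm <= 0
  if (any(bad_svl)) {
    stop("svl_mm must be positive; violated in row(s) ",
         paste(rows[bad_svl], collapse = ", "), call. = FALSE)
  }
  bad_age <- out$age_years <= 0 | out$age_years > 2
  if (any(bad_age)) {
    stop("age_years must lie in (0, 2]; violated in row(s) ",
         paste(rows[bad_age], collapse = ", "), call. = FALSE)
  }
  out
}

empty_larvae <- function() {
  data.frame(wetland_id = character(), capture_date = as.Date(character()),
             pond_fill_date = as.Date(character()), svl_mm = numeric(),
             age_years = numeric(), stringsAsFactors = FALSE)
}

#' Read metamorph records from CSV
#'
#' Expects columns `wetland_id, cohort_year, svl_mm`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with one row per metamorph record.
#' @export
read_metamorph_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .require_cols(df, c("wetland_id", "cohort_year", "svl_mm"), path)
  if (nrow(df) == 0) return(empty_metamorphs())
  rows <- seq_len(nrow(df)) + 1L
  out <- data.frame(
    wetland_id = df$wetland_id,
    cohort_year = as.integer(.parse_num(df$cohort_year, "cohort_year", rows)),
    svl_mm = .parse_num(df$svl_mm, "svl_mm", rows),
    stringsAsFactors = FALSE
  )
  bad <- out$svl_mm <= 0
  if (any(bad)) {
    stop("svl_mm must be positive; violated in row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  }
  out
}

empty_metamorphs <- function() {
  data.frame(wetland_id = character(), cohort_year = integer(),
             svl_mm = numeric(), stringsAsFactors = FALSE)
}

#' Construct an adult capture history
#'
#' @param individual_id Unique identifier of the marked individual.
#' @param first_capture_date Calendar date of the first capture.
#' @param time_offset_years Numeric vector of elapsed times (years) since
#'   first capture; the first element must be exactly 0 and offsets must be
#'   strictly increasing.
#' @param svl_mm Positive lengths (mm), one per occasion.
#' @return An object of class `capture_history`.
#' @export
capture_history <- function(individual_id, first_capture_date,
                            time_offset_years, svl_mm) {
  stopifnot(length(time_offset_years) == length(svl_mm),
            length(svl_mm) >= 1)
  if (time_offset_years[1] != 0) {
    stop("first occasion must have offset 0", call. = FALSE)
  }
  if (length(time_offset_years) > 1 &&
      any(diff(time_offset_years) <= 0)) {
    stop("occasion offsets must be strictly increasing", call. = FALSE)
  }
  if (any(svl_mm <= 0)) stop("svl_mm must be positive", call. = FALSE)
  structure(
    list(individual_id = as.character(individual_id),
         first_capture_date = as.Date(first_capture_date),
         time_offset_years = as.numeric(time_offset_years),
         svl_mm = as.numeric(svl_mm)),
    class = "capture_history"
  )
}

#' Read adult capture histories from a long-format CSV
#'
#' Expects columns `individual_id, capture_date, svl_mm`, one row per
#' capture occasion; rows may appear in any order. Rows are grouped by
#' individual, sorted by date, and converted to per-individual time offsets
#' in years from the first capture. Duplicate same-day captures of one
#' individual are rejected.
#'
#' @param path Path to a CSV file.
#' @return A list of `capture_history` objects, ordered by individual id.
#' @export
read_adult_captures_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .require_cols(df, c("individual_id", "capture_date", "svl_mm"), path)
  if (nrow(df) == 0) return(list())
  rows <- seq_len(nrow(df)) + 1L
  df$capture_date <- .parse_date(df$capture_date, "capture_date", rows)
  df$svl_mm <- .parse_num(df$svl_mm, "svl_mm", rows)
  bad <- df$svl_mm <= 0
  if (any(bad)) {
    stop("svl_mm must be positive; violated in row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("individual_id", "capture_date")])
  if (any(dup)) {
    stop("duplicate same-day capture(s) in row(s) ",
         paste(rows[dup], collapse = ", "), call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(df)), df$individual_id)
  lapply(split_idx, function(idx) {
    sub <- df[idx[order(df$capture_date[idx])], ]
    offsets <- as.numeric(sub$capture_date - sub$capture_date[1]) /
      DAYS_PER_YEAR
    capture_history(sub$individual_id[1], sub$capture_date[1],
                    offsets, sub$svl_mm)
  })
}

#' Bundle the three streams into a dataset
#'
#' @param larvae Data frame of larval records (see [read_larval_csv()]).
#' @param metamorphs Data frame of metamorph records.
#' @param adults List of `capture_history` objects.
#' @return An object of class `growth_dataset`.
#' @export
growth_dataset <- function(larvae = empty_larvae(),
                           metamorphs = empty_metamorphs(),
                           adults = list()) {
  stopifnot(is.data.frame(larvae), is.data.frame(metamorphs),
            is.list(adults))
  if (length(adults) > 0) {
    stopifnot(all(vapply(adults, inherits, logical(1), "capture_history")))
    ids <- vapply(adults, `[[`, character(1), "individual_id")
    if (anyDuplicated(ids)) {
      stop("duplicate individual_id among adult histories", call. = FALSE)
    }
  }
  structure(list(larvae = larvae, metamorphs = metamorphs, adults = adults),
            class = "growth_dataset")
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat("<growth_dataset>\n")
  cat("  larvae:     ", nrow(x$larvae), "records\n")
  cat("  metamorphs: ", nrow(x$metamorphs), "records\n")
  cat("  adults:     ", length(x$adults), "capture histories\n")
  invisible(x)
}

.stream_summary <- function(svl) {
  if (length(svl) == 0) {
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_))
  }
  list(min = min(svl), max = max(svl), mean = mean(svl))
}

#' Validate a dataset and summarise its streams
#'
#' Report-only: counts per stream (including the number of adults with at
#' least one recapture), min/max/mean SVL per stream, and any invariant
#' violations found. Never throws.
#'
#' @param ds A `growth_dataset`.
#' @return A list with elements `counts`, `svl_summary`, `violations`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "growth_dataset"))
  violations <- character()
  if (nrow(ds$larvae) > 0) {
    if (any(ds$larvae$svl_mm <= 0)) {
      violations <- c(violations, "larvae: non-positive svl_mm")
    }
    if (any(ds$larvae$age_years <= 0 | ds$larvae$age_years > 2)) {
      violations <- c(violations, "larvae: age_years outside (0, 2]")
    }
  }
  if (nrow(ds$metamorphs) > 0 && any(ds$metamorphs$svl_mm <= 0)) {
    violations <- c(violations, "metamorphs: non-positive svl_mm")
  }
  n_occ <- vapply(ds$adults, function(h) length(h$svl_mm), integer(1))
  adult_svl <- unlist(lapply(ds$adults, `[[`, "svl_mm"))
  counts <- list(
    n_larvae = nrow(ds$larvae),
    n_metamorphs = nrow(ds$metamorphs),
    n_adults = length(ds$adults),
    n_adults_recaptured = sum(n_occ >= 2)
  )
  list(
    counts = counts,
    svl_summary = list(
      larvae = .stream_summary(ds$larvae$svl_mm),
      metamorphs = .stream_summary(ds$metamorphs$svl_mm),
      adults = .stream_summary(adult_svl)
    ),
    violations = violations
  )
}

#' Write a validation report to JSON
#'
#' @param report Result of [validate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write the three streams back to CSV
#'
#' Inverse of the readers: writing then reading reproduces every field.
#' Adult histories are flattened to long format by reconstructing calendar
#' dates from the first-capture date and the year offsets.
#'
#' @param ds A `growth_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "growth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(larvae = file.path(dir, "larvae.csv"),
             metamorphs = file.path(dir, "metamorphs.csv"),
             adults = file.path(dir, "adult_captures.csv"))
  larv <- ds$larvae
  larv$capture_date <- format(larv$capture_date, "%Y-%m-%d")
  larv$pond_fill_date <- format(larv$pond_fill_date, "%Y-%m-%d")
  utils::write.csv(
    larv[, c("wetland_id", "capture_date", "pond_fill_date", "svl_mm")],
    paths["larvae"], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$metamorphs, paths["metamorphs"],
                   row.names = FALSE, quote = FALSE)
  adult_rows <- do.call(rbind, lapply(ds$adults, function(h) {
    data.frame(
      individual_id = h$individual_id,
      capture_date = format(
        h$first_capture_date + round(h$time_offset_years * DAYS_PER_YEAR),
        "%Y-%m-%d"),
      svl_mm = h$svl_mm, stringsAsFactors = FALSE)
  }))
  if (is.null(adult_rows)) {
    adult_rows <- data.frame(individual_id = character(),
                             capture_date = character(),
                             svl_mm = numeric())
  }
  utils::write.csv(adult_rows, paths["adults"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
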