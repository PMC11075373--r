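#' Prescription records: loading, validation, writing
#'
#' A prescription record is one dispensing event linking a patient to a
#' hospital for one drug class on one date, with a daily dose in mg and a
#' number of days supplied. Records travel as a data frame with columns
#' `patient_id`, `hospital_id`, `drug`, `date`, `daily_dose_mg`,
#' `days_supplied`.
#'
#' @name narcscreen-records
NULL

RECORD_FIELDS <- c("patient_id", "hospital_id", "drug", "date",
                   "daily_dose_mg", "days_supplied")

#' Default study window
#'
#' Two years of full mandatory electronic reporting, 2019-07-01 to
#' 2021-06-30.
#' @return Vector of two `Date`s (inclusive bounds).
#' @export
default_study_window <- function() {
  as.Date(c("2019-07-01", "2021-06-30"))
}

#' Validate a prescription record data frame
#'
#' Checks field presence, positivity of dose and days supplied, drug class
#' membership, date parseability, and disjointness of the patient and
#' hospital id namespaces. Row-level problems are collected, not thrown.
#'
#' @param df Data frame with the six record columns.
#' @return List with elements `records` (the valid rows, canonical types)
#'   and `errors` (data frame of `row`, `field`, `message` for invalid rows).
#' @export
validate_records <- function(df) {
  missing <- setdiff(RECORD_FIELDS, names(df))
  if (length(missing) > 0) {
    stop("record table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  err_row <- integer(0); err_field <- character(0); err_msg <- character(0)
  note <- function(rows, field, msg) {
    err_row <<- c(err_row, rows)
    err_field <<- c(err_field, rep(field, length(rows)))
    err_msg <<- c(err_msg, rep(msg, length(rows)))
  }

  patient_id <- as.character(df$patient_id)
  hospital_id <- as.character(df$hospital_id)
  drug <- as.character(df$drug)
  date <- suppressWarnings(as.Date(as.character(df$date), format = "%Y-%m-%d"))
  dose <- suppressWarnings(as.numeric(df$daily_dose_mg))
  days <- suppressWarnings(as.numeric(df$days_supplied))

  note(which(is.na(patient_id) | patient_id == ""), "patient_id", "empty patient id")
  note(which(is.na(hospital_id) | hospital_id == ""), "hospital_id", "empty hospital id")
  note(which(!drug %in% drug_classes()), "drug", "unknown drug class")
  note(which(is.na(date)), "date", "unparseable date (expected YYYY-MM-DD)")
  note(which(is.na(dose) | dose <= 0), "daily_dose_mg", "daily dose must be a positive number")
  note(which(is.na(days) | days < 1 | days != floor(days)), "days_supplied",
       "days supplied must be a positive integer")

  clash <- intersect(unique(patient_id[!is.na(patient_id)]),
                     unique(hospital_id[!is.na(hospital_id)]))
  if (length(clash) > 0) {
    stop("patient and hospital id namespaces overlap: ",
         paste(utils::head(clash, 3), collapse = ", "), call. = FALSE)
  }

  bad <- sort(unique(err_row))
  keep <- setdiff(seq_len(n), bad)
  records <- data.frame(
    patient_id = patient_id[keep],
    hospital_id = hospital_id[keep],
    drug = drug[keep],
    date = date[keep],
    daily_dose_mg = dose[keep],
    days_supplied = as.integer(days[keep]),
    stringsAsFactors = FALSE
  )
  errors <- data.frame(row = err_row, field = err_field, message = err_msg,
                       stringsAsFactors = FALSE)
  errors <- errors[order(errors$row), , drop = FALSE]
  rownames(errors) <- NULL
  list(records = records, errors = errors)
}

#' Load prescription records from a delimited text file
#'
#' Reads a UTF-8 header-row file (comma by default, tab supported), maps
#' columns to the canonical record fields, validates every row, and
#' optionally restricts to a study window. Malformed rows are dropped and
#' reported with their line numbers; rows outside the window are dropped
#' with a count, mirroring the extraction step of a monitoring analysis.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping record fields to
#'   file column names, e.g. `c(patient_id = "pid")`. Unmapped fields use
#'   their canonical names.
#' @param sep Field separator, `","` or `"\t"`.
#' @param window `NULL` for no windowing, or two dates (inclusive);
#'   defaults to [default_study_window()].
#' @return List with `records` (validated data frame), `errors` (row-level
#'   validation report), and `n_dropped_window` (count outside the window).
#' @export
load_records <- function(path, schema = NULL, sep = ",",
                         window = default_study_window()) {
  if (!file.exists(path)) stop("record file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  mapping <- stats::setNames(RECORD_FIELDS, RECORD_FIELDS)
  if (!is.null(schema)) mapping[names(schema)] <- unname(schema)
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing) > 0) {
    stop("record file lacks mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- raw[, unname(mapping), drop = FALSE]
  names(df) <- names(mapping)
  out <- validate_records(df)
  out$n_dropped_window <- 0L
  if (!is.null(window)) {
    window <- as.Date(window)
    inside <- out$records$date >= window[1] & out$records$date <= window[2]
    out$n_dropped_window <- sum(!inside)
    out$records <- out$records[inside, , drop = FALSE]
    rownames(out$records) <- NULL
  }
  out
}

#' Write prescription records in the canonical dialect
#'
#' Canonical dialect: comma-separated, header row, ISO dates, no quoting.
#' Loading a written file reproduces the record collection exactly.
#'
#' @param records Validated record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load hospital attributes (size category and region)
#'
#' Sidecar table keyed by hospital id. Unknown size or region codes are an
#' error; hospitals absent from the table are later reported as `UNKNOWN`
#' rather than dropped, because stratification is a reporting layer, not a
#' filter.
#'
#' @param path Delimited text file with columns `hospital_id`,
#'   `size_category`, `region`.
#' @param sep Field separator.
#' @return Data frame with one row per hospital id.
#' @export
load_hospital_attributes <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  need <- c("hospital_id", "size_category", "region")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("attribute file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$hospital_id)) {
    stop("duplicate hospital_id in attribute file", call. = FALSE)
  }
  bad_size <- setdiff(unique(df$size_category), size_categories())
  bad_region <- setdiff(unique(df$region), region_codes())
  if (length(bad_size) > 0) {
    stop("unknown size category code(s): ", paste(bad_size, collapse = ", "),
         call. = FALSE)
  }
  if (length(bad_region) > 0) {
    stop("unknown region code(s): ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' Write hospital attributes
#' @param attributes Data frame from [load_hospital_attributes()] or the
#'   generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hospital_attributes <- function(attributes, path) {
  utils::write.table(attributes[, c("hospital_id", "size_category", "region")],
                     path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Join size/region attributes onto a hospital table
#'
#' @param hospital_ids Character vector of hospital ids.
#' @param attributes Attribute data frame, or `NULL`.
#' @return Data frame `hospital_id`, `size_category`, `region`; hospitals
#'   without an attribute row get `"UNKNOWN"` for both fields.
#' @export
attach_attributes <- function(hospital_ids, attributes = NULL) {
  out <- data.frame(hospital_id = hospital_ids,
                    size_category = "UNKNOWN", region = "UNKNOWN",
                    stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    idx <- match(out$hospital_id, attributes$hospital_id)
    hit <- !is.na(idx)
    out$size_category[hit] <- attributes$size_category[idx[hit]]
    out$region[hit] <- attributes$region[idx[hit]]
  }
  out
}
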