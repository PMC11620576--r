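#' @importFrom stats aggregate
NULL

RECORD_CLASSES <- c("diagnosis_icd10", "drug_mhlw", "procedure_billing")

#' Construct a labeled claims cohort
#'
#' A cohort bundles a patient table (one row per patient, with age and the
#' gold-standard IgAN label obtained from chart review) and a billing-record
#' table (one row per patient x record class x code, with the number of times
#' the code appeared over the whole observation window). Diagnosis codes are
#' stored as presence only (count clamped to 1); drug and procedure codes
#' keep their occurrence counts. Duplicate (patient, class, code) rows are
#' merged by summing counts.
#'
#' @param patients Data frame with columns `patient_id` (unique strings),
#'   `age_years` (non-negative, finite), `label_igan` (logical or 0/1).
#' @param records Data frame with columns `patient_id`, `record_class` (one
#'   of `"diagnosis_icd10"`, `"drug_mhlw"`, `"procedure_billing"`), `code`
#'   (non-empty string), `count` (integer >= 1). May have zero rows.
#' @return An object of class `claims_cohort`.
#' @export
claims_cohort <- function(patients, records) {
  req_p <- c("patient_id", "age_years", "label_igan")
  req_r <- c("patient_id", "record_class", "code", "count")
  if (!all(req_p %in% names(patients))) {
    stop("`patients` must have columns patient_id, age_years, label_igan")
  }
  if (!all(req_r %in% names(records))) {
    stop("`records` must have columns patient_id, record_class, code, count")
  }
  patients <- data.frame(
    patient_id = as.character(patients$patient_id),
    age_years  = as.numeric(patients$age_years),
    label_igan = as.logical(patients$label_igan),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in `patients`: ",
         patients$patient_id[duplicated(patients$patient_id)][1L])
  }
  if (any(!is.finite(patients$age_years)) || any(patients$age_years < 0)) {
    stop("`age_years` must be finite and non-negative")
  }
  if (anyNA(patients$label_igan)) stop("`label_igan` must be TRUE/FALSE or 0/1")

  records <- data.frame(
    patient_id   = as.character(records$patient_id),
    record_class = as.character(records$record_class),
    code         = as.character(records$code),
    count        = as.integer(records$count),
    stringsAsFactors = FALSE
  )
  if (nrow(records) > 0L) {
    bad_class <- !records$record_class %in% RECORD_CLASSES
    if (any(bad_class)) {
      stop("unknown record_class: ", records$record_class[bad_class][1L])
    }
    if (any(!nzchar(records$code))) stop("record codes must be non-empty")
    if (anyNA(records$count) || any(records$count < 1L)) {
      stop("record counts must be integers >= 1")
    }
    unknown <- !records$patient_id %in% patients$patient_id
    if (any(unknown)) {
      stop(sprintf("referential-integrity error: record for unknown patient '%s'",
                   records$patient_id[unknown][1L]))
    }
    key <- paste(records$patient_id, records$record_class, records$code,
                 sep = "\r")
    if (anyDuplicated(key)) {
      counts <- rowsum(records$count, key, reorder = FALSE)
      first <- !duplicated(key)
      records <- records[first, , drop = FALSE]
      records$count <- as.integer(counts[match(key[first], rownames(counts))])
    }
    # diagnoses are billed as presence, not frequency
    dx <- records$record_class == "diagnosis_icd10"
    records$count[dx] <- 1L
    rownames(records) <- NULL
  }
  structure(list(patients = patients, records = records),
            class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  npos <- sum(x$patients$label_igan)
  cat(sprintf("<claims_cohort: %d patients (%d IgAN, %.1f%%), %d billing records>\n",
              nrow(x$patients), npos,
              100 * npos / max(1L, nrow(x$patients)), nrow(x$records)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A `claims_cohort`.
#' @return Integer.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "claims_cohort"))
  nrow(cohort$patients)
}

#' Read a labeled claims cohort from disk
#'
#' The on-disk representation is two UTF-8 tables: a records table with
#' header `patient_id,record_class,code,count` and a patients table with
#' header `patient_id,age_years,label_igan` (`label_igan` coded 0/1). The
#' `"jsonl"` dialect stores one JSON object per line with the same fields.
#' Duplicate record rows are merged by summing counts and diagnosis counts
#' are clamped to presence, as in [claims_cohort()].
#'
#' @param records_path,patients_path File paths.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return A `claims_cohort`.
#' @export
read_cohort <- function(records_path, patients_path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  for (p in c(records_path, patients_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  if (format == "csv") {
    records  <- read_checked_csv(records_path,
                                 c("patient_id", "record_class", "code", "count"))
    patients <- read_checked_csv(patients_path,
                                 c("patient_id", "age_years", "label_igan"))
  } else {
    records  <- read_jsonl(records_path,
                           c("patient_id", "record_class", "code", "count"))
    patients <- read_jsonl(patients_path,
                           c("patient_id", "age_years", "label_igan"))
  }
  if (nrow(records) > 0L) {
    n <- suppressWarnings(as.numeric(records$count))
    if (anyNA(n)) {
      stop(sprintf("parse error in %s, line %d: count '%s' is not a number",
                   records_path, which(is.na(n))[1L] + 1L,
                   records$count[which(is.na(n))[1L]]))
    }
    records$count <- as.integer(n)
  }
  a <- suppressWarnings(as.numeric(patients$age_years))
  if (anyNA(a) && nrow(patients) > 0L) {
    stop(sprintf("parse error in %s, line %d: age_years '%s' is not a number",
                 patients_path, which(is.na(a))[1L] + 1L,
                 patients$age_years[which(is.na(a))[1L]]))
  }
  patients$age_years <- a
  lab <- patients$label_igan
  if (!all(lab %in% c(0, 1, "0", "1", TRUE, FALSE))) {
    stop(sprintf("parse error in %s: label_igan must be 0 or 1", patients_path))
  }
  patients$label_igan <- as.integer(lab) == 1L
  claims_cohort(patients, records)
}

read_checked_csv <- function(path, expected_cols) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), expected_cols)) {
    stop(sprintf("parse error in %s, line 1: expected header '%s', found '%s'",
                 path, paste(expected_cols, collapse = ","),
                 paste(names(df), collapse = ",")))
  }
  df
}

read_jsonl <- function(path, expected_cols) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(expected_cols)),
                                        expected_cols))
    return(df)
  }
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      stop(sprintf("parse error in %s, line %d: %s",
                                   path, i, conditionMessage(e)), call. = FALSE)
                    })
    missing <- setdiff(expected_cols, names(obj))
    if (length(missing) > 0L) {
      stop(sprintf("parse error in %s, line %d: missing field '%s'",
                   path, i, missing[1L]))
    }
    as.data.frame(obj[expected_cols], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a claims cohort to disk
#'
#' Rows are emitted in a deterministic order (records by patient_id, record
#' class, code; patients by patient_id) so identical cohorts serialize to
#' identical bytes. `read_cohort()` after `write_cohort()` reproduces the
#' cohort exactly.
#'
#' @param cohort A `claims_cohort`.
#' @inheritParams read_cohort
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, records_path, patients_path,
                         format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "claims_cohort"))
  rec <- cohort$records
  rec <- rec[order(rec$patient_id, rec$record_class, rec$code), , drop = FALSE]
  pat <- cohort$patients[order(cohort$patients$patient_id), , drop = FALSE]
  pat_out <- data.frame(patient_id = pat$patient_id,
                        age_years  = pat$age_years,
                        label_igan = as.integer(pat$label_igan))
  if (format == "csv") {
    write_csv_lf(rec, records_path)
    write_csv_lf(pat_out, patients_path)
  } else {
    write_jsonl(rec, records_path)
    write_jsonl(pat_out, patients_path)
  }
  invisible(cohort)
}

write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df) > 0L) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA),
                 con, sep = "\n")
    }
  }
}
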