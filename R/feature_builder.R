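#' Build a patient x feature matrix under a preprocessing pattern
#'
#' Converts a cohort's billing records into the numeric matrix consumed by
#' the classifier, under one of three preprocessing patterns:
#'
#' * `"a"` (raw): one feature per distinct raw code, medication and
#'   diagnosis codes uncompiled;
#' * `"b"` (compiled, nephrology excluded): drug codes collapsed to
#'   therapeutic class + administration route ([drug_group_key()]),
#'   diagnosis codes collapsed to their first two characters, and the
#'   nephrology ICD-10 category (N0xx--N2xx) dropped entirely;
#' * `"c"` (compiled, nephrology kept): as `"b"`, but nephrology diagnosis
#'   codes are kept, compiled to their first three characters.
#'
#' Procedure/billing item codes are never compiled. Counts are summed within
#' a group; diagnosis-derived columns are clamped to 0/1 (presence). An
#' `age_years` column is always appended. Feature names are prefixed by code
#' system (`dx:`, `drug:`, `proc:`) and the column order is sorted, so
#' construction is deterministic. Features whose name (or bare code part)
#' matches a denylist pattern -- e.g. variables considered leaky for a given
#' study -- are dropped.
#'
#' @param cohort A `claims_cohort` with at least one patient.
#' @param pattern `"a"`, `"b"`, or `"c"`.
#' @param denylist Character vector of wildcard patterns
#'   (see [matches_code_pattern()]); default empty.
#' @return An object of class `feature_matrix`: list with `patient_ids`,
#'   `feature_names`, `values` (numeric matrix), `labels` (logical), and
#'   `pattern`.
#' @export
build_feature_matrix <- function(cohort, pattern = c("a", "b", "c"),
                                 denylist = character()) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(cohort, "claims_cohort"))
  if (n_patients(cohort) == 0L) stop("cohort has no patients")

  rec <- cohort$records
  feat <- character(nrow(rec))
  is_dx   <- rec$record_class == "diagnosis_icd10"
  is_drug <- rec$record_class == "drug_mhlw"
  is_proc <- rec$record_class == "procedure_billing"
  feat[is_proc] <- paste0("proc:", rec$code[is_proc])
  if (pattern == "a") {
    feat[is_dx]   <- paste0("dx:", rec$code[is_dx])
    feat[is_drug] <- paste0("drug:", rec$code[is_drug])
  } else {
    if (any(is_drug)) {
      drug_codes <- rec$code[is_drug]
      bad <- nchar(drug_codes) != 12L | is.na(mhlw_route(drug_codes))
      if (any(bad)) {
        # surface grammar errors with the standard message
        parse_mhlw_code(drug_codes[bad][1L])
      }
      feat[is_drug] <- paste0("drug:", substr(drug_codes, 1L, 4L), ":",
                              mhlw_route(drug_codes))
    }
    scheme <- if (pattern == "b") "pattern_b" else "pattern_c"
    key <- icd10_group_key(rec$code[is_dx], scheme)
    feat[is_dx] <- ifelse(is.na(key), NA_character_, paste0("dx:", key))
  }
  keep <- !is.na(feat)
  rec <- rec[keep, , drop = FALSE]
  feat <- feat[keep]

  ids <- cohort$patients$patient_id
  feature_names <- sort(unique(feat))
  values <- matrix(0, nrow = length(ids), ncol = length(feature_names),
                   dimnames = list(ids, feature_names))
  if (nrow(rec) > 0L) {
    agg <- rowsum(rec$count, paste(rec$patient_id, feat, sep = "\r"))
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    values[cbind(match(vapply(parts, `[[`, "", 1L), ids),
                 match(vapply(parts, `[[`, "", 2L), feature_names))] <-
      agg[, 1L]
  }
  dx_cols <- startsWith(feature_names, "dx:")
  if (any(dx_cols)) values[, dx_cols] <- pmin(values[, dx_cols, drop = FALSE], 1)
  values <- cbind(values, age_years = cohort$patients$age_years)
  feature_names <- c(feature_names, "age_years")

  if (length(denylist) > 0L) {
    bare <- sub("^(dx|drug|proc):", "", feature_names)
    drop <- Reduce(`|`, lapply(denylist, function(p) {
      matches_code_pattern(p, feature_names) | matches_code_pattern(p, bare)
    }))
    values <- values[, !drop, drop = FALSE]
    feature_names <- feature_names[!drop]
  }
  ord <- order(feature_names)
  structure(
    list(patient_ids = ids, feature_names = feature_names[ord],
         values = values[, ord, drop = FALSE],
         labels = cohort$patients$label_igan, pattern = pattern),
    class = "feature_matrix"
  )
}

#' Number of feature columns in a feature matrix
#' @param matrix A `feature_matrix`.
#' @return Integer.
#' @export
feature_count <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  length(matrix$feature_names)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: pattern (%s), %d patients x %d features, %d IgAN>\n",
              x$pattern, length(x$patient_ids), feature_count(x),
              sum(x$labels)))
  invisible(x)
}

#' Subset the rows (patients) of a feature matrix
#'
#' @param matrix A `feature_matrix`.
#' @param rows Integer or logical row index.
#' @return A `feature_matrix` over the selected patients.
#' @export
fm_subset <- function(matrix, rows) {
  stopifnot(inherits(matrix, "feature_matrix"))
  structure(
    list(patient_ids = matrix$patient_ids[rows],
         feature_names = matrix$feature_names,
         values = matrix$values[rows, , drop = FALSE],
         labels = matrix$labels[rows], pattern = matrix$pattern),
    class = "feature_matrix"
  )
}

#' Serialize a feature matrix to TSV
#'
#' One row per patient; first column `patient_id`, last column `label_igan`
#' (0/1), feature columns between, in matrix order.
#'
#' @param matrix A `feature_matrix`.
#' @param path Output path.
#' @return Invisibly, the matrix.
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  df <- data.frame(patient_id = matrix$patient_ids,
                   matrix$values,
                   label_igan = as.integer(matrix$labels),
                   check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(matrix)
}
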