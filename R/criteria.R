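#' Define a single billing-data criterion
#'
#' A criterion tests one clinical fact against a patient's billing records:
#' presence of a diagnosis code family, a billing (procedure) item appearing
#' at least a given number of times, or use of a drug class, optionally
#' restricted to an administration route. Code families are expressed as
#' wildcard patterns (see [matches_code_pattern()]).
#'
#' @param name Short identifier.
#' @param kind One of `"diagnosis_present"`, `"procedure_count_at_least"`,
#'   `"drug_class_present"`.
#' @param code_patterns Character vector of wildcard patterns (>= 1).
#' @param threshold Minimum total occurrence count (count criteria only).
#' @param route Optional administration route restriction for drug criteria:
#'   `"oral"`, `"infusion"`, or `"external"`.
#' @return An object of class `criterion` (also a `criterion_expr` leaf).
#' @export
criterion <- function(name, kind, code_patterns, threshold = 1L, route = NULL) {
  kind <- match.arg(kind, c("diagnosis_present", "procedure_count_at_least",
                            "drug_class_present"))
  if (length(code_patterns) < 1L || any(!nzchar(code_patterns))) {
    stop("`code_patterns` must contain at least one non-empty pattern")
  }
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L) stop("`threshold` must be >= 1")
  if (!is.null(route)) {
    route <- match.arg(route, c("oral", "infusion", "external"))
    if (kind != "drug_class_present") stop("`route` applies only to drug criteria")
  }
  structure(list(name = name, kind = kind, code_patterns = code_patterns,
                 threshold = threshold, route = route),
            class = c("criterion", "criterion_expr"))
}

#' Combine criteria with logical AND / OR
#'
#' Builds an expression tree over criteria; [evaluate_expr()] applies the
#' tree per patient. `crit_all()` is conjunction, `crit_any()` disjunction.
#'
#' @param ... Two or more `criterion_expr` objects.
#' @param name Optional label for reports.
#' @return A `criterion_expr`.
#' @export
crit_all <- function(..., name = NULL) new_crit_node("and", list(...), name)

#' @rdname crit_all
#' @export
crit_any <- function(..., name = NULL) new_crit_node("or", list(...), name)

new_crit_node <- function(op, children, name) {
  if (length(children) < 2L) stop("combined criteria need at least 2 children")
  ok <- vapply(children, inherits, logical(1), what = "criterion_expr")
  if (!all(ok)) stop("all children must be criterion or criterion_expr objects")
  structure(list(op = op, children = children, name = name),
            class = "criterion_expr")
}

#' Evaluate a criterion expression over a cohort
#'
#' @param expr A `criterion` or combined `criterion_expr`.
#' @param cohort A `claims_cohort`.
#' @return Logical vector, one element per patient, in the order of
#'   `cohort$patients`.
#' @export
evaluate_expr <- function(expr, cohort) {
  stopifnot(inherits(cohort, "claims_cohort"))
  if (inherits(expr, "criterion")) return(evaluate_criterion(expr, cohort))
  stopifnot(inherits(expr, "criterion_expr"))
  parts <- lapply(expr$children, evaluate_expr, cohort = cohort)
  if (expr$op == "and") Reduce(`&`, parts) else Reduce(`|`, parts)
}

evaluate_criterion <- function(crit, cohort) {
  class_of_kind <- c(diagnosis_present         = "diagnosis_icd10",
                     procedure_count_at_least  = "procedure_billing",
                     drug_class_present        = "drug_mhlw")
  rec <- cohort$records
  rec <- rec[rec$record_class == class_of_kind[[crit$kind]], , drop = FALSE]
  if (nrow(rec) > 0L) {
    hit <- Reduce(`|`, lapply(crit$code_patterns, matches_code_pattern,
                              code = rec$code))
    if (!is.null(crit$route)) {
      hit <- hit & mhlw_route(rec$code) %in% crit$route
    }
    rec <- rec[hit, , drop = FALSE]
  }
  totals <- rep(0L, n_patients(cohort))
  if (nrow(rec) > 0L) {
    s <- rowsum(rec$count, rec$patient_id)
    idx <- match(rownames(s), cohort$patients$patient_id)
    totals[idx] <- as.integer(s[, 1L])
  }
  totals >= crit$threshold
}

#' The default billing-code criteria for IgAN phenotyping
#'
#' Criteria over ICD-10 diagnosis codes, billing item codes, and MHLW drug
#' classes built from diagnoses and guideline-recommended examinations and
#' treatments for IgA nephropathy:
#'
#' * `igan_code` -- diagnosis code of IgAN itself (N028);
#' * `any_glomerular` -- any glomerular-disease diagnosis (N00x--N08x);
#' * `recurrent_hematuria` (N02x), `chronic_gn` (N03x);
#' * `serum_iga_once` / `serum_iga_twice` -- serum IgA measurement (billing
#'   item D015) at least once / at least twice;
#' * `needle_biopsy` (D412), `immunostaining` (N002);
#' * `ras_inhibitor` -- renin-angiotensin system inhibitors (MHLW classes
#'   2144, 2149);
#' * `corticosteroid_injectable` -- class 2456 restricted to the infusion
#'   route; `corticosteroid_any` -- class 2456, any route;
#' * `dilazep_class` -- the coronary-artery-dilator class that includes
#'   dilazep (2171);
#' * `tonsillitis_treatment` -- billing item J098.
#'
#' @return Named list of `criterion` objects.
#' @export
default_criteria <- function() {
  list(
    igan_code = criterion("igan_code", "diagnosis_present", "N028"),
    any_glomerular = criterion(
      "any_glomerular", "diagnosis_present",
      c("N00x", "N01x", "N02x", "N03x", "N04x", "N05x", "N06x", "N07x", "N08x")),
    recurrent_hematuria = criterion("recurrent_hematuria", "diagnosis_present", "N02x"),
    chronic_gn = criterion("chronic_gn", "diagnosis_present", "N03x"),
    serum_iga_once  = criterion("serum_iga_once",  "procedure_count_at_least",
                                "D015", threshold = 1L),
    serum_iga_twice = criterion("serum_iga_twice", "procedure_count_at_least",
                                "D015", threshold = 2L),
    needle_biopsy  = criterion("needle_biopsy",  "procedure_count_at_least", "D412"),
    immunostaining = criterion("immunostaining", "procedure_count_at_least", "N002"),
    ras_inhibitor = criterion("ras_inhibitor", "drug_class_present",
                              c("2144xxxxxxxx", "2149xxxxxxxx")),
    corticosteroid_injectable = criterion("corticosteroid_injectable",
                                          "drug_class_present", "2456xxxxxxxx",
                                          route = "infusion"),
    corticosteroid_any = criterion("corticosteroid_any", "drug_class_present",
                                   "2456xxxxxxxx"),
    dilazep_class = criterion("dilazep_class", "drug_class_present", "2171xxxxxxxx"),
    tonsillitis_treatment = criterion("tonsillitis_treatment",
                                      "procedure_count_at_least", "J098")
  )
}

#' The six manual scoring factors
#'
#' The factor-count score awards one point per satisfied item, following the
#' headings of the Japanese clinical guidelines for IgAN: two or more serum
#' IgA measurements; needle biopsy together with immunostaining or
#' immunofluorescence; renin-angiotensin system inhibitors; the drug group
#' that includes dilazep hydrochloride hydrate; corticosteroids in any form;
#' and treatment of tonsillitis.
#'
#' @return List of six `criterion_expr` objects.
#' @export
default_score_factors <- function() {
  cr <- default_criteria()
  list(
    serum_iga_twice   = cr$serum_iga_twice,
    biopsy_immunostain = crit_all(cr$needle_biopsy, cr$immunostaining,
                                  name = "biopsy_immunostain"),
    ras_inhibitor     = cr$ras_inhibitor,
    dilazep_class     = cr$dilazep_class,
    corticosteroid_any = cr$corticosteroid_any,
    tonsillitis_treatment = cr$tonsillitis_treatment
  )
}

#' Factor-count manual score per patient
#'
#' Counts, for each patient, how many of the scoring factors are satisfied
#' (0 to the number of factors; 0--6 with the defaults). The score is the
#' input to the manual ROC analysis.
#'
#' @param cohort A `claims_cohort`.
#' @param factors List of `criterion_expr` objects; defaults to
#'   [default_score_factors()].
#' @return Integer vector aligned to `cohort$patients`.
#' @export
manual_score <- function(cohort, factors = default_score_factors()) {
  if (length(factors) == 0L) stop("`factors` must contain at least one item")
  hits <- vapply(factors, evaluate_expr, logical(n_patients(cohort)),
                 cohort = cohort)
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = n_patients(cohort))
  as.integer(rowSums(hits))
}

#' Diagnostic-performance metrics from predicted and true labels
#'
#' Computes the 2x2 confusion table and sensitivity, specificity, positive
#' and negative predictive value, and accuracy. When there are no predicted
#' positives the PPV is undefined and reported as `NA` rather than 0.
#'
#' @param predicted Logical vector of criterion/classifier calls.
#' @param labels Logical vector of gold-standard labels (same length; both
#'   classes present).
#' @return An object of class `confusion_metrics` with fields `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, labels) {
  predicted <- as.logical(predicted); labels <- as.logical(labels)
  if (length(predicted) != length(labels)) {
    stop("`predicted` and `labels` must have the same length")
  }
  if (anyNA(predicted) || anyNA(labels)) stop("missing values not allowed")
  if (!any(labels) || all(labels)) {
    stop("`labels` must contain at least one positive and one negative")
  }
  tp <- sum(predicted & labels);  fp <- sum(predicted & !labels)
  fn <- sum(!predicted & labels); tn <- sum(!predicted & !labels)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
         npv = if (tn + fn == 0L) NA_real_ else tn / (tn + fn),
         accuracy = (tp + tn) / (tp + fp + fn + tn)),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics: TP %d FP %d FN %d TN %d>\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  Sn %.4f  Sp %.4f  PV+ %s  PV- %s  Ac %.4f\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.4f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.4f", x$npv)),
              x$accuracy))
  invisible(x)
}

#' Round half away from zero, as used for display of metrics
#'
#' Plain `round()` rounds half to even; printed diagnostic tables
#' conventionally round half up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Metrics table for a set of criteria over a labeled cohort
#'
#' Evaluates each expression and tabulates the 2x2 counts and the five
#' diagnostic metrics, one row per criterion, in the style of a manual
#' test-performance table.
#'
#' @param cohort A `claims_cohort`.
#' @param exprs Named list of `criterion_expr` objects.
#' @param digits Decimal places for the metric columns (half-up); `NULL`
#'   leaves metrics unrounded.
#' @return Data frame with columns `name`, `tp`, `fp`, `fn`, `tn`, `sn`,
#'   `sp`, `ppv`, `npv`, `ac`.
#' @export
metrics_table <- function(cohort, exprs = default_criteria(), digits = 4L) {
  stopifnot(length(exprs) > 0L, !is.null(names(exprs)))
  labels <- cohort$patients$label_igan
  rows <- lapply(names(exprs), function(nm) {
    m <- confusion_metrics(evaluate_expr(exprs[[nm]], cohort), labels)
    data.frame(name = nm, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
               sn = m$sensitivity, sp = m$specificity, ppv = m$ppv,
               npv = m$npv, ac = m$accuracy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    for (cl in c("sn", "sp", "ppv", "npv", "ac")) {
      out[[cl]] <- round_half_up(out[[cl]], digits)
    }
  }
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson chi-square statistic with 1 degree of freedom and its
#' upper-tail p-value, for comparing a binary characteristic between two
#' groups laid out as `a b / c d`.
#'
#' @param a,b,c,d Non-negative integer cell counts; all row and column
#'   margins must be positive.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) stop("cell counts must be non-negative")
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
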