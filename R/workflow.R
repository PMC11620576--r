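#' Default combined criteria for the manual-analysis report
#'
#' Expression trees pairing the diagnostic code families with the
#' guideline-recommended examinations and treatments, in the style of the
#' combined rows of a manual test-performance table: the N02x/N03x
#' disjunction, biopsy with immunostaining, and their conjunctions with the
#' treatment criteria. Joint metrics of combined criteria depend on the
#' within-patient joint distribution of codes, which the deterministic
#' fixture does not model; on the fixture they are layout artifacts.
#'
#' @return Named list of `criterion_expr` objects.
#' @export
default_combined_criteria <- function() {
  cr <- default_criteria()
  hema_gn <- crit_any(cr$recurrent_hematuria, cr$chronic_gn, name = "hematuria_or_gn")
  biopsy  <- crit_all(cr$needle_biopsy, cr$immunostaining, name = "biopsy_immunostain")
  list(
    hematuria_or_gn = hema_gn,
    biopsy_immunostain = biopsy,
    hema_gn_and_iga_twice = crit_all(hema_gn, cr$serum_iga_twice),
    hema_gn_and_biopsy = crit_all(hema_gn, biopsy),
    hema_gn_and_dilazep = crit_all(hema_gn, cr$dilazep_class),
    hema_gn_and_ras = crit_all(hema_gn, cr$ras_inhibitor),
    hema_gn_and_steroid_iv = crit_all(hema_gn, cr$corticosteroid_injectable),
    iga_twice_and_biopsy = crit_all(cr$serum_iga_twice, biopsy)
  )
}

#' Run the manual rule-based analysis over a cohort
#'
#' Evaluates the single criteria and the combined expressions, tabulates the
#' five diagnostic metrics per row, computes the factor-count manual score
#' and its ROC with the Youden-optimal cutoff, and (optionally) writes the
#' metrics table and ROC points as CSV files.
#'
#' @param cohort A `claims_cohort`.
#' @param criteria Named list of single criteria; default [default_criteria()].
#' @param combined Named list of combined expressions; default
#'   [default_combined_criteria()]. May be empty.
#' @param factors Scoring factors; default [default_score_factors()].
#' @param out_dir Optional output directory; if given, writes
#'   `criteria_metrics.csv` and `manual_score_roc.csv` there.
#' @return List with `metrics` (data frame), `score` (integer vector), and
#'   `roc` (a `roc_result`).
#' @export
run_manual_analysis <- function(cohort, criteria = default_criteria(),
                                combined = default_combined_criteria(),
                                factors = default_score_factors(),
                                out_dir = NULL) {
  if (length(criteria) + length(combined) == 0L) {
    stop("no criteria configured")
  }
  metrics <- metrics_table(cohort, c(criteria, combined))
  score <- manual_score(cohort, factors)
  roc <- roc_curve(score, cohort$patients$label_igan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_lf(metrics, file.path(out_dir, "criteria_metrics.csv"))
    write_roc_csv(roc, file.path(out_dir, "manual_score_roc.csv"))
  }
  list(metrics = metrics, score = score, roc = roc)
}

#' Run the cross-validated machine-learning analysis over a cohort
#'
#' Builds the feature matrix for each requested preprocessing pattern, runs
#' stratified k-fold cross-validated boosting on each, and (optionally)
#' writes one JSON report plus per-fold ROC CSVs per pattern.
#'
#' @param cohort A `claims_cohort`.
#' @param patterns Subset of `c("a", "b", "c")`.
#' @param k,seed,budget,ranges Passed to [cross_validate()].
#' @param denylist Passed to [build_feature_matrix()].
#' @param out_dir Optional output directory.
#' @return Named list of `cv_report` objects, one per pattern.
#' @export
run_ml_analysis <- function(cohort, patterns = c("a", "b", "c"), k = 5L,
                            seed = 1L, budget = 50L,
                            ranges = default_search_ranges(),
                            denylist = character(), out_dir = NULL) {
  stopifnot(all(patterns %in% c("a", "b", "c")))
  reports <- lapply(patterns, function(p) {
    fm <- build_feature_matrix(cohort, pattern = p, denylist = denylist)
    rep <- cross_validate(fm, k = k, seed = seed, budget = budget,
                          ranges = ranges)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_cv_report(rep, file.path(out_dir, sprintf("cv_report_%s.json", p)))
      for (f in seq_along(rep$roc)) {
        write_roc_csv(rep$roc[[f]],
                      file.path(out_dir, sprintf("roc_pattern_%s_fold%d.csv", p, f)))
      }
    }
    rep
  })
  stats::setNames(reports, patterns)
}

#' Read a named-criteria configuration file
#'
#' Reads criteria from a YAML or JSON file: a mapping of name to an object
#' with `kind`, `code_patterns`, and optional `threshold` and `route`.
#'
#' @param path Path to the configuration file.
#' @return Named list of `criterion` objects.
#' @export
criteria_from_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configuration")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (length(raw) == 0L || is.null(names(raw))) {
    stop("criteria configuration must be a named mapping")
  }
  out <- lapply(names(raw), function(nm) {
    item <- raw[[nm]]
    criterion(nm, kind = item$kind,
              code_patterns = unlist(item$code_patterns),
              threshold = if (is.null(item$threshold)) 1L else item$threshold,
              route = item$route)
  })
  stats::setNames(out, names(raw))
}
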