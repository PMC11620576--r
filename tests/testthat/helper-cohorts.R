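# small in-code cohorts used across test files

toy_patients <- function(ids, label = FALSE, age = 50) {
  data.frame(patient_id = ids, age_years = age, label_igan = label,
             stringsAsFactors = FALSE)
}

toy_records <- function(patient_id, record_class, code, count = 1L) {
  data.frame(patient_id = patient_id, record_class = record_class,
             code = code, count = count, stringsAsFactors = FALSE)
}

# three patients with a mix of record classes
toy_cohort <- function() {
  claims_cohort(
    toy_patients(c("P1", "P2", "P3"), label = c(TRUE, FALSE, FALSE),
                 age = c(40, 60, 55)),
    toy_records(
      patient_id   = c("P1", "P1", "P1", "P2", "P2", "P3"),
      record_class = c("diagnosis_icd10", "drug_mhlw", "procedure_billing",
                       "diagnosis_icd10", "procedure_billing", "drug_mhlw"),
      code  = c("N028", "2171005F2021", "D015", "N039", "D015", "2149001F1021"),
      count = c(1L, 2L, 3L, 1L, 1L, 1L)
    )
  )
}

# random labeled cohort with well-formed codes, for property-style tests
random_cohort <- function(n = 30L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("R%03d", seq_len(n))
  codes <- data.frame(
    code = c("N028", "N039", "J359", "D015", "D412", "2171005F2021",
             "2456401D1021"),
    record_class = c("diagnosis_icd10", "diagnosis_icd10", "diagnosis_icd10",
                     "procedure_billing", "procedure_billing", "drug_mhlw",
                     "drug_mhlw"),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (i in seq_len(nrow(codes))) {
    has <- runif(n) < 0.4
    if (any(has)) {
      rows[[i]] <- toy_records(ids[has], codes$record_class[i], codes$code[i],
                               count = 1L + rpois(sum(has), 1))
    }
  }
  claims_cohort(
    toy_patients(ids, label = runif(n) < 0.3, age = round(runif(n, 20, 80))),
    do.call(rbind, rows)
  )
}

# valid random MHLW codes, vectorised
random_mhlw_codes <- function(m, seed = 1L) {
  set.seed(seed)
  sprintf("%04d%03d%s%d%03d",
          sample(1000:9999, m, replace = TRUE),
          sample(0:999, m, replace = TRUE),
          sample(LETTERS, m, replace = TRUE),
          sample(0:9, m, replace = TRUE),
          sample(0:999, m, replace = TRUE))
}

# brute-force pairwise Mann-Whitney AUC with half credit for ties
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
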