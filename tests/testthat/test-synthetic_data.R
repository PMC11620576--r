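test_that("the default specification carries the study's marginal counts", {
  sp <- default_spec()
  expect_equal(sp$n_igan, 437L)
  expect_equal(sp$n_non, 3306L)
  f <- function(code) unlist(sp$freq[sp$freq$code == code, c("igan", "non")],
                             use.names = FALSE)
  expect_equal(f("N028"), c(231L, 106L))
  expect_equal(f("D412"), c(162L, 385L))
  expect_equal(f("J098"), c(2L, 0L))
  expect_equal(f("D015"), c(276L, 1611L))
  expect_equal(sp$iga_split$igan, c(once = 85L, twice = 191L))
  expect_equal(sp$iga_split$non, c(once = 1049L, twice = 562L))
  # the RAS and N02x families decompose into per-code counts
  expect_equal(f("2144002F1021") + f("2149001F1021"), c(293L, 1353L))
  expect_equal(f("N028") + f("N021"), c(235L, 158L))
  expect_error(cohort_spec(n_igan = 10), "exceed")
})

test_that("the fixture reproduces every specified marginal exactly", {
  sp <- default_spec()
  co <- build_table1_fixture(sp)
  expect_equal(n_patients(co), 3743L)
  expect_equal(sum(co$patients$label_igan), 437L)
  m <- estimate_marginals(co)
  obs <- merge(sp$freq, m, by = c("code", "record_class"), all.x = TRUE)
  obs$igan.y[is.na(obs$igan.y)] <- 0L
  obs$non.y[is.na(obs$non.y)] <- 0L
  expect_equal(obs$igan.y, obs$igan.x)
  expect_equal(obs$non.y, obs$non.x)
  # serum IgA split: exactly-once and twice-or-more blocks
  lab <- co$patients$label_igan
  iga2 <- evaluate_expr(default_criteria()$serum_iga_twice, co)
  expect_equal(c(sum(iga2 & lab), sum(iga2 & !lab)), c(191L, 562L))
  iga1 <- evaluate_expr(default_criteria()$serum_iga_once, co)
  expect_equal(c(sum(iga1 & lab), sum(iga1 & !lab)), c(276L, 1611L))
  # the glomerular union and the family criteria
  cr <- default_criteria()
  glom <- evaluate_expr(cr$any_glomerular, co)
  expect_equal(c(sum(glom & lab), sum(glom & !lab)), c(380L, 1327L))
  ras <- evaluate_expr(cr$ras_inhibitor, co)
  expect_equal(c(sum(ras & lab), sum(ras & !lab)), c(293L, 1353L))
  stif <- evaluate_expr(cr$corticosteroid_injectable, co)
  expect_equal(c(sum(stif & lab), sum(stif & !lab)), c(60L, 151L))
  stany <- evaluate_expr(cr$corticosteroid_any, co)
  expect_equal(c(sum(stany & lab), sum(stany & !lab)), c(144L, 552L))
  # ages sit at the class means
  expect_equal(unique(co$patients$age_years[lab]), 47.1)
  expect_equal(unique(co$patients$age_years[!lab]), 57.1)
})

test_that("generation is reproducible and labels are fixed, not sampled", {
  sp <- cohort_spec(n_noise_codes = 20)
  g1 <- generate_cohort(sp, seed = 17)
  g2 <- generate_cohort(sp, seed = 17)
  expect_identical(g1, g2)
  g3 <- generate_cohort(sp, seed = 18)
  expect_false(identical(g1$cohort$records, g3$cohort$records))
  expect_equal(sum(g1$cohort$patients$label_igan), sp$n_igan)
  expect_equal(n_patients(g1$cohort), sp$n_igan + sp$n_non)
})

test_that("generated codes are well-formed for their record class", {
  g <- generate_cohort(cohort_spec(n_noise_codes = 60), seed = 19)
  rec <- g$cohort$records
  drugs <- unique(rec$code[rec$record_class == "drug_mhlw"])
  for (d in drugs) expect_equal(format_mhlw_code(parse_mhlw_code(d)), d)
  dx <- unique(rec$code[rec$record_class == "diagnosis_icd10"])
  expect_true(all(grepl("^[A-Z][0-9A-Z]{2,3}$", dx)))
  proc <- unique(rec$code[rec$record_class == "procedure_billing"])
  expect_true(all(grepl("^[A-Z][0-9]{3}$", proc)))
  expect_true(all(g$cohort$patients$age_years >= 0))
})

test_that("generated per-code frequencies recover the specification", {
  sp <- cohort_spec(n_noise_codes = 0)
  # average over replicates with fixed seeds; each margin within 3 binomial
  # standard errors of its target
  reps <- 8L
  tot_igan <- tot_non <- numeric(nrow(sp$freq))
  for (s in seq_len(reps)) {
    m <- estimate_marginals(generate_cohort(sp, seed = 100 + s)$cohort)
    idx <- match(sp$freq$code, m$code)
    tot_igan <- tot_igan + ifelse(is.na(idx), 0L, m$igan[idx])
    tot_non  <- tot_non + ifelse(is.na(idx), 0L, m$non[idx])
  }
  p1 <- sp$freq$igan / sp$n_igan
  p0 <- sp$freq$non / sp$n_non
  se1 <- sqrt(p1 * (1 - p1) / (sp$n_igan * reps))
  se0 <- sqrt(p0 * (1 - p0) / (sp$n_non * reps))
  expect_true(all(abs(tot_igan / reps / sp$n_igan - p1) <= 3 * se1 + 1e-12))
  expect_true(all(abs(tot_non / reps / sp$n_non - p0) <= 3 * se0 + 1e-12))
})

test_that("dependence induces co-occurrence of linked codes; zero removes it", {
  presence <- function(cohort, code) {
    ids <- cohort$patients$patient_id
    ids %in% cohort$records$patient_id[cohort$records$code == code]
  }
  cor_in_class <- function(spec, seed) {
    co <- generate_cohort(spec, seed)$cohort
    keep <- !co$patients$label_igan  # larger class
    suppressWarnings(cor(presence(co, "D412")[keep], presence(co, "N002")[keep]))
  }
  indep <- cor_in_class(cohort_spec(dependence_strength = 0, n_noise_codes = 0),
                        seed = 23)
  linked <- cor_in_class(cohort_spec(dependence_strength = 1.5, n_noise_codes = 0),
                         seed = 23)
  expect_lt(abs(indep), 0.05)
  expect_gt(linked, 0.15)
})

test_that("marginal estimation agrees with a brute-force per-patient scan", {
  co <- random_cohort(n = 25, seed = 29)
  m <- estimate_marginals(co)
  for (i in seq_len(nrow(m))) {
    carriers <- unique(co$records$patient_id[co$records$code == m$code[i]])
    lab <- co$patients$label_igan[match(carriers, co$patients$patient_id)]
    expect_equal(m$igan[i], sum(lab))
    expect_equal(m$non[i], sum(!lab))
  }
  empty <- claims_cohort(
    toy_patients("P1"),
    toy_records(character(0), character(0), character(0), integer(0)))
  expect_equal(nrow(estimate_marginals(empty)), 0L)
})
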