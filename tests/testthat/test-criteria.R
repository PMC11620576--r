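test_that("default criteria match their defining codes and thresholds", {
  cr <- default_criteria()
  co <- toy_cohort()  # P1: N028, dilazep x2, D015 x3; P2: N039, D015 x1
  expect_equal(evaluate_expr(cr$igan_code, co), c(TRUE, FALSE, FALSE))
  expect_equal(evaluate_expr(cr$chronic_gn, co), c(FALSE, TRUE, FALSE))
  expect_equal(evaluate_expr(cr$serum_iga_once, co), c(TRUE, TRUE, FALSE))
  expect_equal(evaluate_expr(cr$serum_iga_twice, co), c(TRUE, FALSE, FALSE))
  expect_equal(evaluate_expr(cr$dilazep_class, co), c(TRUE, FALSE, FALSE))
  # both RAS classes match the family criterion
  expect_equal(evaluate_expr(cr$ras_inhibitor, co), c(FALSE, FALSE, TRUE))
})

test_that("drug criteria can be restricted to the administration route", {
  cr <- default_criteria()
  co <- claims_cohort(
    toy_patients(c("P1", "P2")),
    toy_records(c("P1", "P2"), "drug_mhlw",
                c("2456001F1021", "2456401D1021"))  # oral vs infusion
  )
  expect_equal(evaluate_expr(cr$corticosteroid_any, co), c(TRUE, TRUE))
  expect_equal(evaluate_expr(cr$corticosteroid_injectable, co), c(FALSE, TRUE))
})

test_that("AND and OR expressions evaluate per patient with set inclusion", {
  cr <- default_criteria()
  co <- claims_cohort(
    toy_patients(c("P1", "P2", "P3")),
    toy_records(c("P1", "P2", "P2"),
                c("diagnosis_icd10", "procedure_billing", "procedure_billing"),
                c("N039", "D412", "N002"))
  )
  or_dx <- crit_any(cr$recurrent_hematuria, cr$chronic_gn)
  and_bx <- crit_all(cr$needle_biopsy, cr$immunostaining)
  expect_equal(evaluate_expr(or_dx, co), c(TRUE, FALSE, FALSE))
  expect_equal(evaluate_expr(and_bx, co), c(FALSE, TRUE, FALSE))
  # a patient with only one conjunct fails the AND
  co2 <- claims_cohort(toy_patients("P1"),
                       toy_records("P1", "procedure_billing", "D412"))
  expect_false(evaluate_expr(and_bx, co2))
  # AND implies OR for every patient
  rc <- random_cohort(n = 50, seed = 11)
  x <- cr$serum_iga_twice; y <- cr$needle_biopsy
  expect_true(all(evaluate_expr(crit_all(x, y), rc) <=
                    evaluate_expr(crit_any(x, y), rc)))
})

test_that("confusion metrics reproduce the IgAN-code row and identity cases", {
  pred <- c(rep(TRUE, 231), rep(FALSE, 206), rep(TRUE, 106), rep(FALSE, 3200))
  lab  <- c(rep(TRUE, 437), rep(FALSE, 3306))
  m <- confusion_metrics(pred, lab)
  expect_equal(m$tp, 231); expect_equal(m$fn, 206)
  expect_equal(m$fp, 106); expect_equal(m$tn, 3200)
  expect_equal(round_half_up(m$sensitivity), 0.5286)
  expect_equal(round_half_up(m$specificity), 0.9679)
  expect_equal(round_half_up(m$ppv), 0.6855)
  expect_equal(round_half_up(m$npv), 0.9395)
  expect_equal(round_half_up(m$accuracy), 0.9166)
  # degenerate predictors
  all_pos <- confusion_metrics(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(all_pos$sensitivity, 1); expect_equal(all_pos$specificity, 0)
  perfect <- confusion_metrics(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv",
                                "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))
  none <- confusion_metrics(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(is.na(none$ppv))  # undefined, flagged rather than 0
})

test_that("metric identities hold exactly over random integer tables", {
  set.seed(99)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    fp <- sample(0:50, 1); tn <- sample(0:50, 1)
    if (tp + fn == 0 || fp + tn == 0) next
    pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
    lab  <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
    m <- confusion_metrics(pred, lab)
    n <- tp + fn + fp + tn
    prev <- (tp + fn) / n
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$accuracy,
                 m$sensitivity * prev + m$specificity * (1 - prev))
  }
})

test_that("OR boosts sensitivity and AND boosts specificity", {
  cr <- default_criteria()
  co <- build_table1_fixture()
  lab <- co$patients$label_igan
  for (pair in list(list(cr$igan_code, cr$serum_iga_twice),
                    list(cr$needle_biopsy, cr$immunostaining),
                    list(cr$ras_inhibitor, cr$dilazep_class))) {
    mx <- confusion_metrics(evaluate_expr(pair[[1]], co), lab)
    my <- confusion_metrics(evaluate_expr(pair[[2]], co), lab)
    m_or  <- confusion_metrics(evaluate_expr(crit_any(pair[[1]], pair[[2]]), co), lab)
    m_and <- confusion_metrics(evaluate_expr(crit_all(pair[[1]], pair[[2]]), co), lab)
    expect_gte(m_or$sensitivity, max(mx$sensitivity, my$sensitivity))
    expect_gte(m_and$specificity, max(mx$specificity, my$specificity))
  }
})

test_that("the manual score counts satisfied factors and is monotone", {
  # no matching records -> 0
  empty <- claims_cohort(
    toy_patients("P1"),
    toy_records(character(0), character(0), character(0), integer(0)))
  expect_equal(manual_score(empty), 0L)
  # serum IgA twice + biopsy-with-immunostain + oral corticosteroid -> 3
  co <- claims_cohort(
    toy_patients("P1"),
    toy_records(rep("P1", 4),
                c("procedure_billing", "procedure_billing",
                  "procedure_billing", "drug_mhlw"),
                c("D015", "D412", "N002", "2456001F1021"),
                count = c(2L, 1L, 1L, 1L))
  )
  expect_equal(manual_score(co), 3L)
  # adding records never decreases the score
  co2 <- claims_cohort(
    co$patients,
    rbind(co$records, toy_records("P1", "drug_mhlw", "2171005F2021")))
  expect_gte(manual_score(co2), manual_score(co))
  expect_equal(manual_score(co2), 4L)
  expect_error(manual_score(co, factors = list()), "at least one")
})

test_that("chi-square matches the closed-form Pearson statistic", {
  # perfectly proportional and symmetric tables have statistic 0
  prop <- chi_square_2x2(10, 20, 30, 60)
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  # closed-form oracle N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  pearson_2x2 <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  got <- chi_square_2x2(31, 406, 203, 3103)
  expect_equal(got$statistic, pearson_2x2(31, 406, 203, 3103))
  expect_equal(got$statistic, 0.5988, tolerance = 1e-3)
  expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))
  set.seed(12)
  for (i in 1:20) {
    t4 <- sample(1:200, 4)
    expect_equal(chi_square_2x2(t4[1], t4[2], t4[3], t4[4])$statistic,
                 pearson_2x2(t4[1], t4[2], t4[3], t4[4]))
  }
  expect_error(chi_square_2x2(0, 0, 5, 5), "margins")
})

test_that("criteria can be loaded from a configuration file", {
  cfg <- withr::local_tempfile(fileext = ".json")
  writeLines('{"iga_twice": {"kind": "procedure_count_at_least",
                "code_patterns": ["D015"], "threshold": 2},
               "steroid_iv": {"kind": "drug_class_present",
                "code_patterns": ["2456xxxxxxxx"], "route": "infusion"}}', cfg)
  crs <- criteria_from_config(cfg)
  expect_named(crs, c("iga_twice", "steroid_iv"))
  expect_equal(crs$iga_twice$threshold, 2L)
  expect_equal(crs$steroid_iv$route, "infusion")
})
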