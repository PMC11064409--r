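# Rule-level behavior of the thirteen criteria on hand-built children.

test_that("NICU criterion needs full term, early admission, and 4+ days", {
  met <- function(ga, day, dur_d) {
    b <- fix_bundle(ga = ga,
                    encounters = list(fix_enc("icu", day, dur_d * 24)))
    evaluate_nicu_stay(b, TEST_SPECS)$met
  }
  expect_true(met(280, 1, 5))
  expect_false(met(230, 0, 30))     # pre-term: criterion not applicable
  expect_false(met(280, 10, 6))     # outside the 7-day birth window
  expect_false(met(280, 1, 3))      # too short
  r <- evaluate_nicu_stay(fix_bundle(
    ga = 280, encounters = list(fix_enc("icu", 1, 5 * 24))), TEST_SPECS)
  expect_equal(r$first_met_age, 5)  # met once the stay reaches 4 days
})

test_that("hospitalizations: prolonged stay, counts, and the PMA filter", {
  met <- function(ga, stays) {
    enc <- lapply(stays, function(s) fix_enc("inpatient", s[1], s[2]))
    evaluate_hospitalizations(fix_bundle(ga = ga, encounters = enc),
                              TEST_SPECS)$met
  }
  expect_true(met(280, list(c(60, 15 * 24))))           # one 15-day stay
  expect_false(met(280, list(c(60, 13 * 24))))          # 13 days, alone
  expect_true(met(280, list(c(60, 72), c(150, 72))))    # 2 stays, full-term
  expect_false(met(230, list(c(60, 72), c(150, 72))))   # pre-term needs 3
  expect_true(met(230, list(c(60, 72), c(150, 72), c(240, 72))))
  # birth hospitalization of a 26-week newborn starts before 245 d PMA
  expect_false(met(182, list(c(0, 60 * 24))))
  # same stay pattern admitted after 245 d PMA counts as prolonged
  expect_true(met(182, list(c(70, 60 * 24))))
})

test_that("specialists: distinct included types, term-specific thresholds", {
  visit <- function(sp, day) fix_enc("specialist_visit", day, 1,
                                     specialty = sp)
  b <- fix_bundle(encounters = list(visit("Pediatric Cardiology", 10),
                                    visit("Pediatric Neurology", 20),
                                    visit("Medical Genetics", 30)))
  r <- evaluate_multiple_specialists(b, TEST_VOCAB$taxonomy, TEST_SPECS)
  expect_true(r$met)
  expect_equal(r$first_met_age, 30)

  b <- fix_bundle(encounters = lapply(1:10, function(d)
    visit("Pediatric Cardiology", d)))
  expect_false(evaluate_multiple_specialists(b, TEST_VOCAB$taxonomy,
                                             TEST_SPECS)$met)

  # pre-term with 3 types, one excluded: only 2 count
  b <- fix_bundle(ga = 230,
                  encounters = list(visit("Pediatric Cardiology", 10),
                                    visit("Pediatric Neurology", 20),
                                    visit("Pediatric Infectious Disease", 30)))
  r <- evaluate_multiple_specialists(b, TEST_VOCAB$taxonomy, TEST_SPECS)
  expect_false(r$met)
  expect_equal(r$evidence_count, 2L)
})

test_that("ER visits: term-specific count thresholds and first-met age", {
  ers <- function(k) lapply(seq_len(k), function(j)
    fix_enc("emergency", 10 * j, 4))
  b <- fix_bundle(encounters = ers(5))
  r <- evaluate_er_visits(b, TEST_SPECS)
  expect_true(r$met)
  expect_equal(r$first_met_age, 50)
  expect_false(evaluate_er_visits(fix_bundle(encounters = ers(4)),
                                  TEST_SPECS)$met)
  expect_false(evaluate_er_visits(fix_bundle(ga = 230, encounters = ers(6)),
                                  TEST_SPECS)$met)
  expect_true(evaluate_er_visits(fix_bundle(ga = 230, encounters = ers(7)),
                                 TEST_SPECS)$met)
})

test_that("feeding support: keyword procedures unless cancelled, or ICD codes", {
  fk <- TEST_VOCAB$feeding_codes
  fr <- TEST_VOCAB$feeding_rule
  b <- fix_bundle(procedures = list(fix_proc("Gastrostomy tube placement", 40)))
  expect_true(evaluate_feeding_support(b, fk, fr)$met)
  b <- fix_bundle(procedures = list(
    fix_proc("Gastrostomy tube placement", 40, status = "cancelled")))
  expect_false(evaluate_feeding_support(b, fk, fr)$met)
  expect_false(evaluate_feeding_support(fix_bundle(), fk, fr)$met)
  co <- fix_cohort(encounters = list(fix_enc("outpatient", 30, 1, id = "E1")),
                   diagnoses = list(fix_dx("Z93.1", 30, "E1")))
  expect_true(evaluate_feeding_support(child_bundle(co, "K1"), fk, fr)$met)
})

test_that("respiratory support must be clear of every surgery window", {
  vent <- function(day) fix_proc("Mechanical ventilation", day)
  surg <- function(day) fix_proc("Appendectomy", day, surgical = TRUE)
  m <- function(...) evaluate_respiratory_support(
    fix_bundle(procedures = list(...)), TEST_SPECS,
    TEST_VOCAB$respiratory_codes, TEST_VOCAB$respiratory_rule)$met
  expect_true(m(vent(30)))
  expect_false(m(vent(30), surg(30)))   # perioperative
  expect_false(m(vent(33), surg(30)))   # day s+3: still inside window
  expect_true(m(vent(35), surg(30)))    # s+5 qualifies
  expect_true(m(vent(29), surg(30)))    # s-1 qualifies
  expect_false(m(vent(32), surg(30), surg(33)))  # blocked by both
  # cardiothoracic ICU admissions anchor the window too
  b <- fix_bundle(encounters = list(fix_enc("cticu", 30, 48)),
                  procedures = list(vent(31)))
  expect_false(evaluate_respiratory_support(b, TEST_SPECS,
                                            TEST_VOCAB$respiratory_codes,
                                            TEST_VOCAB$respiratory_rule)$met)
})

test_that("order criteria accept completed/preliminary/final, never cancelled", {
  b <- fix_bundle(lab_orders = list(fix_lab("imaging_mri", 50, "final")))
  expect_true(evaluate_order_criterion(b, "imaging")$met)
  b <- fix_bundle(lab_orders = list(fix_lab("imaging_ct", 50, "cancelled")))
  expect_false(evaluate_order_criterion(b, "imaging")$met)
  b <- fix_bundle(lab_orders = list(fix_lab("metabolic_test", 60)))
  expect_true(evaluate_order_criterion(b, "metabolic_tests")$met)
  expect_false(evaluate_order_criterion(b, "genetic_tests")$met)
  expect_error(evaluate_order_criterion(b, "proteomics"), "unknown order")
})

test_that("death is detected from dispositions or the death date", {
  dd <- TEST_VOCAB$death_dispositions
  b <- fix_bundle(encounters = list(
    fix_enc("inpatient", 100, 24, disposition = "Expired")))
  expect_true(evaluate_death(b, dd)$met)
  b <- fix_bundle(encounters = list(
    fix_enc("inpatient", 100, 24, disposition = "Home")))
  expect_false(evaluate_death(b, dd)$met)
  b <- fix_bundle(death_day = 400)
  r <- evaluate_death(b, dd)
  expect_true(r$met)
  expect_equal(r$first_met_age, 400)
})

test_that("developmental delay: one specialist visit or two distinct ICD dates", {
  ddc <- TEST_VOCAB$developmental_delay_codes
  b <- fix_bundle(encounters = list(
    fix_enc("specialist_visit", 200, 1,
            specialty = "Developmental Pediatrics")))
  expect_true(evaluate_developmental_delay(b, ddc)$met)

  co1 <- fix_cohort(encounters = list(fix_enc("outpatient", 100, 1, id = "E1")),
                    diagnoses = list(fix_dx("F80.1", 100, "E1")))
  expect_false(evaluate_developmental_delay(child_bundle(co1, "K1"), ddc)$met)

  co2 <- fix_cohort(
    encounters = list(fix_enc("outpatient", 100, 1, id = "E1"),
                      fix_enc("outpatient", 150, 1, id = "E2")),
    diagnoses = list(fix_dx("F80.1", 100, "E1"), fix_dx("R62.50", 150, "E2")))
  r <- evaluate_developmental_delay(child_bundle(co2, "K1"), ddc)
  expect_true(r$met)
  expect_equal(r$first_met_age, 150)

  # two codes on the same date are one occurrence
  co3 <- fix_cohort(
    encounters = list(fix_enc("outpatient", 100, 1, id = "E1")),
    diagnoses = list(fix_dx("F80.1", 100, "E1"), fix_dx("F82.4", 100, "E1")))
  expect_false(evaluate_developmental_delay(child_bundle(co3, "K1"), ddc)$met)
})

test_that("metabolic ICD codes must span two distinct encounters", {
  mc <- TEST_VOCAB$metabolic_codes
  co <- fix_cohort(
    encounters = list(fix_enc("outpatient", 90, 1, id = "A"),
                      fix_enc("outpatient", 150, 1, id = "B")),
    diagnoses = list(fix_dx("E71.311", 90, "A"), fix_dx("E71.311", 150, "B")))
  r <- evaluate_metabolic_icd(child_bundle(co, "K1"), mc)
  expect_true(r$met)
  expect_equal(r$first_met_age, 150)

  co <- fix_cohort(
    encounters = list(fix_enc("outpatient", 90, 1, id = "A")),
    diagnoses = list(fix_dx("E71.311", 90, "A"), fix_dx("E70.0", 90, "A")))
  expect_false(evaluate_metabolic_icd(child_bundle(co, "K1"), mc)$met)
  expect_false(evaluate_metabolic_icd(fix_bundle(), mc)$met)
})

test_that("heart surgery: CTICU encounters or cardiothoracic procedures", {
  b <- fix_bundle(encounters = list(fix_enc("cticu", 3, 72)))
  r <- evaluate_heart_surgery(b)
  expect_true(r$met)
  expect_equal(r$first_met_age, 3)
  b <- fix_bundle(procedures = list(
    fix_proc("VSD repair", 20, surgical = TRUE, cardiothoracic = TRUE)))
  expect_true(evaluate_heart_surgery(b)$met)
  b <- fix_bundle(procedures = list(
    fix_proc("Inguinal hernia repair", 20, surgical = TRUE)))
  expect_false(evaluate_heart_surgery(b)$met)
})

test_that("evaluate_all composes the rules and keeps ages within the window", {
  p <- evaluate_all(fix_bundle(), TEST_SPECS, TEST_VOCAB)
  expect_false(any(p$met))
  expect_true(all(is.na(p$first_met_age)))

  enc <- c(lapply(1:5, function(j) fix_enc("emergency", 10 * j, 4)))
  b <- fix_bundle(encounters = enc,
                  lab_orders = list(fix_lab("imaging_mri", 50, "final")))
  p <- evaluate_all(b, TEST_SPECS, TEST_VOCAB)
  expect_setequal(p$criterion[p$met], c("er_visits", "imaging"))
  expect_true(all(p$met == !is.na(p$first_met_age)))
  expect_true(all(p$first_met_age[p$met] <= 1095))

  # pre-term child whose only event is a 30-day NICU stay from birth
  b <- fix_bundle(ga = 182, encounters = list(fix_enc("icu", 0, 30 * 24)))
  expect_false(any(evaluate_all(b, TEST_SPECS, TEST_VOCAB)$met))
})

test_that("added events never un-meet a criterion except via new surgeries", {
  base_enc <- lapply(1:5, function(j) fix_enc("emergency", 10 * j, 4))
  b1 <- fix_bundle(encounters = base_enc,
                   procedures = list(fix_proc("Mechanical ventilation", 30)))
  p1 <- evaluate_all(b1, TEST_SPECS, TEST_VOCAB)
  extra <- c(base_enc, list(fix_enc("emergency", 60, 4),
                            fix_enc("inpatient", 100, 72),
                            fix_enc("cticu", 200, 48)))
  b2 <- fix_bundle(encounters = extra,
                   procedures = list(fix_proc("Mechanical ventilation", 30),
                                     fix_proc("Tendon release", 150,
                                              surgical = TRUE)))
  p2 <- evaluate_all(b2, TEST_SPECS, TEST_VOCAB)
  kept <- setdiff(p1$criterion[p1$met], "respiratory_support")
  expect_true(all(kept %in% p2$criterion[p2$met]))

  # the documented exception: a surgery landing on the support day
  b3 <- fix_bundle(procedures = list(fix_proc("Mechanical ventilation", 30),
                                     fix_proc("Appendectomy", 30,
                                              surgical = TRUE)))
  p3 <- evaluate_all(b3, TEST_SPECS, TEST_VOCAB)
  expect_false(p3$met[p3$criterion == "respiratory_support"])
})

test_that("engine agrees with brute-force oracles on 1,000 synthetic children", {
  gen <- suppressWarnings(
    generate_cohort(generator_config(n_children = 1000, seed = 31)))
  prof <- evaluate_cohort(gen$cohort, TEST_SPECS, TEST_VOCAB)
  m <- met_matrix(prof)
  for (i in seq(1, 1000, by = 3)) {  # every third child keeps runtime modest
    id <- prof$child_id[i]
    expect_identical(m[i, ], oracle_child_met(gen$cohort, id),
                     info = id)
  }
})
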