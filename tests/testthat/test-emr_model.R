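test_that("term status uses the 37-week (259-day) cutoff", {
  expect_identical(derive_term_status(280), "full_term")
  expect_identical(derive_term_status(258), "pre_term")
  expect_identical(derive_term_status(259), "full_term")
  expect_error(derive_term_status(120), "\\[140, 315\\]")
  expect_error(derive_term_status(400), "\\[140, 315\\]")
})

test_that("postmenstrual age is gestational age plus chronological age", {
  b <- as.Date("2020-01-01")
  expect_equal(postmenstrual_age(245, b, b), 245)
  expect_equal(postmenstrual_age(245, b, b + 10), 255)
  expect_equal(postmenstrual_age(196, b, b + 49), 245)  # exactly 35 weeks
  expect_error(postmenstrual_age(245, b, b - 1), "precedes birth")
})

test_that("hospitalization episodes merge contiguous stays and censor open ends", {
  one <- fix_cohort(encounters = list(fix_enc("inpatient", 1, 50)))
  ep <- hospitalization_episodes(one$encounters, FIX_BIRTH)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_hours, 50)
  expect_false(ep$censored)

  # [day 1, day 3] and [day 3, day 5] share an endpoint: one 96 h episode
  two <- fix_cohort(encounters = list(fix_enc("inpatient", 1, 48),
                                      fix_enc("inpatient", 3, 48)))
  ep <- hospitalization_episodes(two$encounters, FIX_BIRTH)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_hours, 96)

  er <- fix_cohort(encounters = list(fix_enc("emergency", 1, 4)))
  expect_equal(nrow(hospitalization_episodes(er$encounters, FIX_BIRTH)), 0L)

  open <- fix_cohort(encounters = list(fix_enc_open("inpatient", 10)))
  ep <- hospitalization_episodes(open$encounters, FIX_BIRTH)
  expect_true(ep$censored)
  expect_equal(ep$duration_hours, (1095 - 10) * 24 - 8)  # to the window end
})

test_that("episode merging is insensitive to encounter order", {
  rows <- list(fix_enc("inpatient", 1, 30), fix_enc("inpatient", 2, 60),
               fix_enc("inpatient", 10, 48), fix_enc("inpatient", 40, 24),
               fix_enc("inpatient", 41, 36))
  co <- fix_cohort(encounters = rows)
  ref <- hospitalization_episodes(co$encounters, FIX_BIRTH)
  set.seed(3)
  for (r in 1:5) {
    shuf <- co$encounters[sample.int(nrow(co$encounters)), ]
    expect_equal(hospitalization_episodes(shuf, FIX_BIRTH), ref)
  }
})

test_that("cohorts round-trip through CSV exactly", {
  gen <- suppressWarnings(
    generate_cohort(generator_config(n_children = 100, seed = 5)))
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, dir)
  back <- read_cohort(dir)
  for (tab in c("children", "encounters", "diagnoses", "procedures",
                "lab_orders")) {
    expect_equal(back[[tab]], gen$cohort[[tab]], info = tab)
  }
  expect_equal(nrow(empty_cohort()$children), 0L)
})

test_that("validation rejects dangling ids, unknown columns, bad dates", {
  ch <- data.frame(child_id = "K1", mother_id = "M1",
                   birth_date = FIX_BIRTH, gestational_age_days = 280L,
                   death_date = as.Date(NA), stringsAsFactors = FALSE)
  e <- pheindex:::empty_encounters_table()
  d <- pheindex:::empty_diagnoses_table()
  p <- pheindex:::empty_procedures_table()
  l <- pheindex:::empty_lab_orders_table()

  dx_bad <- fix_dx("F80.1", 10, "E999", child = "GHOST")
  expect_error(cohort(ch, e, dx_bad, p, l), "unknown child_id 'GHOST'")

  dx_dangling <- fix_dx("F80.1", 10, "E999")
  expect_error(cohort(ch, e, dx_dangling, p, l), "does not resolve")

  ch_extra <- cbind(ch, zipcode = "10029")
  expect_error(cohort(ch_extra, e, d, p, l), "unknown column")

  ch_bad <- ch; ch_bad$birth_date <- "01/01/2020"
  expect_error(cohort(ch_bad, e, d, p, l), "unparseable birth_date")

  enc_spec <- fix_enc("specialist_visit", 5, 1)  # specialty missing
  expect_error(cohort(ch, enc_spec, d, p, l), "without specialty")

  enc_rev <- fix_enc("inpatient", 5, 24)
  enc_rev$end <- enc_rev$start - 3600
  expect_error(cohort(ch, enc_rev, d, p, l), "end before start")
})

test_that("events after the three-year window are dropped once and never again", {
  rows <- c(lapply(c(10, 20, 30, 40), function(d) fix_enc("emergency", d, 4)),
            list(fix_enc("emergency", 1200, 4), fix_enc("emergency", 1300, 4)))
  expect_message(co <- fix_cohort(encounters = rows), "dropping 2 event")
  expect_equal(nrow(co$encounters), 4L)
  # idempotence: a second pass drops nothing
  expect_no_message(
    co2 <- cohort(co$children, co$encounters, co$diagnoses, co$procedures,
                  co$lab_orders))
  expect_equal(co2$encounters, co$encounters)
  # the censored visits cannot push the child over the ER threshold
  b <- child_bundle(co, "K1")
  expect_false(evaluate_er_visits(b, TEST_SPECS)$met)
})
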